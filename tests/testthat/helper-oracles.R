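# Independent oracles used across the suite.  Each is a deliberately naive
# implementation (dense loops, brute force) kept free of the package's own
# code paths.

# Dense double-loop 2D convolution with half-sample symmetric reflection.
oracle_convolve2d <- function(px, kernel2d) {
  kr <- (nrow(kernel2d) - 1L) %/% 2L
  nr <- nrow(px); nc <- ncol(px)
  refl <- function(i, n) {
    j <- (i - 1L) %% (2L * n)
    ifelse(j < n, j + 1L, 2L * n - j)
  }
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    acc <- 0
    for (dr in -kr:kr) for (dc in -kr:kr)
      acc <- acc + kernel2d[dr + kr + 1L, dc + kr + 1L] *
        px[refl(r + dr, nr), refl(cc + dc, nc)]
    out[r, cc] <- acc
  }
  out
}

oracle_gaussian_kernel2d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k1 <- exp(-(-r:r)^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  outer(k1, k1)
}

# Brute-force MCT: correlation at every distinct level above the minimum.
oracle_mct <- function(px) {
  v <- as.vector(px)
  levels_ <- sort(unique(v))[-1L]
  best_t <- NA_real_; best_c <- -Inf
  for (t in levels_) {
    b <- as.numeric(v >= t)
    cc <- suppressWarnings(stats::cor(v, b))
    if (is.finite(cc) && cc > best_c + 1e-12) { best_c <- cc; best_t <- t }
  }
  list(threshold = best_t, correlation = best_c)
}

# Recursive flood fill (8-connected) component counter.
oracle_component_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  n <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (mask[r, cc] == 0L || seen[r, cc]) next
    n <- n + 1L
    stack <- list(c(r, cc)); seen[r, cc] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- p[1L] + dr; c2 <- p[2L] + dc
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        if (mask[r2, c2] != 0L && !seen[r2, c2]) {
          seen[r2, c2] <- TRUE
          stack[[length(stack) + 1L]] <- c(r2, c2)
        }
      }
    }
  }
  n
}

# Count local maxima of a 1D profile, merging plateaus; values within
# max(v) * tol collapse to one level so fp dust on flat tops is ignored.
oracle_count_maxima_1d <- function(v, tol = 1e-9) {
  vr <- round(v / (max(v) * tol))
  r <- rle(vr)
  k <- length(r$values)
  n <- 0L
  for (i in seq_len(k)) {
    lo <- if (i == 1L) -Inf else r$values[i - 1L]
    hi <- if (i == k) -Inf else r$values[i + 1L]
    if (r$values[i] > lo && r$values[i] > hi) n <- n + 1L
  }
  n
}

# Exhaustive plateau-merged local-maximum count of a 2D field above a
# floor value (8-neighbourhood).
oracle_count_maxima_2d <- function(px, floor_value = -Inf, tol = 1e-9) {
  nr <- nrow(px); nc <- ncol(px)
  q <- round(px / (max(px) * tol))
  is_cand <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (px[r, cc] <= floor_value) next
    ok <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      r2 <- r + dr; c2 <- cc + dc
      if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
      if (q[r2, c2] > q[r, cc]) ok <- FALSE
    }
    is_cand[r, cc] <- ok
  }
  # group candidate plateaus: adjacent candidates share a quantized value
  oracle_component_count(ifelse(is_cand, 1L, 0L))
}

# Render a binary mask of filled discs given centres (row, col) and radius.
render_discs <- function(size, centers, radius) {
  m <- matrix(0L, size, size)
  for (i in seq_len(nrow(centers))) {
    for (r in seq_len(size)) for (cc in seq_len(size)) {
      if ((r - centers[i, 1L])^2 + (cc - centers[i, 2L])^2 <= radius^2)
        m[r, cc] <- 1L
    }
  }
  m
}

# Render a field of 2D Gaussian peaks (row, col, amplitude), sigma in px.
render_gaussians <- function(size, spots, sigma) {
  m <- matrix(0, size, size)
  for (i in seq_len(nrow(spots))) {
    g <- spots[i, 3L] *
      outer(exp(-(seq_len(size) - spots[i, 1L])^2 / (2 * sigma^2)),
            exp(-(seq_len(size) - spots[i, 2L])^2 / (2 * sigma^2)))
    m <- m + g
  }
  m
}
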