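# Maximum Correlation Thresholding (MCT).
#
# The global threshold used by every segmentation stage: among all distinct
# observed intensity levels, pick the one whose foreground mask (I >= t) has
# maximal Pearson correlation with the grayscale image itself.  Working on
# observed levels rather than a fixed bin grid makes the method bit-depth
# agnostic and lets a brute-force scan verify it exactly.

#' Maximum correlation threshold
#'
#' Optionally pre-smooths the image with a Gaussian of sigma
#' `pre_smooth_px` (0 disables), then evaluates every distinct intensity
#' value except the global minimum as a candidate threshold `t`, computing
#' the Pearson correlation between the (smoothed) image and the binary mask
#' `I >= t` over all pixels, and returns the maximizer.  Ties are broken
#' toward the smallest threshold, i.e. the more inclusive foreground.
#'
#' @param img An [sr_image] (or matrix).
#' @param pre_smooth_px Non-negative Gaussian sigma in pixels applied before
#'   threshold selection; the returned `smoothed` image is also what the
#'   mask should be taken on (smoothing-before-threshold semantics).
#' @return A list of class `sr_threshold` with fields `threshold` (an
#'   intensity value present in the analysed image), `correlation` (the
#'   maximum achieved, in \[-1, 1\]), `candidates_evaluated`, and `smoothed`
#'   (the image the threshold refers to).
#' @examples
#' img <- sr_image(matrix(c(rep(0, 8), rep(200, 8)), 4, 4))
#' mct_threshold(img, pre_smooth_px = 0)$threshold  # 200, correlation 1
#' @export
mct_threshold <- function(img, pre_smooth_px = 1.0) {
  img <- as_sr_image(img)
  if (!is.numeric(pre_smooth_px) || pre_smooth_px < 0)
    stop_srseg("`pre_smooth_px` must be >= 0", "parameter")
  work <- if (pre_smooth_px > 0)
    gaussian_smooth(img, pre_smooth_px / FWHM_TO_SIGMA) else img
  v <- as.vector(work$pixels)
  n <- length(v)
  sv <- sort(v)  # ascending
  levels_ <- unique(sv)
  if (length(levels_) < 2L)
    stop_srseg("no threshold separates a constant image", "degenerate")
  cand <- levels_[-1L]  # all distinct values except the global minimum
  # For threshold t: n1 = #{v >= t}, S1 = sum of v over that set.  Pearson
  # correlation between v and the 0/1 mask reduces to
  #   (S1 - n1*mean) / sqrt(ssv * n1*(n - n1)/n)
  # computed from suffix sums of the sorted vector.
  first_ge <- findInterval(cand, sv, left.open = TRUE) + 1L  # index of first value >= t
  suffix <- rev(cumsum(rev(sv)))
  n1 <- n - first_ge + 1L
  S1 <- suffix[first_ge]
  mu <- mean(v)
  ssv <- sum((v - mu)^2)
  num <- S1 - n1 * mu
  den <- sqrt(ssv * n1 * (n - n1) / n)
  corr <- num / den
  best <- which.max(corr)  # which.max takes the first = smallest candidate on ties
  structure(
    list(threshold = cand[best], correlation = corr[best],
         candidates_evaluated = length(cand), smoothed = work),
    class = "sr_threshold")
}

#' @export
print.sr_threshold <- function(x, ...) {
  cat(sprintf("<sr_threshold> t = %g (correlation %.4f over %d candidates)\n",
              x$threshold, x$correlation, x$candidates_evaluated))
  invisible(x)
}

#' Apply a global threshold
#'
#' @param img An [sr_image] (or matrix).
#' @param t Threshold intensity.
#' @return Integer 0/1 matrix, 1 where intensity >= `t`.
#' @export
apply_threshold <- function(img, t) {
  img <- as_sr_image(img)
  mask <- matrix(0L, nrow(img$pixels), ncol(img$pixels))
  mask[img$pixels >= t] <- 1L
  mask
}
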