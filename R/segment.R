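# Primary object identification: threshold -> connected components ->
# declump (shape or intensity watershed with lower-maxima suppression) ->
# size/border filtering -> per-object measurements.

#' Segmentation parameters
#'
#' @param threshold_pre_smooth_px Gaussian sigma (px) applied before MCT
#'   threshold selection; the mask is taken on the smoothed image. 0
#'   disables.  Default 1, the standard pre-smoothing for MCT.
#' @param declump_method `"shape"` (distance-transform watershed, for fused
#'   parent objects whose internal intensity varies cluster to cluster),
#'   `"intensity"` (local-maxima watershed, for resolving individual
#'   clusters), or `"none"`.
#' @param suppression_distance_px Minimum spacing between watershed seeds;
#'   maxima closer than this to a higher maximum are discarded.  `"auto"`
#'   resolves to the median equivalent radius of the pre-declump connected
#'   components, the natural scale of the objects being separated.
#' @param min_diameter_px,max_diameter_px Accepted equivalent-diameter
#'   range; objects outside it are removed.
#' @param discard_border Drop objects touching any image edge.  Sensible for
#'   parent objects (partial pores are not countable); child clusters
#'   inherit the decision through their parent.
#' @return A list of class `sr_seg_params`.
#' @export
segmentation_params <- function(threshold_pre_smooth_px = 1.0,
                                declump_method = c("shape", "intensity", "none"),
                                suppression_distance_px = "auto",
                                min_diameter_px = 2,
                                max_diameter_px = 40,
                                discard_border = FALSE) {
  declump_method <- match.arg(declump_method)
  if (!identical(suppression_distance_px, "auto") &&
      (!is.numeric(suppression_distance_px) || suppression_distance_px <= 0))
    stop_srseg("`suppression_distance_px` must be \"auto\" or a positive number",
               "parameter")
  if (!is.numeric(min_diameter_px) || !is.numeric(max_diameter_px) ||
      min_diameter_px >= max_diameter_px)
    stop_srseg(sprintf(
      "size range invalid: min_diameter_px (%s) must be < max_diameter_px (%s)",
      format(min_diameter_px), format(max_diameter_px)), "parameter")
  if (threshold_pre_smooth_px < 0)
    stop_srseg("`threshold_pre_smooth_px` must be >= 0", "parameter")
  structure(list(threshold_pre_smooth_px = threshold_pre_smooth_px,
                 declump_method = declump_method,
                 suppression_distance_px = suppression_distance_px,
                 min_diameter_px = min_diameter_px,
                 max_diameter_px = max_diameter_px,
                 discard_border = isTRUE(discard_border)),
            class = "sr_seg_params")
}

#' 8-connected component labelling
#'
#' Foreground components are labelled 1..N in raster-scan order of their
#' first pixel (row-major), so labelling is deterministic.
#'
#' @param mask Integer 0/1 matrix.
#' @return Integer label matrix (0 = background).
#' @export
connected_components <- function(mask) {
  storage.mode(mask) <- "integer"
  .cc_label(mask)
}

#' Median equivalent radius of labelled objects
#'
#' The radius of the circle with the same area, `sqrt(area / pi)`, median
#' over objects (even counts average the two middle values).  This is the
#' statistic used to resolve `"auto"` lower-maxima suppression distances:
#' the suppression distance is set to the median radius of the objects
#' being declumped.
#'
#' @param lm Integer label matrix with >= 1 object.
#' @return Positive scalar, pixels.
#' @export
median_equivalent_radius <- function(lm) {
  areas <- tabulate(lm[lm > 0L])
  areas <- areas[areas > 0L]
  if (length(areas) == 0L)
    stop_srseg("label map has no objects", "degenerate")
  stats::median(sqrt(areas / pi))
}

# One seed per local-maximum plateau of `img` inside `mask`, then greedy
# lower-maxima suppression *within each connected component*: maxima are
# visited in decreasing value (ties: increasing raster index) and kept only
# if no already-kept maximum of the same component lies within
# `suppression_px`.  Per-component suppression guarantees every component
# keeps at least one seed, so declumping can only split, never lose,
# objects.  Returns a data.frame (row, col, label 1..n_seeds in raster
# order of the component they seed).
find_watershed_seeds <- function(img, mask, suppression_px) {
  comp <- connected_components(mask)
  storage.mode(mask) <- "integer"
  cand <- .local_max_mask(img, mask)
  # plateaus: adjacent candidate pixels always share one value, so a plain
  # connected-component pass groups them; keep the raster-first pixel
  plab <- .cc_label(cand)
  if (max(plab) == 0L) return(NULL)
  idx <- which(plab > 0L)
  rows <- (idx - 1L) %% nrow(mask) + 1L
  cols <- (idx - 1L) %/% nrow(mask) + 1L
  raster <- (rows - 1L) * ncol(mask) + cols
  ord <- order(plab[idx], raster)
  first <- ord[!duplicated(plab[idx][ord])]
  seeds <- data.frame(row = rows[first], col = cols[first],
                      value = img[cbind(rows[first], cols[first])],
                      comp = comp[cbind(rows[first], cols[first])],
                      raster = raster[first])
  keep <- logical(nrow(seeds))
  for (cid in unique(seeds$comp)) {
    i_comp <- which(seeds$comp == cid)
    i_comp <- i_comp[order(-seeds$value[i_comp], seeds$raster[i_comp])]
    kept_r <- numeric(0); kept_c <- numeric(0)
    for (i in i_comp) {
      if (length(kept_r) == 0L ||
          min(sqrt((kept_r - seeds$row[i])^2 + (kept_c - seeds$col[i])^2)) >=
            suppression_px) {
        keep[i] <- TRUE
        kept_r <- c(kept_r, seeds$row[i]); kept_c <- c(kept_c, seeds$col[i])
      }
    }
  }
  seeds <- seeds[keep, , drop = FALSE]
  seeds <- seeds[order(seeds$raster), , drop = FALSE]
  seeds$label <- seq_len(nrow(seeds))
  seeds
}

run_declump <- function(mask, elevation_img, seed_img, suppression_px) {
  storage.mode(mask) <- "integer"
  if (!all(mask %in% c(0L, 1L)))
    stop_srseg("mask must be 0/1", "parameter")
  if (!all(dim(elevation_img) == dim(mask)))
    stop_srseg("mask and image dimensions differ", "dimension")
  if (sum(mask) == 0L) return(matrix(0L, nrow(mask), ncol(mask)))
  seeds <- find_watershed_seeds(seed_img, mask, suppression_px)
  if (is.null(seeds)) return(connected_components(mask))
  .seeded_watershed(-elevation_img, mask,
                    as.matrix(seeds[, c("row", "col")]),
                    as.integer(seeds$label))
}

#' Declump a binary mask by shape
#'
#' Splits touching objects at shape indentations: the Euclidean distance
#' transform of the foreground is smoothed with a 1 px sigma Gaussian (to
#' kill plateau artifacts of discrete discs), its local maxima become
#' watershed seeds after lower-maxima suppression, and a seeded watershed on
#' the negated distance map partitions the foreground.  The method of
#' choice for Gaussian-fused parent objects, whose internal intensity
#' varies from one merged cluster to the next and would over-segment under
#' intensity-based splitting.
#'
#' @param mask Integer 0/1 matrix.
#' @param suppression_distance_px Minimum seed spacing, pixels.
#' @return Integer label matrix whose positive labels exactly tile the
#'   foreground.
#' @export
declump_shape <- function(mask, suppression_distance_px) {
  storage.mode(mask) <- "integer"
  if (sum(mask) == 0L) return(matrix(0L, nrow(mask), ncol(mask)))
  dm <- EBImage::distmap(mask)
  dm[!is.finite(dm)] <- max(dim(mask))  # all-foreground image: flat cap
  dms <- separable_convolve(dm, gaussian_kernel_1d(1.0))
  run_declump(mask, elevation_img = dms, seed_img = dms,
              suppression_px = suppression_distance_px)
}

#' Declump a binary mask by intensity maxima
#'
#' Splits touching objects at intensity valleys: local maxima of `img`
#' inside the foreground seed a watershed on the negated intensities.  The
#' method of choice for resolving individual clusters in the raw
#' super-resolved image.
#'
#' @param mask Integer 0/1 matrix.
#' @param img An [sr_image] (or matrix) supplying the intensities.
#' @param suppression_distance_px Minimum seed spacing, pixels.
#' @return Integer label matrix whose positive labels exactly tile the
#'   foreground.
#' @export
declump_intensity <- function(mask, img, suppression_distance_px) {
  img <- as_sr_image(img)
  storage.mode(mask) <- "integer"
  if (!all(dim(img$pixels) == dim(mask)))
    stop_srseg("mask and image dimensions differ", "dimension")
  if (sum(mask) == 0L) return(matrix(0L, nrow(mask), ncol(mask)))
  run_declump(mask, elevation_img = img$pixels, seed_img = img$pixels,
              suppression_px = suppression_distance_px)
}

#' Measure labelled objects
#'
#' @param lm Integer label matrix.
#' @param img An [sr_image] (or matrix) with the intensities to measure
#'   (by convention the ORIGINAL unsmoothed image).
#' @return Data frame with one row per label: `label`, `centroid_row`,
#'   `centroid_col` (0-based pixel coordinates), `area_px`,
#'   `equivalent_diameter_px` (`2*sqrt(area/pi)`), `mean_intensity`,
#'   `max_intensity`.
#' @export
measure_objects <- function(lm, img) {
  img <- as_sr_image(img)
  if (!all(dim(img$pixels) == dim(lm)))
    stop_srseg("label map and image dimensions differ", "dimension")
  idx <- which(lm > 0L)
  if (length(idx) == 0L)
    return(data.frame(label = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area_px = integer(0),
                      equivalent_diameter_px = numeric(0),
                      mean_intensity = numeric(0), max_intensity = numeric(0)))
  lab <- lm[idx]
  rows0 <- (idx - 1L) %% nrow(lm)        # 0-based
  cols0 <- (idx - 1L) %/% nrow(lm)
  vals <- img$pixels[idx]
  area <- tabulate(lab)
  labs <- which(area > 0L)
  f <- factor(lab, levels = labs)  # numeric label order, not lexicographic
  data.frame(
    label = labs,
    centroid_row = as.vector(tapply(rows0, f, mean)),
    centroid_col = as.vector(tapply(cols0, f, mean)),
    area_px = area[labs],
    equivalent_diameter_px = 2 * sqrt(area[labs] / pi),
    mean_intensity = as.vector(tapply(vals, f, mean)),
    max_intensity = as.vector(tapply(vals, f, max)),
    row.names = NULL)
}

#' Filter objects by size and border contact
#'
#' Removes objects whose equivalent diameter falls outside
#' `[min_diameter_px, max_diameter_px]` and, if `discard_border`, objects
#' touching any image edge; survivors are relabelled 1..N preserving raster
#' order of their first pixel.
#'
#' @param lm Integer label matrix.
#' @param params An [segmentation_params()] object.
#' @return Filtered, consecutively relabelled integer label matrix.
#' @export
filter_objects <- function(lm, params) {
  stopifnot(inherits(params, "sr_seg_params"))
  if (max(lm) == 0L) return(lm)
  area <- tabulate(lm[lm > 0L])
  eqd <- 2 * sqrt(area / pi)
  drop <- which(eqd < params$min_diameter_px | eqd > params$max_diameter_px)
  if (params$discard_border) {
    border_labels <- unique(c(lm[1L, ], lm[nrow(lm), ], lm[, 1L], lm[, ncol(lm)]))
    drop <- union(drop, border_labels[border_labels > 0L])
  }
  if (length(drop)) lm[lm %in% drop] <- 0L
  relabel_raster(lm)
}

# Relabel surviving labels 1..N in raster order of each label's first pixel.
relabel_raster <- function(lm) {
  idx <- which(lm > 0L)
  if (length(idx) == 0L) return(lm)
  rows <- (idx - 1L) %% nrow(lm)
  cols <- (idx - 1L) %/% nrow(lm)
  raster <- rows * ncol(lm) + cols
  firsts <- tapply(raster, lm[idx], min)
  old <- as.integer(names(firsts))[order(firsts)]
  map <- integer(max(lm))
  map[old] <- seq_along(old)
  lm[idx] <- map[lm[idx]]
  lm
}

#' Identify primary objects
#'
#' The full single-stage segmentation: optional Gaussian pre-smoothing, MCT
#' thresholding (mask taken on the smoothed image), 8-connected components,
#' declumping per `params` (with `"auto"` suppression resolved to the
#' median equivalent radius of the pre-declump components), size/border
#' filtering, and measurements on the ORIGINAL unsmoothed intensities.
#'
#' @param img An [sr_image] (or matrix).
#' @param params An [segmentation_params()] object.
#' @return A list of class `sr_segmentation`: `labels` (label matrix),
#'   `objects` (measurement data frame), `threshold` (the `sr_threshold`
#'   used), `suppression_distance_px` (resolved value, NA when not
#'   declumped), and `params`.
#' @examples
#' set.seed(1)
#' img <- matrix(5, 64, 64)
#' img[20:25, 20:25] <- 200; img[40:46, 50:56] <- 150
#' seg <- identify_primary_objects(sr_image(img),
#'   segmentation_params(declump_method = "none", min_diameter_px = 3,
#'                       max_diameter_px = 20))
#' nrow(seg$objects)  # 2
#' @export
identify_primary_objects <- function(img, params = segmentation_params()) {
  img <- as_sr_image(img)
  stopifnot(inherits(params, "sr_seg_params"))
  th <- mct_threshold(img, params$threshold_pre_smooth_px)
  mask <- apply_threshold(th$smoothed, th$threshold)
  pre <- connected_components(mask)
  supp <- NA_real_
  if (params$declump_method != "none" && max(pre) > 0L) {
    supp <- if (identical(params$suppression_distance_px, "auto"))
      median_equivalent_radius(pre) else params$suppression_distance_px
    lm <- switch(params$declump_method,
                 shape = declump_shape(mask, supp),
                 intensity = declump_intensity(mask, img, supp))
  } else {
    lm <- pre
  }
  lm <- filter_objects(lm, params)
  structure(list(labels = lm,
                 objects = measure_objects(lm, img),
                 threshold = th,
                 suppression_distance_px = supp,
                 params = params),
            class = "sr_segmentation")
}

#' @export
print.sr_segmentation <- function(x, ...) {
  cat(sprintf("<sr_segmentation> %d objects (threshold %g, declump %s%s)\n",
              nrow(x$objects), x$threshold$threshold, x$params$declump_method,
              if (is.na(x$suppression_distance_px)) "" else
                sprintf(", suppression %.2f px", x$suppression_distance_px)))
  invisible(x)
}
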