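# Preprocessing and fusion filters.
#
# The central trick of the whole procedure lives here: convolving a
# super-resolved image with a Gaussian wide enough to span the gaps between
# nanoscopic clusters merges those clusters into one connected parent object
# (a nuclear-pore "donut", an active zone), in effect walking the resolution
# back toward the diffraction limit in a controlled way.  The filter width
# is parameterized as an "artifact diameter": the full width (FWHM) of the
# features to be fused.

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))  # 1/2.3548...

#' Convert an artifact diameter (FWHM, px) to a Gaussian sigma
#' @param diameter_px Positive feature width in pixels.
#' @return Sigma in pixels.
#' @export
fwhm_to_sigma <- function(diameter_px) diameter_px * FWHM_TO_SIGMA

# 1D convolution of each matrix column with a symmetric kernel under
# half-sample symmetric ("reflect") extension: edge pixel duplicated,
# abc -> cba|abc|cba.  This extension makes a normalized symmetric kernel
# preserve both constants and the total sum exactly.
convolve_cols <- function(m, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  n <- nrow(m)
  if (r == 0L) return(m * kernel)
  # fold an arbitrary (possibly out-of-range) index back into 1..n by
  # repeated half-sample reflection (period 2n)
  reflect <- function(i) {
    j <- (i - 1L) %% (2L * n)
    ifelse(j < n, j + 1L, 2L * n - j)
  }
  ext <- m[reflect(seq.int(1L - r, n + r)), , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (k in seq_along(kernel))
    out <- out + kernel[k] * ext[(k - 1L) + seq_len(n), , drop = FALSE]
  out
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable symmetric-kernel convolution with reflective boundaries.
separable_convolve <- function(px, kernel) {
  t(convolve_cols(t(convolve_cols(px, kernel)), kernel))
}

#' Gaussian smoothing / cluster fusion
#'
#' Convolves the image with a normalized isotropic 2D Gaussian whose FWHM is
#' `artifact_diameter_px`, with reflective boundary handling.  Two point
#' sources closer than about one artifact diameter fuse into a single
#' intensity maximum; more distant ones remain separate.  Small diameters
#' blur noise ahead of thresholding, large diameters fuse clusters into
#' parent objects.
#'
#' @param img An [sr_image] (or matrix).
#' @param artifact_diameter_px Positive FWHM of the kernel, pixels.
#' @return Smoothed [sr_image]; the spatial mean is preserved and the
#'   intensity range can only contract.
#' @examples
#' imp <- matrix(0, 21, 21); imp[11, 11] <- 1
#' sm <- gaussian_smooth(sr_image(imp), 5)
#' which(sm$pixels == max(sm$pixels))  # peak stays at the impulse
#' @export
gaussian_smooth <- function(img, artifact_diameter_px) {
  img <- as_sr_image(img)
  if (!is.numeric(artifact_diameter_px) || length(artifact_diameter_px) != 1L ||
      !is.finite(artifact_diameter_px) || artifact_diameter_px <= 0)
    stop_srseg("`artifact_diameter_px` must be a positive number", "parameter")
  k <- gaussian_kernel_1d(fwhm_to_sigma(artifact_diameter_px))
  px <- separable_convolve(img$pixels, k)
  px[px < 0] <- 0  # fp dust
  sr_image(px, img$pixel_size_nm, img$name)
}

#' 3x3 mean smoothing
#'
#' Replaces every pixel by the mean of its 3x3 neighbourhood (reflective
#' boundary).  The mildest of the three preprocessing options; retained
#' because on noisy acquisitions it is typically *not* sufficient to stop
#' over-segmentation, which the bandpass comparison demonstrates.
#'
#' @param img An [sr_image] (or matrix).
#' @return Smoothed [sr_image].
#' @export
mean_smooth_3x3 <- function(img) {
  img <- as_sr_image(img)
  px <- separable_convolve(img$pixels, rep(1 / 3, 3L))
  sr_image(px, img$pixel_size_nm, img$name)
}

#' Difference-of-Gaussians bandpass filter
#'
#' Suppresses structure smaller than `small_diameter_px` (single noisy edge
#' pixels) and larger than `large_diameter_px` (uneven background), then
#' shifts the result so its minimum is 0 to keep downstream thresholding's
#' non-negativity invariant.
#'
#' The cutoff diameters follow the frequency-domain convention of the
#' classical FFT bandpass tools: each Gaussian transmits 50\% amplitude for
#' periodic structure exactly at its cutoff size, i.e.
#' `sigma = d * sqrt(ln 2 / 2) / pi ~ 0.187 d`.  This is deliberately much
#' milder than reading the diameters as kernel FWHMs: a "remove structures
#' up to 3 px" setting must suppress single-pixel outliers while leaving
#' clusters only a few pixels wide countable, which an FWHM-3 px kernel
#' would blur past their Rayleigh limit.
#'
#' @param img An [sr_image] (or matrix).
#' @param small_diameter_px,large_diameter_px Band edges,
#'   `0 < small < large`.
#' @return Filtered [sr_image]; a constant input maps to identically zero.
#' @export
bandpass_filter <- function(img, small_diameter_px = 3, large_diameter_px = 40) {
  img <- as_sr_image(img)
  if (!is.numeric(small_diameter_px) || !is.numeric(large_diameter_px) ||
      small_diameter_px <= 0 || large_diameter_px <= small_diameter_px)
    stop_srseg("bandpass requires 0 < small_diameter_px < large_diameter_px",
               "parameter")
  cutoff_sigma <- function(d) d * sqrt(log(2) / 2) / pi
  lo <- separable_convolve(img$pixels, gaussian_kernel_1d(cutoff_sigma(small_diameter_px)))
  hi <- separable_convolve(img$pixels, gaussian_kernel_1d(cutoff_sigma(large_diameter_px)))
  px <- lo - hi
  px <- px - min(px)
  px[px < 0] <- 0
  sr_image(px, img$pixel_size_nm, img$name)
}
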