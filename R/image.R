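#' Single-channel intensity image
#'
#' The universal currency of the pipeline: a 2D grid of non-negative, finite
#' real intensities, optionally annotated with a physical pixel size.  All
#' filtering, thresholding and segmentation operate on this type.  The pixel
#' size is carried for the simulator and for reporting only; segmentation
#' parameters are expressed in pixels throughout.
#'
#' @param pixels Numeric matrix of intensities (rows x cols).  All values
#'   must be finite and >= 0.
#' @param pixel_size_nm Positive scalar, nanometres per pixel, or `NA` if
#'   unknown.
#' @param name Character identifier used in messages and provenance.
#' @return An object of class `sr_image` with fields `pixels`,
#'   `pixel_size_nm` and `name`.
#' @examples
#' img <- sr_image(matrix(runif(64), 8, 8), pixel_size_nm = 15)
#' dim(img$pixels)
#' @export
sr_image <- function(pixels, pixel_size_nm = NA_real_, name = "image") {
  if (is.vector(pixels)) pixels <- matrix(pixels, nrow = 1L)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_srseg("`pixels` must be a numeric matrix", "type")
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop_srseg("image must have both dimensions >= 1", "type")
  if (!all(is.finite(pixels)))
    stop_srseg("image intensities must all be finite", "type")
  if (any(pixels < 0))
    stop_srseg("image intensities must be non-negative", "type")
  if (!is.na(pixel_size_nm) && (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0))
    stop_srseg("`pixel_size_nm` must be a positive number or NA", "type")
  structure(
    list(pixels = pixels, pixel_size_nm = as.numeric(pixel_size_nm),
         name = as.character(name)[1L]),
    class = "sr_image")
}

#' Multi-channel image
#'
#' An ordered set of equally sized [sr_image] channels with unique names,
#' e.g. a two-color STED acquisition with `"red"` = gp210 and `"green"` =
#' pan-FG.
#'
#' @param channels List of [sr_image] objects sharing identical dimensions
#'   and pixel size.
#' @param channel_names Character vector of unique names, one per channel.
#' @return An object of class `sr_multichannel`.
#' @export
sr_multichannel <- function(channels, channel_names) {
  if (!is.list(channels) || length(channels) == 0L)
    stop_srseg("`channels` must be a non-empty list of sr_image objects", "type")
  if (!all(vapply(channels, inherits, logical(1), "sr_image")))
    stop_srseg("all channels must be sr_image objects", "type")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != length(channels))
    stop_srseg("`channel_names` must match the number of channels", "type")
  if (anyDuplicated(channel_names))
    stop_srseg("channel names must be unique", "type")
  dims <- vapply(channels, function(ch) dim(ch$pixels), integer(2))
  if (ncol(dims) > 1L && any(dims[, -1L, drop = FALSE] != dims[, 1L]))
    stop_srseg("all channels must have the same dimensions", "type")
  names(channels) <- channel_names
  structure(list(channels = channels, channel_names = channel_names),
            class = "sr_multichannel")
}

#' @export
print.sr_image <- function(x, ...) {
  cat(sprintf("<sr_image '%s'> %d x %d px, intensity [%g, %g], pixel size %s nm\n",
              x$name, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels),
              ifelse(is.na(x$pixel_size_nm), "unknown", format(x$pixel_size_nm))))
  invisible(x)
}

#' @export
print.sr_multichannel <- function(x, ...) {
  d <- dim(x$channels[[1L]]$pixels)
  cat(sprintf("<sr_multichannel> %d x %d px, channels: %s\n",
              d[1L], d[2L], paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' Extract one channel from a multi-channel image
#'
#' @param img An [sr_multichannel] object.
#' @param name Channel name to extract.
#' @return The requested [sr_image], unchanged.
#' @export
extract_channel <- function(img, name) {
  stopifnot(inherits(img, "sr_multichannel"))
  if (!name %in% img$channel_names)
    stop_srseg(sprintf("unknown channel '%s'; available: %s", name,
                       paste(img$channel_names, collapse = ", ")), "lookup")
  img$channels[[name]]
}

#' Linear intensity rescaling
#'
#' Affine map of the image intensity range onto `[out_min, out_max]`,
#' preserving intensity order.  Used for visualisation only; the analysis
#' pipeline never rescales.
#'
#' @param img An [sr_image].
#' @param out_min,out_max Target range, `out_min < out_max`.
#' @return Rescaled [sr_image].  A constant image maps to constant
#'   `out_min` with a warning (there is no range to stretch).
#' @export
rescale_linear <- function(img, out_min = 0, out_max = 255) {
  img <- as_sr_image(img)
  if (out_min >= out_max)
    stop_srseg("`out_min` must be < `out_max`", "parameter")
  rng <- range(img$pixels)
  if (rng[1L] == rng[2L]) {
    warning("constant image: rescale_linear returns constant out_min")
    px <- matrix(out_min, nrow(img$pixels), ncol(img$pixels))
    # out_min may be 0; sr_image forbids negatives, guard below
  } else {
    px <- (img$pixels - rng[1L]) / (rng[2L] - rng[1L]) * (out_max - out_min) + out_min
  }
  if (any(px < 0)) px[px < 0] <- 0  # fp guard at the lower edge
  sr_image(px, img$pixel_size_nm, img$name)
}

# Accept a bare matrix where an sr_image is expected.
as_sr_image <- function(x, name = "image") {
  if (inherits(x, "sr_image")) return(x)
  sr_image(x, name = name)
}

# Classed conditions so callers can distinguish error families.
stop_srseg <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("srseg_error_", class),
                                     "srseg_error", "error", "condition")))
}
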