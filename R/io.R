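#' Read a TIFF image
#'
#' Reads an 8- or 16-bit grayscale or RGB TIFF into an [sr_multichannel].
#' Grayscale files yield one channel named `"gray"`; RGB files yield three
#' channels named `"red"`, `"green"`, `"blue"` in that fixed order (the
#' pipeline assigns biology to color, e.g. gp210 in red, pan-FG in green).
#' Stored integer sample values are recovered bit-exactly and held as reals.
#'
#' @param path Path to a TIFF file.
#' @param pixel_size_nm Optional physical pixel size to annotate, nm/px.
#' @return An [sr_multichannel].
#' @export
read_image <- function(path, pixel_size_nm = NA_real_) {
  if (!file.exists(path))
    stop_srseg(sprintf("file not found: %s", path), "io")
  raw <- tryCatch(tiff::readTIFF(path, info = TRUE, as.is = TRUE),
                  error = function(e) stop_srseg(
                    sprintf("cannot read TIFF '%s': %s", path, conditionMessage(e)),
                    "format"))
  info <- attributes(raw)
  bits <- info$bits.per.sample
  if (is.null(bits)) bits <- 8L
  if (!bits %in% c(8L, 16L))
    stop_srseg(sprintf("unsupported bit depth %d in '%s' (8 or 16 expected)",
                       bits, path), "format")
  # readTIFF honours as.is only for some layouts (integer matrices come
  # back raw, RGB planes come back [0,1]-normalized); undo the scaling.
  scale_back <- function(x) {
    if (is.integer(x)) x else round(x * (2^bits - 1))
  }
  nm <- basename(path)
  if (length(dim(raw)) == 2L) {
    px <- scale_back(raw)
    px <- matrix(as.double(px), dim(raw)[1L], dim(raw)[2L])  # shed TIFF attrs
    ch <- list(sr_image(px, pixel_size_nm, nm))
    return(sr_multichannel(ch, "gray"))
  }
  if (length(dim(raw)) == 3L && dim(raw)[3L] %in% c(3L, 4L)) {
    chans <- lapply(1:3, function(k) {
      px <- scale_back(raw[, , k])
      storage.mode(px) <- "double"
      sr_image(px, pixel_size_nm, paste0(nm, ":", c("red", "green", "blue")[k]))
    })
    return(sr_multichannel(chans, c("red", "green", "blue")))
  }
  stop_srseg(sprintf("unsupported TIFF layout in '%s': %s samples per pixel",
                     path, paste(dim(raw), collapse = "x")), "format")
}

#' Write an image or label map as TIFF
#'
#' Intensity images are quantized to the requested unsigned bit depth; label
#' maps (integer matrices) are written as 16-bit so up to 65535 labels
#' round-trip exactly.
#'
#' @param img An [sr_image], [sr_multichannel] (written as RGB, 3 channels
#'   required), or integer label matrix.
#' @param path Output path.
#' @param bits 8 or 16 bits per sample (ignored for multichannel, always 8).
#' @return Invisibly, `path`.
#' @export
write_image <- function(img, path, bits = 16L) {
  if (!bits %in% c(8L, 16L))
    stop_srseg("`bits` must be 8 or 16", "parameter")
  maxval <- 2^bits - 1
  ok <- tryCatch({
    if (inherits(img, "sr_multichannel")) {
      if (length(img$channels) != 3L)
        stop_srseg("RGB TIFF output needs exactly 3 channels", "parameter")
      arr <- vapply(img$channels, function(ch) ch$pixels / 255,
                    matrix(0, nrow(img$channels[[1]]$pixels),
                           ncol(img$channels[[1]]$pixels)))
      arr[arr > 1] <- 1
      tiff::writeTIFF(arr, path, bits.per.sample = 8L)
    } else {
      px <- if (inherits(img, "sr_image")) img$pixels else img
      storage.mode(px) <- "double"
      if (max(px) > maxval)
        stop_srseg(sprintf("intensities exceed %d; rescale before writing at %d bit",
                           maxval, bits), "parameter")
      tiff::writeTIFF(px / maxval, path, bits.per.sample = as.integer(bits))
    }
  }, error = function(e) {
    if (inherits(e, "srseg_error")) stop(e)
    stop_srseg(sprintf("cannot write TIFF '%s': %s", path, conditionMessage(e)), "io")
  })
  invisible(path)
}

#' Write a measurement table as CSV
#'
#' Comma-separated, UTF-8, `.` decimal mark, LF line endings, header row,
#' floating point written with >= 6 significant digits.  Accepts any of the
#' package's tables (object tables, relation tables, histograms).
#'
#' @param rows A data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- formatC(out[[j]], digits = 9, format = "g")
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop_srseg(
                    sprintf("cannot open '%s' for writing", path), "io"))
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}
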