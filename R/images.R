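#' RGB field image
#'
#' Container for a 3-channel nadir field image with per-plot metadata. Channel
#' values are reflectance-like floats in `[0, 1]`. The first channel is always
#' treated symbolically as "R" even when the camera substituted near-infrared
#' for the red band (modified-camera setups place the vegetation signal
#' there); all vegetation-index formulas operate on channel symbols, not
#' wavelengths.
#'
#' @param pixels numeric `H x W x 3` array with values in `[0, 1]`.
#' @param plot_id plot identifier (coerced to character).
#' @param date acquisition date (coerced with [as.Date()]).
#' @param path source file path, if any.
#'
#' @return An object of class `rgb_image` with fields `pixels`, `plot_id`,
#'   `date` and `path`.
#' @export
rgb_image <- function(pixels, plot_id = NA_character_, date = NA, path = NA_character_) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    cc_stop("`pixels` must be an H x W x 3 array", "ccpipe_channel_error")
  if (dim(pixels)[3] != 3L)
    cc_stop(sprintf("expected exactly 3 channels, got %d", dim(pixels)[3]),
            "ccpipe_channel_error")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    cc_stop("channel values must be finite and lie in [0, 1]", "ccpipe_value_error")
  structure(list(pixels = pixels,
                 plot_id = as.character(plot_id),
                 date = as.Date(date),
                 path = path),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image %d x %d, plot %s, date %s>\n",
              d[1], d[2], x$plot_id, format(x$date)))
  invisible(x)
}

#' Read a field image from disk
#'
#' Reads a PNG, TIFF or JPEG raster and rescales it to `[0, 1]` floats
#' (8-bit and 16-bit inputs are divided by their level maximum by the
#' underlying readers). Grayscale and 2-channel rasters are rejected; a
#' 4-channel (RGBA) raster is rejected unless `drop_alpha = TRUE` explicitly
#' authorises discarding the alpha plane.
#'
#' @param path file path; the format is chosen by extension
#'   (`.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg`).
#' @param plot_id,date optional metadata attached to the returned image.
#' @param drop_alpha set `TRUE` to accept RGBA input and drop the alpha plane.
#'
#' @return An [rgb_image()].
#' @export
load_image <- function(path, plot_id = NA_character_, date = NA, drop_alpha = FALSE) {
  if (!file.exists(path))
    cc_stop(sprintf("file not found: %s", path), "ccpipe_io_error")
  ext <- tolower(tools::file_ext(path))
  reader <- switch(ext,
    png  = png::readPNG,
    tif  = ,
    tiff = tiff::readTIFF,
    jpg  = ,
    jpeg = jpeg::readJPEG,
    cc_stop(sprintf("unsupported image format '.%s'", ext), "ccpipe_io_error"))
  px <- tryCatch(reader(path),
                 error = function(e) cc_stop(
                   sprintf("failed to decode %s: %s", path, conditionMessage(e)),
                   "ccpipe_io_error"))
  if (is.matrix(px) || (is.array(px) && dim(px)[3] == 1L))
    cc_stop("grayscale input: a 3-channel image is required", "ccpipe_channel_error")
  if (dim(px)[3] == 2L)
    cc_stop("2-channel (gray+alpha) input is not supported", "ccpipe_channel_error")
  if (dim(px)[3] == 4L) {
    if (!isTRUE(drop_alpha))
      cc_stop("4-channel input: pass drop_alpha = TRUE to discard the alpha plane",
              "ccpipe_channel_error")
    px <- px[, , 1:3, drop = FALSE]
  }
  rgb_image(pmin(pmax(px, 0), 1), plot_id = plot_id, date = date, path = path)
}

#' Read an image manifest
#'
#' The manifest is a headered CSV with columns `path`, `plot_id`, `date`
#' (ISO-8601). Relative paths are resolved against the manifest's directory.
#'
#' @param path CSV file path.
#' @return data.frame with columns `path`, `plot_id`, `date` (and any extras).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) cc_stop(sprintf("manifest not found: %s", path), "ccpipe_io_error")
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "plot_id", "date")
  if (!all(need %in% names(m)))
    cc_stop(sprintf("manifest must have columns %s", paste(need, collapse = ", ")),
            "ccpipe_schema_error")
  m$date <- as.Date(m$date)
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}

#' Binary segmentation mask
#'
#' @param values integer/logical `H x W` matrix; nonzero means plant
#'   (foreground).
#' @param provenance free-form list recording the method and parameters that
#'   produced the mask.
#' @return An integer 0/1 matrix of class `binary_mask`.
#' @export
binary_mask <- function(values, provenance = list()) {
  if (!is.matrix(values)) cc_stop("mask must be a matrix", "ccpipe_value_error")
  v <- matrix(as.integer(values != 0), nrow(values), ncol(values))
  if (anyNA(v)) cc_stop("mask contains NA", "ccpipe_value_error")
  structure(v, class = "binary_mask", provenance = provenance)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d, %d plant px (%.1f%%)>\n",
              nrow(x), ncol(x), sum(x), 100 * mean(x)))
  invisible(x)
}

mask_values <- function(m) {
  if (inherits(m, "binary_mask")) unclass(m) else {
    if (!is.matrix(m)) cc_stop("expected a mask matrix", "ccpipe_value_error")
    matrix(as.integer(m != 0), nrow(m), ncol(m))
  }
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask a [binary_mask()] or 0/1 matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask_values(mask) * 1.0, path)
  invisible(path)
}

#' Read a 0/255 (or 0/1) PNG mask
#'
#' Pixels above half intensity are plant.
#'
#' @param path PNG path.
#' @return A [binary_mask()].
#' @export
read_mask_png <- function(path) {
  px <- tryCatch(png::readPNG(path),
                 error = function(e) cc_stop(sprintf("failed to read mask %s", path),
                                             "ccpipe_io_error"))
  if (is.array(px) && length(dim(px)) == 3L) px <- px[, , 1]
  binary_mask(px > 0.5, provenance = list(source = path))
}

#' Write a vegetation-index plane as 32-bit float TIFF
#'
#' Intended for visual inspection of index images in external viewers.
#' Because TIFF storage of values outside `[0, 1]` is undefined in the
#' writer, the plane is min-max rescaled to `[0, 1]` before writing.
#'
#' @param vi a `vi_image` as returned by [compute_index()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_vi_tiff <- function(vi, path) {
  stopifnot(inherits(vi, "vi_image"))
  rng <- range(vi$values)
  v <- if (diff(rng) > 0) (vi$values - rng[1]) / diff(rng) else vi$values * 0
  tiff::writeTIFF(v, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}
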