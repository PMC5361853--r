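#' Canonical per-pixel feature column order
#'
#' The nine colour components (RGB, HSV, CIE Lab) plus the NDI3*V product
#' index, in the fixed order used by every trained pixel model. Models record
#' this order at training time and verify it at prediction time, so feature
#' tables are portable across sessions.
#'
#' @format Character vector of length 10.
#' @export
PIXEL_FEATURES <- c("R", "G", "B", "H", "S", "V", "L", "a", "b", "NDI3V")

#' Convert an image to HSV and CIE Lab colour planes
#'
#' HSV follows the hexcone model with all three planes in `[0, 1]`; Lab is
#' CIE 1976 L*a*b* under the sRGB/D65 convention, with `L` in `[0, 100]` and
#' `a`, `b` signed.
#'
#' @param img an [rgb_image()].
#' @return A list of class `color_planes` with matrices `H`, `S`, `V`, `L`,
#'   `a`, `b`, each the size of the image.
#' @export
to_color_planes <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  d <- dim(img$pixels)
  flat <- matrix(img$pixels, ncol = 3L)          # columns R, G, B
  hsv <- grDevices::rgb2hsv(t(flat), maxColorValue = 1)
  lab <- grDevices::convertColor(flat, from = "sRGB", to = "Lab")
  mk <- function(v) matrix(v, d[1], d[2])
  structure(list(H = mk(hsv[1, ]), S = mk(hsv[2, ]), V = mk(hsv[3, ]),
                 L = mk(lab[, 1]), a = mk(lab[, 2]), b = mk(lab[, 3])),
            class = "color_planes")
}

vi_image <- function(values, vi_name) {
  structure(list(values = values, vi_name = vi_name), class = "vi_image")
}

#' @export
print.vi_image <- function(x, ...) {
  cat(sprintf("<vi_image %s, %d x %d, range [%.3f, %.3f]>\n", x$vi_name,
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Compute a vegetation-index image
#'
#' Applies one of the colour vegetation indices per pixel on `[0, 1]`
#' channels:
#' \describe{
#'   \item{ExR}{`1.4 R - G` (excess red)}
#'   \item{ExB}{`1.4 B - G` (excess blue)}
#'   \item{ExR_minus_ExB}{`ExR - ExB`}
#'   \item{NDI2}{`(R - B) / (R + B)` (two-band normalized difference)}
#'   \item{NDI3}{`(R + G - 2B) / (R + G + 2B)` (three-band normalized
#'     difference)}
#' }
#' Pixels where an NDI denominator is zero (black pixels) map to 0, the
#' background-neutral value.
#'
#' @param img an [rgb_image()].
#' @param vi_name index name, see above.
#' @return A `vi_image` (list with `values` matrix and `vi_name`).
#' @export
compute_vi <- function(img, vi_name) {
  stopifnot(inherits(img, "rgb_image"))
  R <- img$pixels[, , 1]; G <- img$pixels[, , 2]; B <- img$pixels[, , 3]
  safe_ratio <- function(num, den) ifelse(den == 0, 0, num / ifelse(den == 0, 1, den))
  v <- switch(vi_name,
    ExR  = 1.4 * R - G,
    ExB  = 1.4 * B - G,
    ExR_minus_ExB = (1.4 * R - G) - (1.4 * B - G),
    NDI2 = safe_ratio(R - B, R + B),
    NDI3 = safe_ratio(R + G - 2 * B, R + G + 2 * B),
    cc_stop(sprintf("unknown vegetation index '%s'", vi_name), "ccpipe_config_error"))
  vi_image(v, vi_name)
}

#' Compute a product-index image (NDI2*a, NDI3*a, NDI3*V)
#'
#' Element-wise product of an NDI plane with a colour plane that carries
#' brightness (HSV `V`) or green-red opponency (Lab `a`). `V` is used as-is
#' in `[0, 1]`; the signed `a` plane is min-max rescaled per image to
#' `[0, 1]` before multiplying, so the product keeps the sign structure of
#' the NDI and thresholds remain comparable across images. A constant `a`
#' plane (zero range) rescales to all 0.5 with a warning.
#'
#' @param img an [rgb_image()].
#' @param name one of `"NDI2a"`, `"NDI3a"`, `"NDI3V"`.
#' @param planes optional precomputed [to_color_planes()] result.
#' @return A `vi_image`.
#' @export
compute_product_vi <- function(img, name, planes = NULL) {
  stopifnot(inherits(img, "rgb_image"))
  if (!name %in% c("NDI2a", "NDI3a", "NDI3V"))
    cc_stop(sprintf("unknown product index '%s'", name), "ccpipe_config_error")
  base <- compute_vi(img, if (name == "NDI2a") "NDI2" else "NDI3")
  planes <- planes %||% to_color_planes(img)
  other <- if (name == "NDI3V") planes$V else {
    a <- planes$a
    rng <- range(a)
    if (diff(rng) == 0) {
      cc_warn("constant a-plane: rescaling to all 0.5", "ccpipe_degenerate_warning")
      matrix(0.5, nrow(a), ncol(a))
    } else (a - rng[1]) / diff(rng)
  }
  vi_image(base$values * other, name)
}

#' Compute any supported index image by name
#'
#' Dispatches to [compute_vi()] or [compute_product_vi()].
#'
#' @inheritParams compute_product_vi
#' @param name index name: `ExR`, `ExB`, `ExR_minus_ExB`, `NDI2`, `NDI3`,
#'   `NDI2a`, `NDI3a` or `NDI3V`.
#' @return A `vi_image`.
#' @export
compute_index <- function(img, name, planes = NULL) {
  if (name %in% c("NDI2a", "NDI3a", "NDI3V")) compute_product_vi(img, name, planes)
  else compute_vi(img, name)
}

#' Extract the per-pixel feature table
#'
#' Builds the 10-column feature table (`R, G, B, H, S, V, L, a, b, NDI3V`,
#' in this fixed order; see [PIXEL_FEATURES]) used by the supervised pixel
#' classifiers, one row per pixel in column-major order, optionally
#' restricted to a subset of linear pixel indices.
#'
#' @param img an [rgb_image()].
#' @param pixels optional vector of linear (column-major) pixel indices.
#' @return A data.frame with the 10 feature columns.
#' @export
extract_pixel_features <- function(img, pixels = NULL) {
  stopifnot(inherits(img, "rgb_image"))
  cp <- to_color_planes(img)
  ndi3v <- compute_product_vi(img, "NDI3V", planes = cp)
  df <- data.frame(R = as.vector(img$pixels[, , 1]),
                   G = as.vector(img$pixels[, , 2]),
                   B = as.vector(img$pixels[, , 3]),
                   H = as.vector(cp$H), S = as.vector(cp$S), V = as.vector(cp$V),
                   L = as.vector(cp$L), a = as.vector(cp$a), b = as.vector(cp$b),
                   NDI3V = as.vector(ndi3v$values))
  if (!is.null(pixels)) {
    if (any(pixels < 1 | pixels > nrow(df)))
      cc_stop("pixel indices out of bounds", "ccpipe_value_error")
    df <- df[pixels, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}
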