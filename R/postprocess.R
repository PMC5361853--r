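#' Mask clean-up and canopy-cover computation
#'
#' Segmented masks carry salt-and-pepper noise; [denoise_mask()] removes it
#' with a median (majority) filter followed by small-object removal, and
#' [canopy_cover()] turns a clean mask into a plot-wise canopy-cover record.
#'
#' @name postprocess_cc
NULL

# k x k binary majority filter with reflect (symmetric half-sample) padding,
# computed with an integral image. For 0/1 input the median of a k*k window
# is 1 iff the window holds more than k*k/2 ones (k odd, so no ties).
binary_median <- function(m, k) {
  h <- nrow(m); w <- ncol(m); r <- (k - 1L) %/% 2L
  pr <- c(r:1, 1:h, h:(h - r + 1L))
  pc <- c(r:1, 1:w, w:(w - r + 1L))
  P <- m[pr, pc, drop = FALSE]
  I <- matrix(0, nrow(P) + 1L, ncol(P) + 1L)
  I[-1, -1] <- apply(apply(P, 2L, cumsum), 1L, cumsum) |> t()
  S <- I[(k + 1L):(h + k), (k + 1L):(w + k)] -
       I[1:h, (k + 1L):(w + k)] -
       I[(k + 1L):(h + k), 1:w] +
       I[1:h, 1:w]
  matrix(as.integer(2L * S > k * k), h, w)
}

# Label connected foreground components (4- or 8-connectivity) via igraph.
label_components <- function(m, connectivity = 8L) {
  h <- nrow(m); w <- ncol(m)
  fg <- which(m == 1L)
  lab <- integer(length(m))
  if (!length(fg)) return(list(labels = matrix(lab, h, w), sizes = integer(0)))
  id <- integer(length(m)); id[fg] <- seq_along(fg)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  lm <- m == 1L
  edges <- lapply(offs, function(o) {
    dr <- o[1]; dc <- o[2]
    rows <- max(1L, 1L - dr):min(h, h - dr)
    cols <- max(1L, 1L - dc):min(w, w - dc)
    sel <- lm[rows, cols, drop = FALSE] & lm[rows + dr, cols + dc, drop = FALSE]
    s <- which(sel)
    if (!length(s)) return(NULL)
    nr <- length(rows)
    sr <- rows[((s - 1L) %% nr) + 1L]
    sc <- cols[((s - 1L) %/% nr) + 1L]
    cbind(id[(sc - 1L) * h + sr], id[(sc + dc - 1L) * h + sr + dr])
  })
  ed <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(ed)) g <- igraph::add_edges(g, t(ed))
  comp <- igraph::components(g)
  lab[fg] <- comp$membership
  list(labels = matrix(lab, h, w), sizes = as.integer(comp$csize))
}

#' Remove small connected components from a mask
#'
#' Components strictly smaller than `min_object_px` pixels are deleted
#' (a 399-pixel object is removed, a 400-pixel object is retained under the
#' defaults used by [denoise_mask()]).
#'
#' @param mask a [binary_mask()] or 0/1 matrix.
#' @param min_object_px minimum retained component size, in pixels.
#' @param connectivity 4 or 8 (default; diagonal leaf segments stay
#'   connected).
#' @return A [binary_mask()].
#' @export
remove_small_objects <- function(mask, min_object_px = 400L, connectivity = c(8L, 4L)) {
  connectivity <- as.integer(connectivity)[1]
  if (!connectivity %in% c(4L, 8L))
    cc_stop("connectivity must be 4 or 8", "ccpipe_param_error")
  m <- mask_values(mask)
  cc <- label_components(m, connectivity)
  small <- which(cc$sizes < min_object_px)
  m[cc$labels %in% small] <- 0L
  binary_mask(m, provenance = c(attr(mask, "provenance"),
                                list(min_object_px = min_object_px,
                                     connectivity = connectivity)))
}

#' Denoise a segmented mask
#'
#' Applies a median filter (majority vote for binary data; reflect padding
#' at the borders) and then removes connected objects smaller than
#' `min_object_px` pixels, in that order.
#'
#' @param mask a [binary_mask()] or 0/1 matrix.
#' @param median_size odd filter window size (>= 3), default 5 for a 5 x 5
#'   window.
#' @param min_object_px minimum retained object size in pixels; the default
#'   400 suits full-resolution (multi-megapixel) plot images and should be
#'   scaled down for small frames.
#' @param connectivity component connectivity, 4 or 8.
#' @return A [binary_mask()], strictly binary.
#' @export
denoise_mask <- function(mask, median_size = 5L, min_object_px = 400L,
                         connectivity = c(8L, 4L)) {
  if (median_size %% 2L == 0L || median_size < 3L)
    cc_stop("median_size must be an odd integer >= 3", "ccpipe_param_error")
  m <- mask_values(mask)
  med <- binary_median(m, as.integer(median_size))
  out <- remove_small_objects(med, min_object_px, connectivity)
  attr(out, "provenance") <- c(attr(mask, "provenance"),
                               list(median_size = median_size,
                                    min_object_px = min_object_px,
                                    connectivity = as.integer(connectivity)[1]))
  out
}

#' Canopy cover of a mask
#'
#' Canopy cover is the plant-pixel fraction of the mask, optionally
#' restricted to a rectangular region of interest.
#'
#' @param mask a [binary_mask()] or 0/1 matrix.
#' @param roi optional inclusive rectangle `c(row1, row2, col1, col2)`.
#' @param plot_id,date metadata for the record.
#' @param illumination_class optional 1 (LLC) / 2 (HLC) flag.
#' @param method label of the segmentation method that produced the mask.
#' @return One-row data.frame (class `cc_record`) with columns `plot_id`,
#'   `date`, `cc`, `illumination_class`, `n_plant_px`, `n_total_px`,
#'   `method`.
#' @export
canopy_cover <- function(mask, roi = NULL, plot_id = NA_character_, date = NA,
                         illumination_class = NA_integer_, method = NA_character_) {
  m <- mask_values(mask)
  if (!is.null(roi)) {
    if (length(roi) != 4L || any(roi[c(1, 3)] > roi[c(2, 4)]) ||
        roi[1] < 1 || roi[3] < 1 || roi[2] > nrow(m) || roi[4] > ncol(m))
      cc_stop("roi must be c(row1, row2, col1, col2) within the mask and nonempty",
              "ccpipe_param_error")
    m <- m[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  }
  n_total <- length(m)
  n_plant <- sum(m)
  structure(data.frame(plot_id = as.character(plot_id), date = as.Date(date),
                       cc = n_plant / n_total,
                       illumination_class = as.integer(illumination_class),
                       n_plant_px = n_plant, n_total_px = n_total,
                       method = as.character(method),
                       stringsAsFactors = FALSE),
            class = c("cc_record", "data.frame"))
}
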