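#' Segmentation quality factors Qseg, Sr and Es
#'
#' Compares a segmented mask `S` against a reference mask `R` pixel by pixel
#' over the plant class (i = 1), using exact integer counts with division
#' performed last:
#' \describe{
#'   \item{Qseg}{`|S & R| / |S | R|` — intersection over union of the plant
#'     pixels; 1.0 is a perfect segmentation.}
#'   \item{Sr}{`|S & R| / |R|` — fraction of reference plant pixels
#'     recovered (recall).}
#'   \item{Es}{`|S & !R| / |R|` — misclassified plant pixels (true
#'     background labeled plant) relative to true plant pixels; can
#'     exceed 1.}
#' }
#' When both masks are empty the union is empty and Qseg is defined as 1
#' (vacuous perfect agreement). When the reference has no plant pixels the
#' Sr and Es denominators are undefined: they are returned as `NA` with a
#' warning while Qseg is still reported.
#'
#' @param S segmented [binary_mask()] (or 0/1 matrix).
#' @param R reference [binary_mask()] (or 0/1 matrix), same shape.
#' @return A list of class `quality_scores` with fields `qseg`, `sr`, `es`,
#'   `n_ref_plant`, `n_seg_plant`.
#' @export
evaluate_segmentation <- function(S, R) {
  s <- mask_values(S); r <- mask_values(R)
  if (!all(dim(s) == dim(r)))
    cc_stop("segmented and reference masks have different shapes", "ccpipe_value_error")
  sl <- s == 1L; rl <- r == 1L
  inter <- sum(sl & rl)
  uni <- sum(sl | rl)
  n_ref <- sum(rl)
  n_seg <- sum(sl)
  fp <- sum(sl & !rl)
  qseg <- if (uni == 0L) 1 else inter / uni
  if (n_ref == 0L) {
    cc_warn("reference mask has no plant pixels: Sr and Es are undefined (NA)",
            "ccpipe_degenerate_warning")
    sr <- NA_real_; es <- NA_real_
  } else {
    sr <- inter / n_ref
    es <- fp / n_ref
  }
  structure(list(qseg = qseg, sr = sr, es = es,
                 n_ref_plant = n_ref, n_seg_plant = n_seg),
            class = "quality_scores")
}

#' @export
print.quality_scores <- function(x, ...) {
  cat(sprintf("<quality_scores Qseg = %.4f, Sr = %.4f, Es = %.4f>\n",
              x$qseg, x$sr, x$es))
  invisible(x)
}
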