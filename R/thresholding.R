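#' Automated global thresholding of vegetation-index images
#'
#' Two automated methods are provided: [murow_threshold()], which exploits the
#' periodic row structure of row-crop canopies, and [otsu_threshold()], the
#' classical between-class-variance maximiser.
#'
#' @name thresholding
NULL

threshold_result <- function(threshold, method, ...) {
  structure(c(list(threshold = threshold, method = method), list(...)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result %s: t = %.5f", x$method, x$threshold))
  if (!is.null(x$peaks)) cat(sprintf(", %d peaks", length(x$peaks)))
  cat(">\n")
  invisible(x)
}

# Local maxima of `x` subject to a minimum prominence and minimum spacing.
# Prominence of a peak = height minus the higher of the two deepest valleys
# separating it from higher terrain (or the profile end) on each side.
# Spacing is enforced greedily from the highest peak down.
find_profile_peaks <- function(x, min_spacing = 1, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  # include plateau-start maxima missed by the strict right inequality
  cand2 <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- sort(unique(c(cand, cand2)))
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    lmin <- x[i]; j <- i
    while (j > 1L && x[j - 1L] <= x[i]) { j <- j - 1L; lmin <- min(lmin, x[j]) }
    rmin <- x[i]; j <- i
    while (j < n && x[j + 1L] <= x[i]) { j <- j + 1L; rmin <- min(rmin, x[j]) }
    x[i] - max(lmin, rmin)
  }, numeric(1))
  cand <- cand[prom >= min_prominence]
  if (!length(cand)) return(integer(0))
  keep <- integer(0)
  for (i in cand[order(-x[cand])]) {
    if (!length(keep) || all(abs(keep - i) >= min_spacing)) keep <- c(keep, i)
  }
  sort(keep)
}

murow_profile <- function(values, axis) {
  # "vertical_rows": crop rows run vertically in the frame, so the profile is
  # indexed by image column and each value averages the full image height.
  if (axis == "vertical_rows") colMeans(values) else rowMeans(values)
}

murow_one_axis <- function(values, axis, min_row_spacing_px, smooth_strength) {
  p <- murow_profile(values, axis)
  n <- length(p)
  if (n < 2L * min_row_spacing_px)
    cc_stop("profile too short for the requested row spacing", "ccpipe_value_error")
  # a (numerically) flat profile has no row structure; the epsilon guards
  # against machine-precision wiggle in the spline fit of a constant profile
  if (diff(range(p)) < 1e-8)
    return(list(axis = axis, profile = p, smoothed = p,
                peaks = integer(0), troughs = integer(0)))
  sm <- tryCatch(fitted(smooth.spline(seq_len(n), p, spar = smooth_strength)),
                 error = function(e) p)
  prom <- 0.1 * diff(range(sm))
  peaks <- find_profile_peaks(sm, min_spacing = min_row_spacing_px,
                              min_prominence = prom)
  troughs <- find_profile_peaks(-sm, min_spacing = min_row_spacing_px,
                                min_prominence = prom)
  list(axis = axis, profile = p, smoothed = sm, peaks = peaks, troughs = troughs)
}

#' Row-means (muRow) automated threshold
#'
#' Row crops produce a periodic intensity pattern in vegetation-index images:
#' averaging the index across the image axis parallel to the crop rows gives
#' a profile whose peaks sit on the plant rows and whose troughs sit on the
#' inter-row soil. The profile is smoothed with a spline, peaks (and troughs,
#' reported for diagnostics) are detected subject to a minimum spacing and a
#' prominence floor of 10% of the profile range, and the threshold is the
#' arithmetic mean of the smoothed profile values at the detected peaks.
#'
#' With `row_axis = "auto"` both orientations are profiled and the one with
#' the more regular peak spacing (lower coefficient of variation of
#' inter-peak distances) is kept.
#'
#' Images without detectable row structure (e.g. bare soil shortly after
#' germination) raise a classed `ccpipe_no_rows` error so callers can fall
#' back to [otsu_threshold()].
#'
#' @param vi a `vi_image` (see [compute_index()]).
#' @param row_axis `"auto"`, `"vertical_rows"` (profile over columns) or
#'   `"horizontal_rows"` (profile over rows).
#' @param min_row_spacing_px minimum distance between detected peaks, in
#'   pixels.
#' @param smooth_strength smoothing-spline `spar` in `(0, 1]`; the default
#'   tracks row bumps at typical row spacings.
#' @return A `threshold_result` with fields `threshold`, `method`, `axis`,
#'   `profile`, `smoothed_profile`, `peaks`, `troughs`, `peak_values`.
#' @export
murow_threshold <- function(vi, row_axis = c("auto", "vertical_rows", "horizontal_rows"),
                            min_row_spacing_px = 8L, smooth_strength = 0.3) {
  stopifnot(inherits(vi, "vi_image"))
  row_axis <- match.arg(row_axis)
  axes <- if (row_axis == "auto") c("vertical_rows", "horizontal_rows") else row_axis
  fits <- lapply(axes, function(a)
    murow_one_axis(vi$values, a, min_row_spacing_px, smooth_strength))
  fits <- Filter(function(f) length(f$peaks) >= 1L, fits)
  if (!length(fits))
    cc_stop("no plant rows detected in the index profile (flat or structureless image)",
            "ccpipe_no_rows")
  if (length(fits) > 1L) {
    # the along-row axis shows one prominent peak per crop row, the cross
    # axis only a few accidental bumps: prefer the axis with more detected
    # peaks, breaking ties by the more regular (lower-CV) peak spacing
    np <- vapply(fits, function(f) length(f$peaks), integer(1))
    cv <- vapply(fits, function(f) {
      if (length(f$peaks) < 3L) return(Inf)
      d <- diff(f$peaks); sd(d) / mean(d)
    }, numeric(1))
    fits <- fits[order(-np, cv)]
  }
  f <- fits[[1L]]
  pv <- f$smoothed[f$peaks]
  threshold_result(mean(pv), "murow", axis = f$axis, profile = f$profile,
                   smoothed_profile = f$smoothed, peaks = f$peaks,
                   troughs = f$troughs, peak_values = pv)
}

#' Otsu's automated threshold
#'
#' Histograms the index values into `n_bins` equal-width bins over
#' `[min, max]` and returns the bin edge maximising the between-class
#' variance; among ties the lowest threshold is returned.
#'
#' @param vi a `vi_image`.
#' @param n_bins number of histogram bins.
#' @return A `threshold_result` with fields `threshold`, `method`,
#'   `criterion` (between-class variance per candidate edge) and `edges`.
#' @export
otsu_threshold <- function(vi, n_bins = 256L) {
  stopifnot(inherits(vi, "vi_image"))
  v <- as.vector(vi$values)
  rng <- range(v)
  if (diff(rng) == 0)
    cc_stop("constant index image: no separable classes", "ccpipe_degenerate")
  bin <- pmin(floor((v - rng[1]) / diff(rng) * n_bins) + 1L, n_bins)
  p <- tabulate(bin, n_bins) / length(v)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  k <- seq_len(n_bins - 1L)
  denom <- omega[k] * (1 - omega[k])
  crit <- ifelse(denom > 0, (mu_t * omega[k] - mu[k])^2 / ifelse(denom > 0, denom, 1), -Inf)
  kstar <- which.max(crit)   # first (lowest) maximiser
  edges <- rng[1] + k * diff(rng) / n_bins
  threshold_result(edges[kstar], "otsu", criterion = crit, edges = edges)
}

#' Threshold an index image into a binary mask
#'
#' Foreground (plant) is `vi > t`, strictly.
#'
#' @param vi a `vi_image`.
#' @param t finite threshold.
#' @return A [binary_mask()].
#' @export
apply_threshold <- function(vi, t) {
  stopifnot(inherits(vi, "vi_image"))
  if (!is_scalar_number(t)) cc_stop("threshold must be a finite number", "ccpipe_value_error")
  binary_mask(vi$values > t,
              provenance = list(method = "threshold", vi = vi$vi_name, t = t))
}
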