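#' Exploratory quality control of canopy-cover time series
#'
#' Under normal canopy development, the plot-wise canopy-cover vector of one
#' measurement date correlates strongly with that of any nearby date: the
#' ranking of plots changes slowly. A date whose segmentation went wrong
#' (e.g. extreme illumination) breaks this pattern, showing low correlation
#' with both chronological neighbours. [build_cc_matrix()] arranges records
#' into a plot-by-date matrix, [date_correlation_matrix()] computes the
#' between-date correlation matrix, and [flag_outlier_dates()] reports
#' suspicious dates.
#'
#' @name timeseries_eda
NULL

#' Arrange canopy-cover records into a plot-by-date matrix
#'
#' @param records data.frame with columns `plot_id`, `date`, `cc` (e.g.
#'   rbind-ed [canopy_cover()] records).
#' @return A `cc_matrix`: list with `values` (plots x dates, `NA` where a
#'   combination is missing), `plot_ids`, and `dates` sorted ascending.
#' @export
build_cc_matrix <- function(records) {
  need <- c("plot_id", "date", "cc")
  if (!all(need %in% names(records)))
    cc_stop("records need columns plot_id, date, cc", "ccpipe_schema_error")
  records$date <- as.Date(records$date)
  key <- paste(records$plot_id, records$date)
  if (anyDuplicated(key))
    cc_stop("duplicate (plot_id, date) records", "ccpipe_data_error")
  plots <- sort(unique(records$plot_id))
  dates <- sort(unique(records$date))
  m <- matrix(NA_real_, length(plots), length(dates),
              dimnames = list(plots, format(dates)))
  m[cbind(match(records$plot_id, plots), match(records$date, dates))] <- records$cc
  structure(list(values = m, plot_ids = plots, dates = dates), class = "cc_matrix")
}

#' Between-date correlation matrix of canopy cover
#'
#' Pearson (default) correlation of the plot-wise canopy-cover vectors for
#' every pair of dates, over pairwise-complete plots. A date pair with fewer
#' than `min_pairs` complete plot pairs yields `NA` with a warning.
#'
#' @param m a [build_cc_matrix()] result.
#' @param method `"pearson"` (the conventional r) or `"spearman"`.
#' @param min_pairs minimum number of complete plot pairs per date pair.
#' @return A `corr_matrix`: list with symmetric `values` (dates x dates,
#'   unit diagonal) and `dates`.
#' @export
date_correlation_matrix <- function(m, method = c("pearson", "spearman"),
                                    min_pairs = 3L) {
  stopifnot(inherits(m, "cc_matrix"))
  method <- match.arg(method)
  v <- m$values
  nd <- ncol(v)
  if (nd < 2L || nrow(v) < 2L)
    cc_stop("need at least 2 dates and 2 plots for correlation", "ccpipe_value_error")
  C <- diag(1, nd)
  dimnames(C) <- list(colnames(v), colnames(v))
  n_low <- 0L
  for (i in seq_len(nd - 1L)) for (j in (i + 1L):nd) {
    ok <- !is.na(v[, i]) & !is.na(v[, j])
    if (sum(ok) < min_pairs) {
      C[i, j] <- C[j, i] <- NA_real_
      n_low <- n_low + 1L
    } else {
      r <- suppressWarnings(cor(v[ok, i], v[ok, j], method = method))
      C[i, j] <- C[j, i] <- r
    }
  }
  if (n_low > 0L)
    cc_warn(sprintf("%d date pair(s) had fewer than %d complete plot pairs (NA)",
                    n_low, min_pairs), "ccpipe_sparse_warning")
  structure(list(values = C, dates = m$dates, method = method), class = "corr_matrix")
}

#' Flag measurement dates inconsistent with their neighbours
#'
#' A date is flagged when its canopy-cover correlation with BOTH
#' chronological neighbours (the single neighbour, for the first and last
#' date) falls below `r_min`. Requiring both neighbours distinguishes one
#' bad imaging day from a genuine growth change, which affects a period
#' rather than a single date. `NA` neighbour correlations are treated as
#' uninformative (not low).
#'
#' @param c a [date_correlation_matrix()] result.
#' @param r_min flagging threshold on the neighbour correlations.
#' @return data.frame of flagged dates with columns `date`, `r_prev`,
#'   `r_next` (NA where no such neighbour exists); zero rows when nothing
#'   is flagged. With fewer than 3 dates an empty result is returned with a
#'   warning.
#' @export
flag_outlier_dates <- function(c, r_min = 0.5) {
  stopifnot(inherits(c, "corr_matrix"))
  empty <- data.frame(date = as.Date(character(0)),
                      r_prev = numeric(0), r_next = numeric(0))
  nd <- length(c$dates)
  if (nd < 3L) {
    cc_warn("fewer than 3 dates: not enough context to flag outlier dates",
            "ccpipe_sparse_warning")
    return(empty)
  }
  out <- empty
  for (i in seq_len(nd)) {
    r_prev <- if (i > 1L) c$values[i, i - 1L] else NA_real_
    r_next <- if (i < nd) c$values[i, i + 1L] else NA_real_
    rs <- c(r_prev, r_next)[!is.na(c(r_prev, r_next))]
    if (length(rs) && all(rs < r_min))
      out <- rbind(out, data.frame(date = c$dates[i], r_prev = r_prev, r_next = r_next))
  }
  rownames(out) <- NULL
  out
}
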