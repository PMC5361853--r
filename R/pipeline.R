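#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()], covering the three
#' pipeline steps: image conversion (index choice), segmentation (method and
#' models), and post-processing / EDA.
#'
#' @param method segmentation method: `"otsu"`, `"murow"`, `"kmeans"` or
#'   `"ml"` (scenario-routed supervised models).
#' @param vi index used by the thresholding methods (see [compute_index()]).
#' @param illum_model optional trained [train_illumination_model()] (or path
#'   to a saved one); required for `method = "ml"`, optional otherwise (the
#'   class is then only recorded in the output).
#' @param bank [model_bank()] of segmentation models; required for
#'   `method = "ml"`.
#' @param median_size,min_object_px,connectivity [denoise_mask()]
#'   parameters. `min_object_px` should be scaled to the frame size (400 px
#'   suits multi-megapixel plot images).
#' @param murow_fallback_otsu when the muRow profile finds no rows (classed
#'   `ccpipe_no_rows` error), fall back to Otsu instead of failing the
#'   image.
#' @param r_min EDA flagging threshold (see [flag_outlier_dates()]).
#' @param seed seed for stochastic segmenters (k-means).
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(method = c("otsu", "murow", "kmeans", "ml"),
                            vi = "NDI3V", illum_model = NULL, bank = NULL,
                            median_size = 5L, min_object_px = 400L,
                            connectivity = 8L, murow_fallback_otsu = TRUE,
                            r_min = 0.5, seed = 1L) {
  method <- match.arg(method)
  if (is.character(illum_model)) illum_model <- load_illumination_model(illum_model)
  if (method == "ml") {
    if (is.null(bank) || !inherits(bank, "model_bank"))
      cc_stop("method 'ml' requires a model_bank", "ccpipe_config_error")
    if (is.null(illum_model) && (is.null(bank$LLC) || is.null(bank$HLC)) &&
        is.null(bank$ALC))
      cc_stop("method 'ml' without an illumination model requires an ALC model",
              "ccpipe_config_error")
  }
  if (!is.null(illum_model) && !inherits(illum_model, "illumination_model"))
    cc_stop("illum_model must be an illumination_model (or a path to one)",
            "ccpipe_config_error")
  structure(list(method = method, vi = vi, illum_model = illum_model, bank = bank,
                 median_size = as.integer(median_size),
                 min_object_px = as.integer(min_object_px),
                 connectivity = as.integer(connectivity),
                 murow_fallback_otsu = isTRUE(murow_fallback_otsu),
                 r_min = r_min, seed = as.integer(seed)),
            class = "pipeline_config")
}

segment_one <- function(config, img) {
  cls <- NA_integer_
  if (!is.null(config$illum_model))
    cls <- classify_illumination(config$illum_model, img)
  mask <- switch(config$method,
    otsu = {
      vi <- compute_index(img, config$vi)
      apply_threshold(vi, otsu_threshold(vi)$threshold)
    },
    murow = {
      vi <- compute_index(img, config$vi)
      t <- tryCatch(murow_threshold(vi)$threshold,
                    ccpipe_no_rows = function(e) {
                      if (!config$murow_fallback_otsu) stop(e)
                      otsu_threshold(vi)$threshold
                    })
      apply_threshold(vi, t)
    },
    kmeans = segment_kmeans(img, seed = config$seed),
    ml = {
      model <- if (!is.na(cls)) route_scenario(config$bank, cls)
               else config$bank$ALC
      segment_supervised(model, img)
    })
  list(mask = mask, cls = cls)
}

#' Run the full image-analysis pipeline over a manifest
#'
#' For each image: (1) conversion to the configured index / feature space,
#' with optional illumination classification; (2) segmentation by the
#' configured method; (3) mask denoising and canopy-cover extraction.
#' Afterwards the canopy-cover records are arranged plot-by-date and
#' screened with the between-date correlation EDA. A failing image is
#' logged and skipped; the batch aborts only if every image fails.
#'
#' @param config a [pipeline_config()].
#' @param manifest data.frame with columns `path`, `plot_id`, `date`, or the
#'   path of such a CSV (see [read_manifest()]).
#' @param out_dir optional output directory; when given, writes
#'   `<stem>_mask.png` per image, `cc.csv`, `corr.csv`, `flags.csv` and
#'   `run.log`.
#' @return List with `records` (canopy-cover data.frame), `corr`
#'   (`corr_matrix` or `NULL`), `flags` (data.frame), and `log` (per-image
#'   status data.frame).
#' @export
run_pipeline <- function(config, manifest, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (!is.data.frame(manifest) || nrow(manifest) == 0L)
    cc_stop("manifest is empty", "ccpipe_value_error")
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- list()
  log <- data.frame(path = manifest$path, status = "ok", message = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      img <- load_image(row$path, plot_id = row$plot_id, date = row$date)
      seg <- segment_one(config, img)
      mask <- denoise_mask(seg$mask, median_size = config$median_size,
                           min_object_px = config$min_object_px,
                           connectivity = config$connectivity)
      if (!is.null(out_dir)) {
        stem <- tools::file_path_sans_ext(basename(row$path))
        write_mask_png(mask, file.path(out_dir, paste0(stem, "_mask.png")))
      }
      canopy_cover(mask, plot_id = row$plot_id, date = row$date,
                   illumination_class = seg$cls, method = config$method)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      log$status[i] <- "failed"
      log$message[i] <- conditionMessage(res)
    } else {
      records[[length(records) + 1L]] <- res
    }
  }
  if (!length(records))
    cc_stop("all images failed; see the run log", "ccpipe_batch_error")
  records <- do.call(rbind, records)
  corr <- NULL
  flags <- data.frame(date = as.Date(character(0)),
                      r_prev = numeric(0), r_next = numeric(0))
  if (length(unique(records$date)) >= 2L && length(unique(records$plot_id)) >= 2L) {
    ccm <- build_cc_matrix(records)
    corr <- suppressWarnings(date_correlation_matrix(ccm, min_pairs = 3L))
    flags <- suppressWarnings(flag_outlier_dates(corr, r_min = config$r_min))
  }
  if (!is.null(out_dir)) {
    write.csv(records, file.path(out_dir, "cc.csv"), row.names = FALSE)
    if (!is.null(corr))
      write.csv(data.frame(date = format(corr$dates), corr$values,
                           check.names = FALSE),
                file.path(out_dir, "corr.csv"), row.names = FALSE)
    write.csv(flags, file.path(out_dir, "flags.csv"), row.names = FALSE)
    write.csv(log, file.path(out_dir, "run.log"), row.names = FALSE)
  }
  list(records = records, corr = corr, flags = flags, log = log)
}
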