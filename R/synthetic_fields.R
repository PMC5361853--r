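#' Synthetic row-crop field scenes with ground truth
#'
#' Generates nadir images of a row crop with a known plant mask, emulating
#' the imaging conditions of canopy-cover phenotyping with an NIR-modified
#' camera: plants are bright in the first ("R") channel and dark in blue,
#' soil is a desaturated brown. Two illumination scenarios are emulated:
#' LLC (low light contrast; uniform illumination, all scene detail captured)
#' and HLC (high light contrast; a multiplicative illumination field with
#' saturated bright patches and deep shadows). The ground-truth mask is
#' frozen before the illumination field is applied, so HLC saturation
#' creates genuine segmentation difficulty without corrupting the truth.
#'
#' @name synthetic_fields
NULL

#' Generate one synthetic field scene
#'
#' Plant pixels are placed as jittered elliptical leaf blobs along
#' `row_count` vertical crop rows until the plant fraction is within
#' `cc_tol` of `cc_target`. Plant colour: first channel mean 0.75, green
#' 0.55, blue 0.15; soil: (0.45, 0.40, 0.35); Gaussian pixel noise sd 0.03.
#' HLC scenes apply bright patches (gain 2.5, clipped at 1.0; at least 5%
#' of pixels saturate) and shadow patches (gain 0.25).
#'
#' @param scenario `"LLC"` or `"HLC"`.
#' @param row_count number of crop rows (>= 1).
#' @param cc_target target plant fraction in `[0, 0.95]`.
#' @param size image size `c(H, W)` in pixels.
#' @param seed RNG seed; scenes are bit-reproducible for a fixed seed.
#' @param cc_tol tolerance on the realised plant fraction.
#' @param plot_id,date metadata forwarded to the embedded [rgb_image()].
#' @return A `field_scene`: list with `image` ([rgb_image()]), `truth`
#'   ([binary_mask()]), `scenario`, `row_count`, `cc_true`, `seed`.
#' @export
generate_field_image <- function(scenario = c("LLC", "HLC"), row_count = 8L,
                                 cc_target = 0.25, size = c(120L, 180L),
                                 seed = 1L, cc_tol = 0.02,
                                 plot_id = NA_character_, date = NA) {
  scenario <- match.arg(scenario)
  if (row_count < 1L) cc_stop("row_count must be >= 1", "ccpipe_param_error")
  if (cc_target < 0 || cc_target > 0.95)
    cc_stop("cc_target must lie in [0, 0.95]", "ccpipe_param_error")
  H <- as.integer(size[1]); W <- as.integer(size[2])
  with_seed(seed, {
    truth <- matrix(0L, H, W)
    if (cc_target > 0) {
      centers <- (seq_len(row_count) - 0.5) * W / row_count
      jitter_sd <- W / (row_count * 6)
      n_px <- H * W
      # leaf-blob radius scales down on small frames so one blob cannot
      # overshoot the cc tolerance
      rmax <- max(2.5, min(5, min(H, W) / 12))
      it <- 0L
      while (sum(truth) / n_px < cc_target) {
        it <- it + 1L
        if (it > 50000L)
          cc_stop("cc_target infeasible for the scene geometry", "ccpipe_generation_error")
        cx <- centers[sample.int(row_count, 1L)] + rnorm(1L, sd = jitter_sd)
        cy <- runif(1L, 1, H)
        rad <- runif(1L, 2, rmax)
        rlo <- max(1L, floor(cy - rad)); rhi <- min(H, ceiling(cy + rad))
        clo <- max(1L, floor(cx - rad)); chi <- min(W, ceiling(cx + rad))
        if (rhi < rlo || chi < clo) next
        rr <- rlo:rhi; cc_ <- clo:chi
        d2 <- outer((rr - cy)^2, (cc_ - cx)^2, "+")
        truth[rr, cc_][d2 <= rad^2] <- 1L
      }
      if (abs(sum(truth) / n_px - cc_target) > cc_tol)
        cc_stop("generated plant fraction missed cc_target beyond tolerance",
                "ccpipe_generation_error")
    }
    plant_mean <- c(0.75, 0.55, 0.15)
    soil_mean <- c(0.45, 0.40, 0.35)
    base <- array(0, c(H, W, 3L))
    for (ch in 1:3) {
      base[, , ch] <- ifelse(truth == 1L, plant_mean[ch], soil_mean[ch]) +
        rnorm(H * W, sd = 0.03)
    }
    gain <- matrix(1, H, W)
    if (scenario == "HLC") {
      add_patch <- function(gain, value, rad_frac) {
        cy <- runif(1L, 1, H); cx <- runif(1L, 1, W)
        rad <- runif(1L, rad_frac[1], rad_frac[2]) * min(H, W)
        rr <- max(1L, floor(cy - rad)):min(H, ceiling(cy + rad))
        cc_ <- max(1L, floor(cx - rad)):min(W, ceiling(cx + rad))
        d2 <- outer((rr - cy)^2, (cc_ - cx)^2, "+")
        gain[rr, cc_][d2 <= rad^2] <- value
        gain
      }  # patch centres lie inside the frame, so these ranges are valid
      for (i in 1:3) gain <- add_patch(gain, 2.5, c(0.12, 0.20))
      for (i in 1:2) gain <- add_patch(gain, 0.25, c(0.10, 0.16))
      # guarantee the defining HLC property: >= 5% saturated pixels
      it <- 0L
      repeat {
        lit <- base * as.vector(gain)
        sat <- mean(pmax(lit[, , 1], lit[, , 2], lit[, , 3]) >= 1)
        if (sat >= 0.05 || it >= 20L) break
        gain <- add_patch(gain, 2.5, c(0.12, 0.20))
        it <- it + 1L
      }
    }
    px <- base * as.vector(gain)
    px <- pmin(pmax(px, 0), 1)
    structure(list(image = rgb_image(px, plot_id = plot_id, date = date),
                   truth = binary_mask(truth, provenance = list(method = "synthetic")),
                   scenario = scenario, row_count = row_count,
                   cc_true = mean(truth), seed = seed),
              class = "field_scene")
  })
}

#' @export
print.field_scene <- function(x, ...) {
  cat(sprintf("<field_scene %s, %d rows, cc_true = %.3f, seed %d>\n",
              x$scenario, x$row_count, x$cc_true, x$seed))
  invisible(x)
}

#' Specify a synthetic canopy-cover time series
#'
#' Per-plot canopy cover follows a logistic growth curve
#' `cc(t) = cc_max / (1 + exp(-rate * (t - t0)))`, non-decreasing within the
#' season. Each date carries one illumination scenario.
#'
#' @param n_plots number of plots.
#' @param dates measurement dates (coerced with [as.Date()]).
#' @param cc_max per-plot asymptotic cover (recycled; capped at 0.95 when
#'   realised).
#' @param t0 per-plot inflection date (recycled).
#' @param rate per-plot logistic rate in 1/day (recycled).
#' @param scenario per-date scenario `"LLC"`/`"HLC"` (recycled).
#' @param size,row_count forwarded to [generate_field_image()].
#' @param seed master seed; per-scene seeds are derived from it.
#' @return A `series_spec` list.
#' @export
series_spec <- function(n_plots = 6L, dates = as.Date("2014-11-07") + seq(0, 150, by = 30),
                        cc_max = seq(0.45, 0.9, length.out = n_plots),
                        t0 = as.Date("2015-01-15"), rate = 0.04,
                        scenario = "LLC", size = c(96L, 144L), row_count = 6L,
                        seed = 1L) {
  dates <- sort(as.Date(dates))
  spec <- list(n_plots = as.integer(n_plots), dates = dates,
               cc_max = rep_len(cc_max, n_plots),
               t0 = rep_len(as.Date(t0), n_plots),
               rate = rep_len(rate, n_plots),
               scenario = rep_len(scenario, length(dates)),
               size = size, row_count = as.integer(row_count),
               seed = as.integer(seed))
  if (!all(spec$scenario %in% c("LLC", "HLC")))
    cc_stop("scenario entries must be LLC or HLC", "ccpipe_param_error")
  if (any(!is.finite(spec$cc_max)) || any(!is.finite(spec$rate)))
    cc_stop("growth parameters must be finite", "ccpipe_param_error")
  structure(spec, class = "series_spec")
}

#' Generate a full synthetic image series
#'
#' @param spec a [series_spec()].
#' @return List with `scenes` (list of `field_scene`s, one per plot x date)
#'   and `truth` (data.frame `plot_id`, `date`, `scenario`, `cc_curve` from
#'   the logistic curve, `cc_true` realised in the mask).
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "series_spec"))
  np <- spec$n_plots; nd <- length(spec$dates)
  seeds <- with_seed(spec$seed, sample.int(.Machine$integer.max - 1L, np * nd))
  scenes <- vector("list", np * nd)
  truth <- data.frame(plot_id = character(np * nd), date = as.Date(rep(NA, np * nd)),
                      scenario = character(np * nd), cc_curve = numeric(np * nd),
                      cc_true = numeric(np * nd), stringsAsFactors = FALSE)
  k <- 0L
  for (p in seq_len(np)) for (d in seq_len(nd)) {
    k <- k + 1L
    dt <- as.numeric(spec$dates[d]) - as.numeric(spec$t0[p])
    cc <- min(spec$cc_max[p] / (1 + exp(-spec$rate[p] * dt)), 0.95)
    pid <- sprintf("plot%03d", p)
    sc <- generate_field_image(spec$scenario[d], row_count = spec$row_count,
                               cc_target = cc, size = spec$size,
                               seed = seeds[k], plot_id = pid,
                               date = spec$dates[d])
    scenes[[k]] <- sc
    truth[k, ] <- list(pid, spec$dates[d], spec$scenario[d], cc, sc$cc_true)
  }
  list(scenes = scenes, truth = truth)
}

#' Write a scene (or series) to disk for file-based pipeline runs
#'
#' `write_scene()` writes the image PNG, the truth-mask PNG and a metadata
#' JSON; `write_series()` writes every scene plus a pipeline-compatible
#' manifest CSV (`path`, `plot_id`, `date`, `truth_path`, `scenario`).
#'
#' @param scene a `field_scene`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem; default combines plot and date.
#' @return The manifest row (data.frame), invisibly for `write_scene()`;
#'   `write_series()` returns the manifest path.
#' @export
write_scene <- function(scene, dir, stem = NULL) {
  stopifnot(inherits(scene, "field_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- stem %||% sprintf("%s_%s", scene$image$plot_id, format(scene$image$date))
  img_path <- file.path(dir, paste0(stem, ".png"))
  truth_path <- file.path(dir, paste0(stem, "_truth.png"))
  png::writePNG(scene$image$pixels, img_path)
  write_mask_png(scene$truth, truth_path)
  jsonlite::write_json(list(plot_id = scene$image$plot_id,
                            date = format(scene$image$date),
                            scenario = scene$scenario,
                            row_count = scene$row_count,
                            cc_true = scene$cc_true, seed = scene$seed),
                       file.path(dir, paste0(stem, ".json")), auto_unbox = TRUE)
  invisible(data.frame(path = img_path, plot_id = scene$image$plot_id,
                       date = format(scene$image$date), truth_path = truth_path,
                       scenario = scene$scenario, stringsAsFactors = FALSE))
}

#' @rdname write_scene
#' @param series a [generate_series()] result.
#' @export
write_series <- function(series, dir) {
  rows <- lapply(series$scenes, write_scene, dir = dir)
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  path
}

#' Default synthetic benchmark for the illumination classifier
#'
#' Generates `n_per_class` LLC and `n_per_class` HLC scenes with varied
#' canopy cover and row counts, and returns their histogram features and
#' class labels (1 = LLC, 2 = HLC).
#'
#' @param n_per_class scenes per class.
#' @param seed master seed.
#' @param size scene size `c(H, W)`.
#' @return List with `features` (matrix, one row per scene), `labels`
#'   (integer vector) and `scenes` (list of `field_scene`s).
#' @export
illumination_benchmark <- function(n_per_class = 100L, seed = 1L,
                                   size = c(96L, 144L)) {
  n <- 2L * n_per_class
  pars <- with_seed(seed, data.frame(
    scenario = rep(c("LLC", "HLC"), each = n_per_class),
    cc = runif(n, 0.05, 0.6),
    rows = sample(5:9, n, replace = TRUE),
    seed = sample.int(.Machine$integer.max - 1L, n)))
  scenes <- lapply(seq_len(n), function(i)
    generate_field_image(pars$scenario[i], row_count = pars$rows[i],
                         cc_target = pars$cc[i], size = size,
                         seed = pars$seed[i]))
  feats <- do.call(rbind, lapply(scenes, function(s) histogram_features(s$image)))
  list(features = feats,
       labels = ifelse(pars$scenario == "LLC", 1L, 2L),
       scenes = scenes)
}
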