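#' Supervised and unsupervised per-pixel plant/background segmentation
#'
#' Pixels are classified in the 10-dimensional feature space of
#' [PIXEL_FEATURES] with a depth-limited decision tree or an SVM. Separate
#' models can be trained per illumination scenario (M_LLC, M_HLC) alongside
#' a general all-light-conditions model (M_ALC); [route_scenario()] selects
#' the model matching the image's illumination class at run time. An
#' unsupervised k-means alternative clusters the Lab (a, b) plane and picks
#' the cluster with the highest mean NDI3 as plant.
#'
#' @name pixel_segmentation
NULL

check_feature_table <- function(table, need_label = TRUE) {
  miss <- setdiff(PIXEL_FEATURES, names(table))
  if (length(miss))
    cc_stop(sprintf("feature table is missing columns: %s", paste(miss, collapse = ", ")),
            "ccpipe_schema_error")
  if (need_label) {
    if (!"label" %in% names(table))
      cc_stop("feature table has no `label` column", "ccpipe_schema_error")
    if (!all(table$label %in% c(0L, 1L)))
      cc_stop("labels must be 0 (background) or 1 (plant)", "ccpipe_value_error")
  }
  invisible(table)
}

#' Train a pixel segmentation model
#'
#' @param table data.frame with the 10 canonical feature columns
#'   ([PIXEL_FEATURES]) plus a `label` column (0 background, 1 plant).
#' @param algorithm `"DT"` (depth-limited decision tree) or `"SVM"`.
#' @param scenario illumination scenario the model is trained for: `"ALC"`
#'   (all light conditions), `"HLC"` or `"LLC"`.
#' @param seed RNG seed for subsampling and fitting.
#' @param max_pixels training-pixel budget; larger tables are reduced by
#'   stratified (per-class, proportional) random subsampling.
#' @param max_depth decision-tree depth limit, preventing pure memorization.
#' @param kernel,cost SVM kernel and regularization; a linear kernel keeps
#'   full-image per-pixel prediction tractable.
#' @return A `seg_model` recording the fitted classifier, the feature-column
#'   order, and a training summary.
#' @export
train_pixel_model <- function(table, algorithm = c("DT", "SVM"),
                              scenario = c("ALC", "HLC", "LLC"),
                              seed = 1L, max_pixels = 500000L,
                              max_depth = 10L, kernel = "linear", cost = 1) {
  algorithm <- match.arg(algorithm)
  scenario <- match.arg(scenario)
  check_feature_table(table)
  if (length(unique(table$label)) < 2L)
    cc_stop("training table must contain both classes", "ccpipe_train_error")
  if (nrow(table) > max_pixels) {
    table <- with_seed(seed, {
      idx <- unlist(lapply(split(seq_len(nrow(table)), table$label), function(i) {
        n <- max(1L, round(length(i) / nrow(table) * max_pixels))
        sample(i, min(n, length(i)))
      }), use.names = FALSE)
      table[sort(idx), , drop = FALSE]
    })
  }
  x <- as.matrix(table[, PIXEL_FEATURES])
  y <- factor(table$label, levels = c(0L, 1L))
  fit <- if (algorithm == "DT") {
    d <- data.frame(x, label = y)
    with_seed(seed, rpart::rpart(label ~ ., data = d, method = "class",
                                 control = rpart::rpart.control(maxdepth = max_depth,
                                                                cp = 1e-4, xval = 0)))
  } else {
    # constant columns cannot be scaled; exclude them from scaling only
    sc <- apply(x, 2, var) > 1e-12
    with_seed(seed, e1071::svm(x, y, kernel = kernel, cost = cost, scale = sc))
  }
  pred <- if (algorithm == "DT") predict(fit, data.frame(x), type = "class")
          else predict(fit, x)
  structure(list(fit = fit, algorithm = algorithm, scenario = scenario,
                 feature_cols = PIXEL_FEATURES,
                 summary = list(n_per_class = as.vector(table(y)), seed = seed,
                                max_pixels = max_pixels,
                                training_accuracy = mean(pred == y))),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<seg_model %s / M_%s, n = %d bg + %d plant, train acc %.3f>\n",
              x$algorithm, x$scenario, s$n_per_class[1], s$n_per_class[2],
              s$training_accuracy))
  invisible(x)
}

predict_pixels <- function(model, table) {
  if (!inherits(model, "seg_model") || is.null(model$fit))
    cc_stop("`model` is not a trained segmentation model", "ccpipe_state_error")
  miss <- setdiff(model$feature_cols, names(table))
  if (length(miss))
    cc_stop(sprintf("prediction table is missing columns: %s", paste(miss, collapse = ", ")),
            "ccpipe_schema_error")
  x <- as.matrix(table[, model$feature_cols])
  p <- if (model$algorithm == "DT") predict(model$fit, data.frame(x), type = "class")
       else predict(model$fit, x)
  as.integer(as.character(p))
}

#' Segment an image with a trained pixel model
#'
#' Applies the model to every pixel's feature vector (identical to running
#' the model row-wise over [extract_pixel_features()] output).
#'
#' @param model a [train_pixel_model()] result.
#' @param img an [rgb_image()].
#' @return A [binary_mask()] the size of the image.
#' @export
segment_supervised <- function(model, img) {
  stopifnot(inherits(img, "rgb_image"))
  feats <- extract_pixel_features(img)
  pred <- predict_pixels(model, feats)
  d <- dim(img$pixels)
  binary_mask(matrix(pred, d[1], d[2]),
              provenance = list(method = "ml", algorithm = model$algorithm,
                                scenario = model$scenario))
}

#' Bundle scenario models for run-time routing
#'
#' @param ALC,HLC,LLC optional `seg_model`s for the matching scenario.
#' @return A `model_bank`.
#' @export
model_bank <- function(ALC = NULL, HLC = NULL, LLC = NULL) {
  b <- list(ALC = ALC, HLC = HLC, LLC = LLC)
  for (s in names(b)) {
    if (!is.null(b[[s]])) {
      if (!inherits(b[[s]], "seg_model"))
        cc_stop(sprintf("bank entry %s is not a seg_model", s), "ccpipe_config_error")
      if (b[[s]]$scenario != s)
        cc_stop(sprintf("bank entry %s holds a model trained for scenario %s",
                        s, b[[s]]$scenario), "ccpipe_config_error")
    }
  }
  structure(b, class = "model_bank")
}

#' Select the scenario model for an illumination class
#'
#' Class 1 (LLC) routes to the M_LLC model, class 2 (HLC) to M_HLC. When the
#' scenario-specific model is absent, the general M_ALC model is used with a
#' warning.
#'
#' @param bank a [model_bank()].
#' @param cls illumination class, 1 (LLC) or 2 (HLC).
#' @return The selected `seg_model`.
#' @export
route_scenario <- function(bank, cls) {
  if (!inherits(bank, "model_bank")) cc_stop("not a model_bank", "ccpipe_config_error")
  if (all(vapply(bank, is.null, logical(1))))
    cc_stop("model bank is empty", "ccpipe_config_error")
  cls <- as.integer(cls)
  if (!cls %in% c(1L, 2L)) cc_stop("illumination class must be 1 or 2", "ccpipe_value_error")
  want <- if (cls == 1L) "LLC" else "HLC"
  if (!is.null(bank[[want]])) return(bank[[want]])
  if (!is.null(bank$ALC)) {
    cc_warn(sprintf("no M_%s model in bank; falling back to M_ALC", want),
            "ccpipe_fallback_warning")
    return(bank$ALC)
  }
  cc_stop(sprintf("bank holds neither M_%s nor M_ALC", want), "ccpipe_config_error")
}

#' Unsupervised k-means segmentation on the Lab (a, b) plane
#'
#' Clusters the per-pixel (a, b) chromaticity pairs into `k = 3` groups
#' (nominally plant, and two background materials such as dry and wet soil)
#' and labels the cluster with the highest mean NDI3 as plant; a tie on mean
#' NDI3 is broken in favour of the larger cluster.
#'
#' @param img an [rgb_image()].
#' @param seed RNG seed for the k-means restarts.
#' @param nstart number of random restarts.
#' @return A [binary_mask()].
#' @export
segment_kmeans <- function(img, seed = 1L, nstart = 10L) {
  stopifnot(inherits(img, "rgb_image"))
  cp <- to_color_planes(img)
  ab <- cbind(as.vector(cp$a), as.vector(cp$b))
  if (nrow(unique(ab)) < 3L)
    cc_stop("fewer than 3 distinct (a, b) values: k-means with k = 3 is degenerate",
            "ccpipe_degenerate")
  km <- with_seed(seed, suppressWarnings(
    kmeans(ab, centers = 3L, nstart = nstart, iter.max = 100L)))
  ndi3 <- as.vector(compute_vi(img, "NDI3")$values)
  mu <- tapply(ndi3, km$cluster, mean)
  sz <- km$size[as.integer(names(mu))]
  plant <- as.integer(names(mu))[order(-mu, -sz)][1L]
  d <- dim(img$pixels)
  binary_mask(matrix(as.integer(km$cluster == plant), d[1], d[2]),
              provenance = list(method = "kmeans", seed = seed))
}

#' Build a labeled training table from an image and its reference mask
#'
#' Convenience for training on synthetic scenes or any image with a known
#' mask: samples up to `n_per_class` pixels per class and returns their
#' feature rows with labels.
#'
#' @param img an [rgb_image()].
#' @param mask reference [binary_mask()] (1 = plant).
#' @param n_per_class pixels sampled per class (all pixels if fewer).
#' @param seed RNG seed.
#' @return data.frame with [PIXEL_FEATURES] columns plus `label`.
#' @export
pixel_training_table <- function(img, mask, n_per_class = 2000L, seed = 1L) {
  m <- mask_values(mask)
  if (!all(dim(m) == dim(img$pixels)[1:2]))
    cc_stop("mask and image shapes differ", "ccpipe_value_error")
  idx <- with_seed(seed, {
    pick <- function(i) if (length(i) <= n_per_class) i else sample(i, n_per_class)
    c(pick(which(m == 1L)), pick(which(m == 0L)))
  })
  tab <- extract_pixel_features(img, pixels = idx)
  tab$label <- as.vector(m)[idx]
  tab
}

#' Read an externally labeled pixel table
#'
#' Headered CSV with the 10 canonical feature columns plus `label`
#' (0 background, 1 plant), e.g. exported from an interactive labeling tool.
#'
#' @param path CSV file path.
#' @return data.frame validated against the canonical schema.
#' @export
read_pixel_table <- function(path) {
  if (!file.exists(path)) cc_stop(sprintf("file not found: %s", path), "ccpipe_io_error")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  check_feature_table(tab)
  tab
}
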