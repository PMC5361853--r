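#' Concatenated RGB histogram features
#'
#' Quantizes each channel to 8-bit levels (0..255), histograms each channel
#' into 256 bins, normalizes each 256-bin block to frequencies so images of
#' different sizes are comparable, and concatenates the blocks in R, G, B
#' order into a vector of 256*3 = 768 numbers.
#'
#' @param img an [rgb_image()].
#' @return Numeric vector of length 768 (class `hist_feature`); each 256-bin
#'   block sums to 1.
#' @export
histogram_features <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  block <- function(ch) {
    lev <- as.integer(round(ch * 255))
    tabulate(lev + 1L, nbins = 256L) / length(lev)
  }
  structure(c(block(img$pixels[, , 1]),
              block(img$pixels[, , 2]),
              block(img$pixels[, , 3])),
            class = "hist_feature", normalized = TRUE)
}

as_feature_matrix <- function(features) {
  if (is.matrix(features)) x <- features
  else if (is.list(features)) x <- do.call(rbind, lapply(features, as.numeric))
  else x <- matrix(as.numeric(features), nrow = 1L)
  if (ncol(x) != 768L)
    cc_stop("illumination features must have length 768 (256 bins x 3 channels)",
            "ccpipe_schema_error")
  x
}

#' Train the SVM illumination-scenario classifier
#'
#' Fits a support-vector machine on concatenated RGB histogram features to
#' separate low light-contrast (LLC, class 1) from high light-contrast
#' (HLC, class 2) images. HLC images contain extremely bright (often
#' saturated) and dark regions; LLC images capture all scene detail in the
#' low-to-medium intensity range. The class coding 1 = LLC, 2 = HLC follows
#' the histogram-figure convention; it is configurable downstream only in
#' the sense that [route_scenario()] maps 1 to the LLC model and 2 to the
#' HLC model.
#'
#' The kernel and regularization are not dictated by the method itself;
#' defaults are an RBF kernel with `cost = 1` and gamma scaled by the
#' overall feature variance (`1 / (768 * var)`). Histogram features are
#' already on a common frequency scale, so no further feature scaling is
#' applied.
#'
#' @param features list of [histogram_features()] vectors, or an `n x 768`
#'   matrix.
#' @param labels integer labels in `{1, 2}` (1 = LLC, 2 = HLC).
#' @param seed RNG seed (used e.g. for cross-validation folds).
#' @param kernel,cost,gamma passed to [e1071::svm()].
#' @param cross if `> 0`, also run k-fold cross-validation and store the
#'   fold accuracies in the summary.
#' @return An `illumination_model` with the fitted classifier and a training
#'   summary (`n_per_class`, kernel, hyperparameters, seed,
#'   `training_accuracy`, optional `cv_accuracy`).
#' @export
train_illumination_model <- function(features, labels, seed = 1L,
                                     kernel = "radial", cost = 1, gamma = NULL,
                                     cross = 0L) {
  x <- as_feature_matrix(features)
  labels <- as.integer(labels)
  if (length(labels) != nrow(x))
    cc_stop("number of labels must match number of feature vectors", "ccpipe_schema_error")
  if (!all(labels %in% c(1L, 2L)))
    cc_stop("labels must be 1 (LLC) or 2 (HLC)", "ccpipe_value_error")
  tab <- table(factor(labels, levels = c(1L, 2L)))
  if (any(tab < 2L))
    cc_stop("need at least 2 examples per class to train", "ccpipe_train_error")
  y <- factor(labels, levels = c(1L, 2L))
  # histogram frequencies are small, so squared distances between feature
  # vectors are tiny; scale gamma by the overall feature variance to put the
  # RBF kernel in its sensitive range
  gamma <- gamma %||% (1 / (ncol(x) * max(var(as.vector(x)), 1e-12)))
  fit <- with_seed(seed,
    e1071::svm(x, y, kernel = kernel, cost = cost, gamma = gamma,
               scale = FALSE, cross = cross))
  acc <- mean(predict(fit, x) == y)
  structure(list(fit = fit,
                 summary = list(n_per_class = as.vector(tab), kernel = kernel,
                                cost = cost, gamma = gamma, seed = seed,
                                training_accuracy = acc,
                                cv_accuracy = if (cross > 0) fit$tot.accuracy / 100)),
            class = "illumination_model")
}

#' @export
print.illumination_model <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<illumination_model SVM(%s), n = %d LLC + %d HLC, train acc %.3f>\n",
              s$kernel, s$n_per_class[1], s$n_per_class[2], s$training_accuracy))
  invisible(x)
}

#' Classify the illumination scenario of an image
#'
#' @param model a trained [train_illumination_model()] result.
#' @param img an [rgb_image()], or a precomputed [histogram_features()]
#'   vector.
#' @return Integer class label: 1 (LLC) or 2 (HLC).
#' @export
classify_illumination <- function(model, img) {
  if (!inherits(model, "illumination_model") || is.null(model$fit))
    cc_stop("`model` is not a trained illumination model", "ccpipe_state_error")
  f <- if (inherits(img, "rgb_image")) histogram_features(img) else img
  x <- as_feature_matrix(f)
  as.integer(as.character(predict(model$fit, x)))
}

#' Save / load an illumination model
#'
#' Models are persisted with a format-version header; loading a mismatched
#' version is refused.
#'
#' @param model an `illumination_model`.
#' @param path file path.
#' @return `save_illumination_model()` returns `path` invisibly;
#'   `load_illumination_model()` returns the model.
#' @export
save_illumination_model <- function(model, path) {
  stopifnot(inherits(model, "illumination_model"))
  obj <- list(format = "ccpipe_illumination_model", version = 1L, model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_illumination_model
#' @export
load_illumination_model <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) cc_stop(sprintf("cannot read model file %s", path),
                                              "ccpipe_io_error"))
  if (!identical(obj$format, "ccpipe_illumination_model") || !identical(obj$version, 1L))
    cc_stop("model file has an unrecognised format/version", "ccpipe_io_error")
  obj$model
}
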