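# Active/rest classification: Gaussian-kernel soft-margin SVM and random
# forest with out-of-bag (OOB) error estimation over stored bootstrap
# memberships.

#' SVM hyper-parameters
#'
#' @param C soft-margin penalty (> 0). Default 1, the empirical setting for
#'   active/rest sEMG classification.
#' @param kernel_width Gaussian kernel width sigma (> 0); the kernel is
#'   `exp(-||x - x'||^2 / (2 * sigma^2))`. Default 0.5.
#' @param kernel `"gaussian"` or `"linear"`.
#' @return an object of class `svm_spec`.
#' @export
svm_spec <- function(C = 1, kernel_width = 0.5, kernel = c("gaussian", "linear")) {
  assert_scalar_pos(C, "C")
  assert_scalar_pos(kernel_width, "kernel_width")
  structure(list(C = C, kernel_width = kernel_width, kernel = match.arg(kernel)),
            class = "svm_spec")
}

#' Random forest hyper-parameters
#'
#' @param trees number of trees K (default 50).
#' @param max_depth maximum tree depth (default 9).
#' @param replace bootstrap with replacement (default `TRUE`; `FALSE` with
#'   `sample_fraction = 1` is the single-tree/no-bootstrap test hook).
#' @param sample_fraction fraction of the training set drawn per tree.
#' @return an object of class `rf_spec`.
#' @export
rf_spec <- function(trees = 50, max_depth = 9, replace = TRUE,
                    sample_fraction = 1) {
  if (trees < 1) stop_input("`trees` must be >= 1")
  if (max_depth < 1) stop_input("`max_depth` must be >= 1")
  structure(list(trees = as.integer(trees), max_depth = as.integer(max_depth),
                 replace = isTRUE(replace), sample_fraction = sample_fraction),
            class = "rf_spec")
}

#' Fit a soft-margin SVM classifier
#'
#' Binary max-margin classifier with Gaussian (RBF) or linear kernel; the
#' decision rule is the sign of the kernel expansion
#' `sum_i alpha_i k(x, x_i) + b`. Labels are taken as 0/1 externally and
#' mapped to -1/+1 internally.
#'
#' @param x feature matrix / data.frame (rows = instances).
#' @param y binary 0/1 labels.
#' @param spec an [svm_spec()].
#' @param scale standardise columns before fitting (default `TRUE`).
#' @return object of class `emg_svm`; use `predict()` to get 0/1 labels.
#' @export
fit_svm <- function(x, y, spec = svm_spec(), scale = TRUE) {
  stopifnot(inherits(spec, "svm_spec"))
  x <- as_feature_matrix(x)
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2) stop_input("training labels contain a single class")
  keep <- apply(x, 2L, function(col) diff(range(col)) > 0)
  if (!any(keep)) stop_input("all feature columns are constant")
  fit <- e1071::svm(
    x = x[, keep, drop = FALSE], y = factor(y, levels = c(0L, 1L)),
    type = "C-classification",
    kernel = if (spec$kernel == "gaussian") "radial" else "linear",
    cost = spec$C, gamma = 1 / (2 * spec$kernel_width^2),
    scale = scale)
  structure(list(fit = fit, spec = spec, n_features = ncol(x), keep = keep),
            class = "emg_svm")
}

#' @export
predict.emg_svm <- function(object, newdata, ...) {
  newdata <- as_feature_matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop_input("newdata has a different number of features than training data")
  }
  as.integer(as.character(predict(object$fit, newdata[, object$keep, drop = FALSE])))
}

#' Fit a random forest with stored bootstrap memberships
#'
#' Grows `spec$trees` depth-limited trees on independent bootstrap samples
#' and retains, per tree, the exact bootstrap membership counts so that
#' out-of-bag membership is reconstructable and [oob_error()] can apply the
#' OOB estimator. Fully reproducible for a fixed seed (single-threaded).
#'
#' @param x feature matrix / data.frame.
#' @param y binary 0/1 labels.
#' @param spec an [rf_spec()].
#' @param seed integer seed.
#' @return object of class `emg_rf` with elements `fit` (the ranger
#'   ensemble), `inbag` (n x K membership count matrix), `train_votes`
#'   (n x K per-tree training-set predictions), `y`.
#' @export
fit_rf <- function(x, y, spec = rf_spec(), seed = 1) {
  stopifnot(inherits(spec, "rf_spec"))
  x <- as_feature_matrix(x)
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2) stop_input("training labels contain a single class")
  df <- as.data.frame(x)
  colnames(df) <- paste0("f", seq_len(ncol(df)))
  fit <- ranger::ranger(
    x = df, y = factor(y, levels = c(0L, 1L)),
    num.trees = spec$trees, max.depth = spec$max_depth,
    replace = spec$replace, sample.fraction = spec$sample_fraction,
    keep.inbag = TRUE, seed = as.integer(seed), num.threads = 1L)
  inbag <- do.call(cbind, fit$inbag.counts)  # n x K counts
  pv <- predict(fit, df, predict.all = TRUE, num.threads = 1L)$predictions
  # ranger returns per-tree factor-level indices; map to 0/1 labels
  lv <- as.integer(fit$forest$levels)
  votes <- matrix(lv[pv], nrow = nrow(pv))
  structure(list(fit = fit, inbag = inbag, train_votes = votes, y = y,
                 spec = spec, n_features = ncol(x), classes = c(0L, 1L)),
            class = "emg_rf")
}

#' Hand-specified forest from explicit votes and memberships
#'
#' Builds a forest-like object directly from a per-tree vote matrix and a
#' bootstrap membership matrix, for constructing exactly known ensembles
#' (e.g. when validating the OOB estimator against hand enumeration).
#'
#' @param votes n x K matrix of per-tree class votes (0/1).
#' @param inbag n x K matrix of bootstrap membership counts (0 = out of bag).
#' @param y true 0/1 labels of the n samples.
#' @return object of class `emg_rf_manual` usable with [predict_vote()] and
#'   [oob_error()].
#' @export
manual_forest <- function(votes, inbag = NULL, y = NULL) {
  votes <- as.matrix(votes)
  if (!is.null(inbag)) {
    inbag <- as.matrix(inbag)
    stopifnot(all(dim(inbag) == dim(votes)))
  }
  structure(list(train_votes = votes, inbag = inbag, y = y,
                 classes = sort(unique(as.integer(votes)))),
            class = "emg_rf_manual")
}

# Majority vote over the columns of a vote matrix; ties broken towards the
# lowest class index.
tally_votes <- function(votes, classes) {
  apply(votes, 1L, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_integer_)
    counts <- vapply(classes, function(cl) sum(v == cl), numeric(1))
    classes[which.max(counts)]  # which.max takes the first (lowest) on ties
  })
}

#' Majority-vote prediction of a forest
#'
#' Each tree votes for a class; the class with the highest average vote wins,
#' with ties broken towards the lowest class index.
#'
#' @param model an `emg_rf` (then `newdata` is required) or an
#'   `emg_rf_manual` (then the stored vote matrix is tallied).
#' @param newdata feature matrix for an `emg_rf`.
#' @return integer class vector.
#' @export
predict_vote <- function(model, newdata = NULL) {
  if (inherits(model, "emg_rf_manual")) {
    return(as.integer(tally_votes(model$train_votes, model$classes)))
  }
  if (!inherits(model, "emg_rf")) stop_input("model is not a fitted forest")
  if (is.null(newdata)) stop_input("`newdata` required for a fitted forest")
  newdata <- as.data.frame(as_feature_matrix(newdata))
  colnames(newdata) <- paste0("f", seq_len(ncol(newdata)))
  pv <- predict(model$fit, newdata, predict.all = TRUE, num.threads = 1L)$predictions
  lv <- as.integer(model$fit$forest$levels)
  as.integer(tally_votes(matrix(lv[pv], nrow = nrow(pv)), model$classes))
}

#' @export
predict.emg_rf <- function(object, newdata, ...) predict_vote(object, newdata)

#' Out-of-bag prediction and error of a forest
#'
#' For every training sample, a prediction by majority vote over only the
#' trees whose bootstrap sample excluded it; the OOB error is the
#' misclassified fraction among samples that are out of bag for at least one
#' tree (samples in every tree's bootstrap are excluded from the
#' denominator).
#'
#' @param model an `emg_rf` or `emg_rf_manual` carrying bootstrap
#'   memberships.
#' @param y true labels; defaults to the labels stored at fit time.
#' @return list with `error` (fraction), `predictions` (OOB votes, `NA` where
#'   a sample has no OOB tree), `n_oob` (denominator count).
#' @export
oob_error <- function(model, y = NULL) {
  if (!inherits(model, c("emg_rf", "emg_rf_manual"))) {
    stop_input("model is not a forest")
  }
  if (is.null(model$inbag)) stop_input("model retains no bootstrap memberships")
  y <- as_binary_labels(y %||% model$y)
  votes <- model$train_votes
  oob_votes <- votes
  oob_votes[model$inbag > 0] <- NA
  pred <- as.integer(tally_votes(oob_votes, model$classes))
  has_oob <- !is.na(pred)
  if (!any(has_oob)) stop_input("no sample is out of bag for any tree; OOB error undefined")
  list(error = mean(pred[has_oob] != y[has_oob]),
       predictions = pred, n_oob = sum(has_oob))
}

#' Mean out-of-bag fraction per tree
#'
#' The expected fraction is `(1 - 1/n)^n`, approaching `exp(-1)` for a
#' standard bootstrap of large `n`.
#' @param model an `emg_rf` or `emg_rf_manual` with memberships.
#' @return mean fraction of samples out of bag, averaged over trees.
#' @export
oob_fraction <- function(model) {
  if (is.null(model$inbag)) stop_input("model retains no bootstrap memberships")
  mean(colMeans(model$inbag == 0))
}
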