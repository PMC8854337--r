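# Epsilon-insensitive support vector regression of force from EMG features.

#' SVR hyper-parameters
#'
#' Defaults follow the package's force-estimation setting: Gaussian kernel
#' with `C = 0.5`, kernel width chosen by the median heuristic
#' (`sigma_sq = "auto"`), and an insensitivity tube of 3% of the normalised
#' force range. Targets are min-max normalised to `[0, 1]` before fitting —
#' see [fit_svr()] — so `epsilon` is expressed in normalised force units; a
#' tube much wider than the residuals of interest would leave the signal
#' unpenalised and flatten the estimate.
#'
#' @param C penalty (> 0).
#' @param epsilon tube half-width (>= 0), in normalised force units.
#' @param sigma_sq Gaussian kernel variance sigma^2 (> 0), or `"auto"` to
#'   use the median heuristic at fit time: half the median pairwise squared
#'   distance of the (scaled) training features. Kernel widths do not
#'   transfer across feature representations, so the data-driven default is
#'   the safe choice; any fixed value can be supplied instead.
#' @param kernel `"gaussian"`, `"linear"` or `"polynomial"`.
#' @return an object of class `svr_spec`.
#' @export
svr_spec <- function(C = 0.5, epsilon = 0.03, sigma_sq = "auto",
                     kernel = c("gaussian", "linear", "polynomial")) {
  assert_scalar_pos(C, "C")
  if (identical(sigma_sq, "auto")) sigma_sq <- NA_real_
  else assert_scalar_pos(sigma_sq, "sigma_sq")
  if (epsilon < 0) stop_input("`epsilon` must be >= 0")
  structure(list(C = C, epsilon = epsilon, sigma_sq = sigma_sq,
                 kernel = match.arg(kernel)),
            class = "svr_spec")
}

#' Gaussian (RBF) kernel
#'
#' `k(x, x') = exp(-||x - x'||^2 / (2 * sigma_sq))`: symmetric, in `(0, 1]`,
#' and equal to 1 iff `x == x'`.
#'
#' @param x,y equal-length numeric vectors.
#' @param sigma_sq kernel variance (> 0).
#' @return similarity value.
#' @export
#' @examples
#' rbf_kernel(c(0, 0), c(1, 1), sigma_sq = 1)  # exp(-1)
rbf_kernel <- function(x, y, sigma_sq) {
  assert_scalar_pos(sigma_sq, "sigma_sq")
  if (length(x) != length(y)) stop_input("inputs must have equal length")
  exp(-sum((x - y)^2) / (2 * sigma_sq))
}

#' Fit epsilon-insensitive support vector regression
#'
#' Minimises `0.5 * ||w||^2 + C * sum(xi_minus + xi_plus)` subject to the
#' epsilon-tube constraints, kernelised. Targets are min-max normalised to
#' `[0, 1]` before fitting by default (predictions are mapped back), so
#' `epsilon` and the reported dual weights live on the normalised scale.
#'
#' @param x feature matrix / data.frame.
#' @param y numeric targets (finite).
#' @param spec an [svr_spec()].
#' @param scale standardise feature columns (default `TRUE`).
#' @param normalize_targets min-max normalise `y` to `[0, 1]` (default
#'   `TRUE`; disable for raw-scale fits).
#' @param tolerance solver termination tolerance.
#' @return object of class `emg_svr` with the support expansion (`dual`
#'   weights, `bias`, support indices) accessible via [svr_dual()].
#' @export
fit_svr <- function(x, y, spec = svr_spec(), scale = TRUE,
                    normalize_targets = TRUE, tolerance = 1e-6) {
  stopifnot(inherits(spec, "svr_spec"))
  x <- as_feature_matrix(x)
  if (any(!is.finite(y))) stop_input("targets contain non-finite values")
  if (nrow(x) < 2) stop_input("need at least 2 training points")
  keep <- apply(x, 2L, function(col) diff(range(col)) > 0)
  if (!any(keep)) stop_input("all feature columns are constant")
  xk <- x[, keep, drop = FALSE]
  y_min <- 0; y_range <- 1
  yy <- as.numeric(y)
  if (normalize_targets) {
    y_min <- min(yy); y_range <- max(yy) - y_min
    if (y_range <= 0) y_range <- 1  # constant target: fit the raw offsets
    yy <- (yy - y_min) / y_range
  }
  sigma_sq <- if (is.na(spec$sigma_sq)) median_heuristic_sigma_sq(xk, scale)
              else spec$sigma_sq
  fit <- e1071::svm(
    x = xk, y = yy, type = "eps-regression",
    kernel = switch(spec$kernel, gaussian = "radial", linear = "linear",
                    polynomial = "polynomial"),
    cost = spec$C, epsilon = spec$epsilon,
    gamma = 1 / (2 * sigma_sq),
    scale = scale, tolerance = tolerance, fitted = FALSE)
  structure(list(fit = fit, spec = spec, n_features = ncol(x), keep = keep,
                 sigma_sq = sigma_sq, y_min = y_min, y_range = y_range,
                 normalize_targets = isTRUE(normalize_targets)),
            class = "emg_svr")
}

# Median heuristic for the Gaussian kernel width: sigma^2 = half the median
# pairwise squared distance, computed on the features as the solver sees them
# (standardised when scale = TRUE). Subsampled for large n; deterministic.
median_heuristic_sigma_sq <- function(x, scale) {
  if (scale) {
    s <- apply(x, 2L, sd)
    x <- sweep(sweep(x, 2L, colMeans(x)), 2L, ifelse(s > 0, s, 1), "/")
  }
  n <- nrow(x)
  idx <- if (n > 400) round(seq(1L, n, length.out = 400L)) else seq_len(n)
  d2 <- as.numeric(stats::dist(x[idx, , drop = FALSE]))^2
  m <- median(d2)
  if (!is.finite(m) || m <= 0) 1 else m / 2
}

#' @export
predict.emg_svr <- function(object, newdata, ...) {
  newdata <- as_feature_matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop_input("newdata has a different number of features than training data")
  }
  p <- if (object$fit$tot.nSV == 0) {
    # every training point sat inside the tube: constant prediction at b
    rep(-object$fit$rho, nrow(newdata))
  } else {
    as.numeric(predict(object$fit, newdata[, object$keep, drop = FALSE]))
  }
  p * object$y_range + object$y_min
}

#' Dual solution of a fitted SVR
#'
#' @param model an `emg_svr`.
#' @return list with `alpha` (signed dual weights `alpha_i - alpha_i^*` of
#'   the support points, bounded by `C` in absolute value), `index` (support
#'   point rows in the training set), `bias`, `n_sv`.
#' @export
svr_dual <- function(model) {
  stopifnot(inherits(model, "emg_svr"))
  list(alpha = as.numeric(model$fit$coefs), index = model$fit$index,
       bias = -model$fit$rho, n_sv = model$fit$tot.nSV)
}
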