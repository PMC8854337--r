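# Evaluation: regression error metrics (including the package's headline
# R-squared convention), confusion matrices, cross-validation folds, and the
# two train/test protocols (trial holdout "A" and pooled 70/30 "B").

#' Regression error metrics
#'
#' Computes MSE, RMSE, MAE, and the relative standard error convention used
#' for the headline accuracy figure:
#' `RSE = sqrt( sum((yhat - y)^2) / sum(|ybar - y|) )` with
#' `R^2 = (1 - RSE) * 100` reported as a percentage. Note the RSE denominator
#' uses absolute (not squared) deviations, so RSE is not scale-invariant
#' (scaling both signals by `k` scales RSE by `sqrt(k)`); the conventional
#' coefficient of determination is reported alongside as
#' `r2_conventional_pct` for comparability.
#'
#' @param y observed values (not all equal: the RSE denominator must be
#'   positive).
#' @param y_hat predicted values, same length.
#' @return one-row data.frame with `n`, `mse`, `rmse`, `mae`, `rse`,
#'   `r2_pct`, `r2_conventional_pct`.
#' @export
#' @examples
#' regression_metrics(c(0, 1, 2), c(0, 1, 3))  # rse = sqrt(1/2), r2 ~ 29.29%
regression_metrics <- function(y, y_hat) {
  if (length(y) != length(y_hat) || length(y) == 0) {
    stop_input("`y` and `y_hat` must be equal-length, non-empty")
  }
  ybar <- mean(y)
  denom <- sum(abs(ybar - y))
  if (denom <= 0) stop_input("`y` is constant; RSE is undefined")
  r <- y_hat - y
  mse <- mean(r^2)
  rse <- sqrt(sum(r^2) / denom)
  ss_tot <- sum((y - ybar)^2)
  data.frame(n = length(y), mse = mse, rmse = sqrt(mse), mae = mean(abs(r)),
             rse = rse, r2_pct = (1 - rse) * 100,
             r2_conventional_pct = (1 - sum(r^2) / ss_tot) * 100)
}

#' Binary confusion summary
#'
#' @param labels true 0/1 labels.
#' @param predictions predicted 0/1 labels, same length.
#' @return object of class `emg_confusion`: `table` (2x2 counts, rows =
#'   truth), `accuracy` (percent), per-class `precision` and `recall`
#'   (fractions), `n`.
#' @export
confusion <- function(labels, predictions) {
  labels <- as_binary_labels(labels)
  predictions <- as_binary_labels(predictions)
  if (length(labels) != length(predictions)) stop_input("length mismatch")
  tab <- table(truth = factor(labels, levels = c(0, 1)),
               predicted = factor(predictions, levels = c(0, 1)))
  prec <- diag(tab) / pmax(colSums(tab), 1)
  rec <- diag(tab) / pmax(rowSums(tab), 1)
  structure(list(table = tab, accuracy = 100 * sum(diag(tab)) / sum(tab),
                 precision = prec, recall = rec, n = sum(tab)),
            class = "emg_confusion")
}

#' @export
print.emg_confusion <- function(x, ...) {
  print(x$table)
  cat(sprintf("accuracy: %.2f%% (n = %d)\n", x$accuracy, x$n))
  invisible(x)
}

#' Seeded (optionally stratified) cross-validation folds
#'
#' @param n number of instances.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @param strata optional factor/vector; folds are balanced within each
#'   stratum (used for classification).
#' @return integer vector of fold assignments in `1..k`; every index appears
#'   in exactly one fold.
#' @export
cv_folds <- function(n, k = 10, seed = NULL, strata = NULL) {
  if (k < 2) stop_input("`k` must be >= 2")
  with_seed_(seed, {
    fold <- integer(n)
    groups <- if (is.null(strata)) list(seq_len(n)) else split(seq_len(n), strata)
    for (g in groups) {
      fold[g] <- sample(rep_len(seq_len(k), length(g)))
    }
    fold
  })
}

# ---- protocol runner -------------------------------------------------------

model_task <- function(model) {
  if (model %in% c("svm", "rf")) "classification" else "regression"
}

fit_predict <- function(model, x_train, y_train, x_test, specs, seed,
                        ga = NULL, tune_ranges = NULL) {
  tuned <- NULL
  m <- switch(model,
    svm = fit_svm(x_train, y_train, specs$svm),
    rf = fit_rf(x_train, y_train, specs$rf, seed = seed),
    svr = fit_svr(x_train, y_train, specs$svr),
    svr_ga = {
      cfg <- ga %||% ga_config()
      cfg$seed <- cfg$seed %||% seed
      tuned <- tune_parameters("svr", x_train, y_train, ranges = tune_ranges,
                               config = cfg)
      fit_svr(x_train, y_train, tuned$spec)
    },
    stop_input(sprintf("unknown model '%s'", model)))
  list(fit = m,
       train = predict(m, x_train), test = predict(m, x_test),
       tuned = tuned)
}

metric_row <- function(task, y, y_hat) {
  if (task == "classification") {
    data.frame(n = length(y), accuracy = confusion(y, y_hat)$accuracy)
  } else {
    regression_metrics(y, y_hat)[c("n", "r2_pct", "rmse", "mse", "mae", "rse")]
  }
}

#' Run a train/test protocol over a cohort
#'
#' Two protocols are supported, per subject:
#'
#' * **Approach A** (trial holdout): fit on the subject's first trial,
#'   evaluate on the second; train metrics are reported too.
#' * **Approach B** (pooled split): pool the subject's trials, draw a seeded
#'   70/30 train/test split (stratified by label for classification), run
#'   `cv_folds`-fold cross-validation inside the training portion for model
#'   verification, then evaluate once on the held-out 30%.
#'
#' The per-subject representation is either windowed time-domain features
#' (default) or decimated envelope samples. Models: `"svm"`, `"rf"`
#' (active/rest classification), `"svr"`, `"svr_ga"` (force regression;
#' `"svr_ga"` first tunes `C`, `epsilon`, `sigma_sq` by GA on the training
#' portion). A cohort-mean row (`subject = "mean"`) is appended per phase,
#' the arithmetic mean of the per-subject metrics.
#'
#' @param recordings list of `emg_recording`s, `trial_count` per subject.
#' @param model one of `"svm"`, `"rf"`, `"svr"`, `"svr_ga"`.
#' @param mode `"A"` or `"B"`.
#' @param seed integer seed for splits, folds, RF and GA.
#' @param train_fraction approach-B training fraction (default 0.7).
#' @param folds approach-B cross-validation folds (default 10; 0 skips CV).
#' @param representation `"windows"` or `"samples"`.
#' @param specs list with elements `svm`, `rf`, `svr` (model
#'   hyper-parameters); missing entries take the package defaults.
#' @param ga [ga_config()] for `"svr_ga"`.
#' @param tune_ranges parameter ranges for `"svr_ga"` (see
#'   [tune_parameters()]).
#' @param emg_config,force_config pre-processing configurations.
#' @param window [window_spec()] for the windowed representation.
#' @param decimate_to sample-mode decimation target rate in Hz.
#' @param label_threshold active/rest force threshold fraction.
#' @param target_delay alignment of force targets to the EMG that produced
#'   them: `"auto"` (default) estimates the electromechanical delay per trial
#'   via [estimate_delay()], a number fixes the delay in seconds, `0`
#'   disables alignment.
#' @return data.frame with one row per subject x phase (`train`, `test`, and
#'   `cv` for approach B) plus cohort-mean rows; regression rows carry
#'   `r2_pct`, `rmse`, `mse`, `mae`, `rse`, classification rows `accuracy`.
#'   For `"svr_ga"` the tuned parameters are attached as attribute
#'   `"tuned_params"` (one named vector per subject).
#' @export
run_protocol <- function(recordings, model = c("svr", "svm", "rf", "svr_ga"),
                         mode = c("B", "A"), seed = 1, train_fraction = 0.7,
                         folds = 10, representation = c("windows", "samples"),
                         specs = list(), ga = NULL, tune_ranges = NULL,
                         emg_config = emg_preproc_config(),
                         force_config = force_preproc_config(),
                         window = window_spec(), decimate_to = 50,
                         label_threshold = 0.1, target_delay = "auto") {
  model <- match.arg(model)
  mode <- match.arg(mode)
  representation <- match.arg(representation)
  task <- model_task(model)
  specs <- utils::modifyList(list(svm = svm_spec(), rf = rf_spec(),
                                  svr = svr_spec()), specs)

  tables <- lapply(recordings, function(rec) {
    env <- preprocess_emg(rec, emg_config)
    frc <- preprocess_force(rec, force_config)
    d <- if (identical(target_delay, "auto")) estimate_delay(env, frc)
         else as.numeric(target_delay)
    if (d > 0) frc <- align_force(frc, d, env$sampling_rate)
    if (representation == "windows") {
      build_feature_matrix(env, frc, window, label_threshold = label_threshold)
    } else {
      sample_matrix(env, frc, decimate_to = decimate_to,
                    label_threshold = label_threshold)
    }
  })
  subjects <- vapply(tables, function(t) t$subject_id[1], character(1))
  out <- list(); tuned_all <- list()
  seeds <- derive_seeds(seed, length(unique(subjects)))

  for (si in seq_along(unique(subjects))) {
    s <- unique(subjects)[si]
    stab <- tables[subjects == s]
    if (mode == "A" && length(stab) < 2) stop_input(sprintf("subject %s lacks a second trial", s))
    sseed <- seeds[si]
    fc <- feature_columns(stab[[1]])
    target <- function(df) if (task == "classification") df$label else df$force_n

    if (mode == "A") {
      xtr <- as_feature_matrix(stab[[1]][fc]); ytr <- target(stab[[1]])
      xte <- as_feature_matrix(stab[[2]][fc]); yte <- target(stab[[2]])
      fp <- fit_predict(model, xtr, ytr, xte, specs, sseed, ga, tune_ranges)
      out[[length(out) + 1L]] <- cbind(subject = s, phase = "train",
                                       metric_row(task, ytr, fp$train))
      out[[length(out) + 1L]] <- cbind(subject = s, phase = "test",
                                       metric_row(task, yte, fp$test))
    } else {
      pooled <- do.call(rbind, stab)
      x <- as_feature_matrix(pooled[fc]); yv <- target(pooled)
      n <- nrow(x)
      idx <- with_seed_(sseed, {
        if (task == "classification") {
          # stratified split: shuffle within class, take 70% of each
          tr <- unlist(lapply(split(seq_len(n), pooled$label), function(g) {
            g <- sample(g); g[seq_len(floor(train_fraction * length(g)))]
          }), use.names = FALSE)
          tr
        } else {
          sample.int(n, floor(train_fraction * n))
        }
      })
      xtr <- x[idx, , drop = FALSE]; ytr <- yv[idx]
      xte <- x[-idx, , drop = FALSE]; yte <- yv[-idx]
      if (folds >= 2) {
        fold <- cv_folds(nrow(xtr), folds, seed = sseed,
                         strata = if (task == "classification") ytr)
        cvm <- lapply(seq_len(folds), function(f) {
          fp <- fit_predict(model, xtr[fold != f, , drop = FALSE], ytr[fold != f],
                            xtr[fold == f, , drop = FALSE], specs, sseed,
                            ga, tune_ranges)
          metric_row(task, ytr[fold == f], fp$test)
        })
        cvm <- do.call(rbind, cvm)
        out[[length(out) + 1L]] <- cbind(subject = s, phase = "cv",
                                         as.data.frame(t(colMeans(cvm))))
      }
      fp <- fit_predict(model, xtr, ytr, xte, specs, sseed, ga, tune_ranges)
      out[[length(out) + 1L]] <- cbind(subject = s, phase = "train",
                                       metric_row(task, ytr, fp$train))
      out[[length(out) + 1L]] <- cbind(subject = s, phase = "test",
                                       metric_row(task, yte, fp$test))
    }
    if (!is.null(fp$tuned)) tuned_all[[s]] <- fp$tuned$params
  }

  res <- do.call(rbind, out)
  res$model <- model; res$mode <- mode
  # cohort mean per phase, arithmetic mean of per-subject metrics
  num_cols <- setdiff(names(res), c("subject", "phase", "model", "mode"))
  for (ph in unique(res$phase)) {
    sub <- res[res$phase == ph, ]
    mrow <- data.frame(subject = "mean", phase = ph,
                       as.list(colMeans(sub[, num_cols, drop = FALSE])),
                       model = model, mode = mode)
    names(mrow) <- c("subject", "phase", num_cols, "model", "mode")
    res <- rbind(res, mrow)
  }
  rownames(res) <- NULL
  if (length(tuned_all)) attr(res, "tuned_params") <- tuned_all
  res
}
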