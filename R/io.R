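# Recording readers/writers (CSV dialect) and run configuration.

#' Write a recording to CSV
#'
#' Columns: `time_s`, one `emg_<channel>` per channel, `force_n`, and
#' `activation` when ground truth is available (synthetic recordings).
#'
#' @param recording an `emg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "emg_recording"))
  df <- data.frame(time_s = recording$time)
  for (i in seq_along(recording$channel_names)) {
    df[[paste0("emg_", recording$channel_names[i])]] <- recording$emg[i, ]
  }
  df$force_n <- recording$force
  if (!is.null(recording$activation_truth)) df$activation <- recording$activation_truth
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read a recording from CSV
#'
#' Validates the schema (`time_s`, at least one `emg_*` column, `force_n`),
#' infers the sampling rate from the time column and rejects duplicated or
#' irregular timestamps (spacing deviating by more than 1 ppm).
#'
#' @param path CSV file written by [write_recording()] (or matching its
#'   dialect).
#' @param subject_id,trial_id identifiers to attach (defaults parsed from
#'   the file name `<subject>_<trial>.csv` when possible).
#' @return an `emg_recording`.
#' @export
read_recording <- function(path, subject_id = NULL, trial_id = NULL) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  df <- data.table::fread(path, data.table = FALSE)
  if (!"time_s" %in% names(df)) stop_input("schema error: missing column `time_s`")
  if (!"force_n" %in% names(df)) stop_input("schema error: missing column `force_n`")
  emg_cols <- grep("^emg_", names(df), value = TRUE)
  if (!length(emg_cols)) stop_input("schema error: no `emg_*` channel columns")
  t <- df$time_s
  d <- diff(t)
  if (any(d <= 0)) stop_input("format error: duplicated or non-increasing timestamps")
  if (max(abs(d - median(d))) > 1e-6 * median(d)) {
    stop_input("format error: irregular time spacing (> 1 ppm)")
  }
  fs <- 1 / median(d)
  base <- sub("\\.csv$", "", basename(path))
  parts <- strsplit(base, "_", fixed = TRUE)[[1]]
  emg <- t(as.matrix(df[emg_cols]))
  rownames(emg) <- sub("^emg_", "", emg_cols)
  structure(list(time = t,
                 emg = emg,
                 force = df$force_n,
                 activation_truth = df$activation,
                 sampling_rate = fs,
                 channel_names = sub("^emg_", "", emg_cols),
                 subject_id = subject_id %||% if (length(parts) >= 2) parts[1] else base,
                 trial_id = trial_id %||% if (length(parts) >= 2) parts[2] else "T1"),
            class = "emg_recording")
}

#' Pipeline run configuration
#'
#' Bundles every stage's settings plus the master seed. All randomness in a
#' pipeline run flows from `seed` through deterministically derived
#' sub-streams (simulation, splits, RF, GA), so a configuration reproduces
#' its outputs exactly.
#'
#' @param n_subjects cohort size.
#' @param seed master integer seed.
#' @param protocol an [emg_protocol()].
#' @param models character vector of models to evaluate (subset of
#'   `"svm"`, `"rf"`, `"svr"`, `"svr_ga"`).
#' @param mode evaluation protocol, `"A"` or `"B"`.
#' @param representation `"windows"` or `"samples"`.
#' @param emg_config,force_config,window stage configurations.
#' @param specs list of model specs (see [run_protocol()]).
#' @param ga [ga_config()] used by `"svr_ga"`.
#' @param folds approach-B cross-validation folds (0 skips CV).
#' @return an object of class `run_config`.
#' @export
run_config <- function(n_subjects = 5, seed = 7, protocol = emg_protocol(),
                       models = c("svm", "rf", "svr", "svr_ga"),
                       mode = "B", representation = "windows",
                       emg_config = emg_preproc_config(),
                       force_config = force_preproc_config(),
                       window = window_spec(), specs = list(),
                       ga = ga_config(generations = 12), folds = 10) {
  structure(list(n_subjects = n_subjects, seed = seed, protocol = protocol,
                 models = models, mode = mode, representation = representation,
                 emg_config = emg_config, force_config = force_config,
                 window = window, specs = specs, ga = ga, folds = folds),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys mirror the [run_config()] arguments
#' (`n_subjects`, `seed`, `models`, `mode`, `representation`, `folds`) plus
#' nested `protocol:`, `emg:`, `force:`, `window:` and `ga:` blocks whose
#' fields are passed to the corresponding constructors. Unknown keys are an
#' error.
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("n_subjects", "seed", "models", "mode", "representation",
             "folds", "protocol", "emg", "force", "window", "ga")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop_input(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
  args <- y[intersect(names(y), c("n_subjects", "seed", "models", "mode",
                                  "representation", "folds"))]
  if (!is.null(y$protocol)) args$protocol <- do.call(emg_protocol, y$protocol)
  if (!is.null(y$emg)) args$emg_config <- do.call(emg_preproc_config, y$emg)
  if (!is.null(y$force)) args$force_config <- do.call(force_preproc_config, y$force)
  if (!is.null(y$window)) args$window <- do.call(window_spec, y$window)
  if (!is.null(y$ga)) args$ga <- do.call(ga_config, y$ga)
  do.call(run_config, args)
}

# Stable hash of a configuration: md5 of its canonical JSON serialisation.
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::serializeJSON(config, digits = 15), tf)
  unname(tools::md5sum(tf))
}
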