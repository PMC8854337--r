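# Windowed time-domain feature extraction and active/rest labelling.

#' Windowing specification
#'
#' @param length window length in seconds (default 0.2).
#' @param step hop between window starts in seconds (default 0.1,
#'   50% overlap); must satisfy `0 < step <= length`.
#' @param alignment `"causal"` windows cover `[start, start + length)`.
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(length = 0.2, step = 0.1, alignment = "causal") {
  if (step <= 0 || step > length) stop_input("`step` must satisfy 0 < step <= length")
  structure(list(length = length, step = step, alignment = alignment),
            class = "window_spec")
}

#' Segment a signal into windows
#'
#' Half-open sample ranges `[start, start + L)`; the number of windows is
#' `floor((n - L) / S) + 1` for signal length `n`, window `L` and step `S`
#' samples.
#'
#' @param n_samples signal length in samples.
#' @param spec a [window_spec()].
#' @param sampling_rate sampling frequency in Hz.
#' @return data.frame with integer columns `start`, `end` (1-based, `end`
#'   inclusive) — one row per window.
#' @export
#' @examples
#' nrow(segment(30000, window_spec(0.2, 0.1), 1000))  # 299 windows
segment <- function(n_samples, spec = window_spec(), sampling_rate) {
  stopifnot(inherits(spec, "window_spec"))
  L <- round(spec$length * sampling_rate)
  S <- max(1L, round(spec$step * sampling_rate))
  if (n_samples < L) stop_input("signal is shorter than one window")
  starts <- seq.int(1L, n_samples - L + 1L, by = S)
  data.frame(start = starts, end = starts + L - 1L)
}

#' Time-domain features of one window
#'
#' Computes the seven standard sEMG time-domain descriptors of a sample
#' window: mean absolute value (MAV), root mean square (RMS), variance (VAR),
#' waveform length (WL, sum of absolute successive differences), zero
#' crossings (ZC), slope sign changes (SSC) and integrated EMG (IEMG, sum of
#' absolute values). ZC counts sign changes whose amplitude step exceeds the
#' deadband; SSC counts turning points whose two-sided slope product exceeds
#' the deadband.
#'
#' @param x numeric window.
#' @param deadband noise deadband for ZC/SSC (same units as `x`; 0 disables).
#' @return named numeric vector `c(mav, rms, var, wl, zc, ssc, iemg)`.
#' @export
#' @examples
#' window_features(c(1, -1, 1, -1))[c("wl", "zc")]  # 6 and 3
window_features <- function(x, deadband = 0) {
  n <- length(x)
  if (n == 0L) stop_input("window is empty")
  d <- diff(x)
  zc <- if (n >= 2) sum(x[-n] * x[-1] < 0 & abs(d) >= deadband) else 0L
  ssc <- if (n >= 3) {
    d1 <- x[2:(n - 1)] - x[1:(n - 2)]
    d2 <- x[2:(n - 1)] - x[3:n]
    sum(d1 * d2 > deadband)
  } else 0L
  c(mav = mean(abs(x)), rms = sqrt(mean(x^2)),
    var = if (n >= 2) var(x) else 0,
    wl = sum(abs(d)), zc = as.numeric(zc), ssc = as.numeric(ssc),
    iemg = sum(abs(x)))
}

#' Feature matrix over all windows and channels
#'
#' @param envelope an `emg_envelope` (or channels x samples matrix).
#' @param spec a [window_spec()].
#' @param sampling_rate required when `envelope` is a bare matrix.
#' @param deadband_fraction ZC/SSC deadband as a fraction of each channel's
#'   maximum (default 1%).
#' @return data.frame with `n_channels * 7` named columns
#'   (`<channel>_<feature>`), one row per window.
#' @export
compute_features <- function(envelope, spec = window_spec(),
                             sampling_rate = NULL, deadband_fraction = 0.01) {
  if (inherits(envelope, "emg_envelope")) {
    vals <- envelope$values
    sampling_rate <- envelope$sampling_rate
  } else {
    vals <- as.matrix(envelope)
    if (is.null(sampling_rate)) stop_input("`sampling_rate` required for a bare matrix")
  }
  win <- segment(ncol(vals), spec, sampling_rate)
  ch <- rownames(vals) %||% paste0("ch", seq_len(nrow(vals)))
  feats <- c("mav", "rms", "var", "wl", "zc", "ssc", "iemg")
  out <- matrix(0, nrow = nrow(win), ncol = nrow(vals) * 7L)
  colnames(out) <- as.vector(t(outer(ch, feats, paste, sep = "_")))
  for (c in seq_len(nrow(vals))) {
    db <- deadband_fraction * max(abs(vals[c, ]))
    for (w in seq_len(nrow(win))) {
      out[w, ((c - 1L) * 7L + 1L):(c * 7L)] <-
        window_features(vals[c, win$start[w]:win$end[w]], deadband = db)
    }
  }
  as.data.frame(out)
}

#' Active/rest labels from per-window force
#'
#' A window is labelled active (1) when its mean force exceeds
#' `threshold_fraction` of the trial's maximum window force, otherwise rest
#' (0).
#'
#' @param force_per_window numeric vector of window-mean force.
#' @param threshold_fraction in (0, 1); default 0.1.
#' @return integer vector of 0/1 labels.
#' @export
label_windows <- function(force_per_window, threshold_fraction = 0.1) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop_input("`threshold_fraction` must be in (0, 1)")
  }
  m <- max(force_per_window)
  if (m <= 0) {
    warning("force is all zero; labelling every window as rest")
    return(rep(0L, length(force_per_window)))
  }
  as.integer(force_per_window > threshold_fraction * m)
}

#' Windowed feature matrix with labels and force targets
#'
#' Combines [compute_features()], window-mean force targets and
#' [label_windows()] into the analysis-ready table consumed by the
#' classifiers and the force regressor.
#'
#' @param envelope an `emg_envelope`.
#' @param force cleaned force trace aligned with the envelope (e.g. from
#'   [preprocess_force()]).
#' @param spec a [window_spec()].
#' @param label_threshold active/rest threshold fraction.
#' @param deadband_fraction ZC/SSC deadband fraction.
#' @return data.frame of features plus `force_n` (window-mean force),
#'   `label` (0/1), `subject_id`, `trial_id`.
#' @export
#' @examples
#' rec <- simulate_recording(seed = 1)
#' fm <- build_feature_matrix(preprocess_emg(rec), preprocess_force(rec))
#' table(fm$label)
build_feature_matrix <- function(envelope, force, spec = window_spec(),
                                 label_threshold = 0.1,
                                 deadband_fraction = 0.01) {
  stopifnot(inherits(envelope, "emg_envelope"))
  if (length(force) != ncol(envelope$values)) {
    stop_input("force and envelope lengths differ")
  }
  win <- segment(ncol(envelope$values), spec, envelope$sampling_rate)
  ft <- compute_features(envelope, spec, deadband_fraction = deadband_fraction)
  fw <- vapply(seq_len(nrow(win)),
               function(w) mean(force[win$start[w]:win$end[w]]), numeric(1))
  ft$force_n <- fw
  ft$label <- label_windows(fw, label_threshold)
  ft$subject_id <- envelope$subject_id %||% NA_character_
  ft$trial_id <- envelope$trial_id %||% NA_character_
  ft
}

#' Per-sample envelope matrix with labels and force targets
#'
#' The alternative "sample-mode" representation: each (optionally decimated)
#' time sample is one instance whose features are the channel envelope values
#' at that sample. Matches pipelines that feed envelope samples directly to
#' the classifier/regressor.
#'
#' @param envelope an `emg_envelope`.
#' @param force cleaned force trace aligned with the envelope.
#' @param decimate_to target sampling rate in Hz (the 6 Hz-bandwidth envelope
#'   is heavily oversampled at 1 kHz); `NULL` keeps every sample.
#' @param label_threshold active/rest threshold fraction of the trial maximum.
#' @return data.frame with one column per channel plus `force_n`, `label`,
#'   `subject_id`, `trial_id`.
#' @export
sample_matrix <- function(envelope, force, decimate_to = 50,
                          label_threshold = 0.1) {
  stopifnot(inherits(envelope, "emg_envelope"))
  vals <- envelope$values
  if (length(force) != ncol(vals)) stop_input("force and envelope lengths differ")
  idx <- if (is.null(decimate_to)) seq_len(ncol(vals)) else {
    seq.int(1L, ncol(vals), by = max(1L, round(envelope$sampling_rate / decimate_to)))
  }
  out <- as.data.frame(t(vals[, idx, drop = FALSE]))
  names(out) <- envelope$channel_names %||% paste0("ch", seq_len(nrow(vals)))
  out$force_n <- force[idx]
  m <- max(force)
  out$label <- if (m > 0) as.integer(force[idx] > label_threshold * m) else 0L
  out$subject_id <- envelope$subject_id %||% NA_character_
  out$trial_id <- envelope$trial_id %||% NA_character_
  out
}

#' Model-input columns of a feature table
#'
#' Names of the columns of a feature table that are model inputs — everything
#' except the `force_n` target, the `label`, and the identifier columns.
#' @param df a feature table from [build_feature_matrix()] or
#'   [sample_matrix()].
#' @return character vector of column names.
#' @export
feature_columns <- function(df) {
  setdiff(names(df), c("force_n", "label", "subject_id", "trial_id"))
}

#' Estimate the electromechanical delay between EMG envelope and force
#'
#' Muscle force lags the EMG envelope by the electromechanical delay plus the
#' force development dynamics. The delay is estimated as the lag (in seconds)
#' that maximises the cross-correlation between the channel-mean envelope and
#' the force trace, searched over `[0, max_delay]`.
#'
#' @param envelope an `emg_envelope` (or channels x samples matrix).
#' @param force force trace aligned with the envelope.
#' @param max_delay largest physiologically plausible delay in seconds.
#' @param sampling_rate required when `envelope` is a bare matrix.
#' @return delay in seconds (>= 0).
#' @export
estimate_delay <- function(envelope, force, max_delay = 0.4,
                           sampling_rate = NULL) {
  if (inherits(envelope, "emg_envelope")) {
    vals <- envelope$values
    sampling_rate <- envelope$sampling_rate
  } else {
    vals <- as.matrix(envelope)
    if (is.null(sampling_rate)) stop_input("`sampling_rate` required for a bare matrix")
  }
  me <- colMeans(vals)
  n <- length(force)
  if (length(me) != n) stop_input("force and envelope lengths differ")
  D <- min(round(max_delay * sampling_rate), n - 2L)
  cc <- vapply(0:D, function(d) {
    suppressWarnings(cor(me[seq_len(n - d)], force[(d + 1L):n]))
  }, numeric(1))
  cc[is.na(cc)] <- -Inf
  (which.max(cc) - 1L) / sampling_rate
}

#' Shift a force trace earlier by a delay
#'
#' Aligns force targets with the EMG that produced them: sample `t` of the
#' result is `force[t + delay]`; the tail is padded with the final value.
#'
#' @param force numeric force trace.
#' @param delay delay in seconds (>= 0).
#' @param sampling_rate sampling frequency in Hz.
#' @return shifted trace, same length.
#' @export
align_force <- function(force, delay, sampling_rate) {
  d <- round(delay * sampling_rate)
  if (d <= 0) return(force)
  n <- length(force)
  if (d >= n) stop_input("`delay` exceeds the trace duration")
  c(force[(d + 1L):n], rep(force[n], d))
}
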