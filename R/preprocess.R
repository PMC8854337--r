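# Signal pre-processing: the 6-step EMG chain (DC removal, band-pass, notch,
# half-wave rectification, smoothing, normalisation) and the 3-step force
# chain (notch, bias removal, 15 Hz low-pass).

#' EMG pre-processing configuration
#'
#' @param bandpass_low,bandpass_high Butterworth band-pass edges in Hz
#'   (defaults 20 and 500; at 1 kHz sampling 500 Hz equals Nyquist and is
#'   clamped, see `clamp_band`).
#' @param bandpass_order Butterworth order per direction (zero-phase
#'   application squares the magnitude response).
#' @param notch_freq powerline notch centre in Hz.
#' @param notch_quality notch quality factor Q (centre / -3 dB width).
#' @param smoothing_method `"lowpass"` (linear envelope: low-pass of the
#'   rectified signal) or `"rms"` (moving RMS).
#' @param smoothing_cutoff envelope low-pass cut-off in Hz.
#' @param smoothing_window moving-RMS window in seconds (used when
#'   `smoothing_method = "rms"`).
#' @param rectification `"half"` zeroes negative samples; `"full"` takes the
#'   absolute value.
#' @param normalization `"per-max"` divides each channel by its own trial
#'   maximum, `"fixed"` divides by `normalization_reference`, `"none"` skips
#'   the step.
#' @param normalization_reference reference amplitude for `"fixed"`.
#' @param clamp_band if `TRUE` (default) a `bandpass_high` at or above Nyquist
#'   is clamped to `0.45 * sampling_rate` with a message; if `FALSE` it is a
#'   configuration error.
#' @return an object of class `emg_preproc_config`.
#' @export
emg_preproc_config <- function(bandpass_low = 20, bandpass_high = 500,
                               bandpass_order = 4, notch_freq = 50,
                               notch_quality = 30,
                               smoothing_method = c("lowpass", "rms"),
                               smoothing_cutoff = 6, smoothing_window = 0.25,
                               rectification = c("half", "full"),
                               normalization = c("per-max", "fixed", "none"),
                               normalization_reference = 1,
                               clamp_band = TRUE) {
  if (bandpass_low <= 0 || bandpass_high <= bandpass_low) {
    stop_input("band-pass edges must satisfy 0 < low < high")
  }
  if (notch_freq <= bandpass_low || notch_freq >= bandpass_high) {
    stop_input("`notch_freq` must lie inside the band-pass")
  }
  structure(list(bandpass_low = bandpass_low, bandpass_high = bandpass_high,
                 bandpass_order = bandpass_order, notch_freq = notch_freq,
                 notch_quality = notch_quality,
                 smoothing_method = match.arg(smoothing_method),
                 smoothing_cutoff = smoothing_cutoff,
                 smoothing_window = smoothing_window,
                 rectification = match.arg(rectification),
                 normalization = match.arg(normalization),
                 normalization_reference = normalization_reference,
                 clamp_band = isTRUE(clamp_band)),
            class = "emg_preproc_config")
}

#' Force pre-processing configuration
#'
#' @param notch_freq powerline notch centre in Hz.
#' @param notch_quality notch quality factor.
#' @param lowpass_cutoff low-pass cut-off in Hz (default 15).
#' @param lowpass_order Butterworth order (default 2, "two-level").
#' @param rectify optionally zero negative samples after bias removal
#'   (off by default).
#' @param normalize divide by the trial maximum so the cleaned force lies in
#'   `[0, 1]` (on by default; skipped for an all-zero trace).
#' @return an object of class `force_preproc_config`.
#' @export
force_preproc_config <- function(notch_freq = 50, notch_quality = 30,
                                 lowpass_cutoff = 15, lowpass_order = 2,
                                 rectify = FALSE, normalize = TRUE) {
  assert_scalar_pos(lowpass_cutoff, "lowpass_cutoff")
  structure(list(notch_freq = notch_freq, notch_quality = notch_quality,
                 lowpass_cutoff = lowpass_cutoff, lowpass_order = lowpass_order,
                 rectify = isTRUE(rectify), normalize = isTRUE(normalize)),
            class = "force_preproc_config")
}

# ---- filter primitives -----------------------------------------------------

# Zero-phase forward-backward IIR filtering with odd-reflection padding at
# both ends. The padding length is set from the filter's settling time
# (slowest pole) so that edge transients of narrow, high-Q stages decay
# inside the padding rather than inside the signal.
zero_phase_filter <- function(b, a, x) {
  n <- length(x)
  p_min <- 3L * (max(length(a), length(b)) - 1L)
  p <- p_min
  if (length(a) > 1L) {
    r <- max(Mod(polyroot(rev(a))))
    if (r < 1 - 1e-9) {
      tau <- -1 / log(r)  # samples to decay by e^-1
      p <- max(p_min, ceiling(9 * tau))  # settle junction ringing to ~e^-9
    } else p <- 3000L
  }
  p <- as.integer(min(p, n - 1L))
  xp <- c(2 * x[1] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  as.numeric(y[(p + 1L):(p + n)])
}

# Biquad IIR notch (constrained zero on the unit circle at f0), quality
# factor Q = f0 / bandwidth. The `signal` package ships no notch designer.
design_notch <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

design_bandpass <- function(config, fs) {
  high <- effective_band_high(config, fs)$high
  bf <- signal::butter(config$bandpass_order,
                       c(config$bandpass_low, high) / (fs / 2), type = "pass")
  list(b = bf$b, a = bf$a)
}

effective_band_high <- function(config, fs) {
  high <- config$bandpass_high
  clamped <- FALSE
  if (high >= fs / 2) {
    if (!config$clamp_band) {
      stop_input(sprintf("bandpass_high = %g Hz is at/above Nyquist (%g Hz); enable clamp_band or lower it",
                         high, fs / 2))
    }
    high <- 0.45 * fs
    clamped <- TRUE
  }
  list(high = high, clamped = clamped)
}

moving_rms <- function(x, w) {
  k <- rep(1 / w, w)
  sq <- stats::filter(x^2, k, sides = 2)
  sq[is.na(sq)] <- x[is.na(sq)]^2  # edges: fall back to the sample itself
  sqrt(pmax(as.numeric(sq), 0))
}

#' Rectify a signal
#'
#' Half-wave rectification zeroes negative samples; full-wave takes the
#' absolute value. Idempotent in both modes.
#' @param x numeric vector.
#' @param mode `"half"` or `"full"`.
#' @return rectified vector.
#' @export
rectify <- function(x, mode = c("half", "full")) {
  mode <- match.arg(mode)
  if (mode == "half") pmax(x, 0) else abs(x)
}

# ---- EMG chain -------------------------------------------------------------

#' Pre-process EMG channels into normalised envelopes
#'
#' Applies, in order: (1) mean (DC) subtraction, (2) zero-phase Butterworth
#' band-pass, (3) zero-phase powerline notch, (4) rectification (half-wave by
#' default), (5) envelope smoothing (6 Hz linear envelope by default), and
#' (6) per-channel normalisation. Step order matters and is recorded in the
#' returned object's `provenance`.
#'
#' @param recording an `emg_recording` (or any list with `emg` matrix and
#'   `sampling_rate`).
#' @param config an [emg_preproc_config()].
#' @return object of class `emg_envelope`: `values` (channels x samples, in
#'   `[0, 1]` after normalisation), `sampling_rate`, `channel_names`,
#'   `provenance`, and the pass-through `subject_id`/`trial_id`.
#' @export
#' @examples
#' rec <- simulate_recording(seed = 1)
#' env <- preprocess_emg(rec)
#' range(env$values)
preprocess_emg <- function(recording, config = emg_preproc_config()) {
  stopifnot(inherits(config, "emg_preproc_config"))
  emg <- recording$emg
  if (is.null(dim(emg))) emg <- matrix(emg, nrow = 1)
  fs <- recording$sampling_rate
  if (is.null(fs) || fs <= 0) stop_input("recording has no valid sampling_rate")

  eb <- effective_band_high(config, fs)
  if (eb$clamped) {
    message(sprintf("bandpass_high clamped from %g to %g Hz (Nyquist %g Hz)",
                    config$bandpass_high, eb$high, fs / 2))
  }
  bp <- design_bandpass(config, fs)
  nt <- design_notch(config$notch_freq, fs, config$notch_quality)

  out <- matrix(0, nrow = nrow(emg), ncol = ncol(emg))
  prov <- c("dc_removal",
            sprintf("bandpass_butterworth(order=%d, %g-%g Hz, zero-phase)",
                    config$bandpass_order, config$bandpass_low, eb$high),
            sprintf("notch(%g Hz, Q=%g, zero-phase)", config$notch_freq,
                    config$notch_quality),
            sprintf("rectification(%s-wave)", config$rectification),
            if (config$smoothing_method == "lowpass") {
              sprintf("smoothing(lowpass %g Hz)", config$smoothing_cutoff)
            } else sprintf("smoothing(moving-rms %gs)", config$smoothing_window),
            sprintf("normalization(%s)", config$normalization))
  if (eb$clamped) prov <- c(prov, "bandpass_high_clamped")

  for (c in seq_len(nrow(emg))) {
    x <- emg[c, ]
    x <- x - mean(x)
    x <- zero_phase_filter(bp$b, bp$a, x)
    x <- zero_phase_filter(nt$b, nt$a, x)
    x <- rectify(x, config$rectification)
    if (config$smoothing_method == "lowpass") {
      lp <- signal::butter(4, config$smoothing_cutoff / (fs / 2), type = "low")
      x <- pmax(zero_phase_filter(lp$b, lp$a, x), 0)  # envelope cannot undershoot
    } else {
      x <- moving_rms(x, max(1L, round(config$smoothing_window * fs)))
    }
    if (config$normalization == "per-max") {
      m <- max(x)
      if (m > .Machine$double.eps) x <- x / m
      else warning(sprintf("channel %d is (near) zero; normalisation skipped", c))
    } else if (config$normalization == "fixed") {
      x <- x / config$normalization_reference
    }
    out[c, ] <- x
  }
  rownames(out) <- rownames(emg) %||% recording$channel_names
  structure(list(values = out, sampling_rate = fs,
                 channel_names = rownames(out),
                 provenance = prov,
                 subject_id = recording$subject_id,
                 trial_id = recording$trial_id),
            class = "emg_envelope")
}

#' @export
print.emg_envelope <- function(x, ...) {
  cat(sprintf("<emg_envelope> %d channels x %d samples @ %g Hz\n steps: %s\n",
              nrow(x$values), ncol(x$values), x$sampling_rate,
              paste(x$provenance, collapse = " -> ")))
  invisible(x)
}

# ---- force chain -----------------------------------------------------------

#' Pre-process the force channel
#'
#' Applies, in order: zero-phase powerline notch, bias removal, optional
#' rectification, zero-phase second-order 15 Hz Butterworth low-pass, and
#' optional normalisation to `[0, 1]`. Bias removal subtracts the median of
#' the rest-segment samples when the recording carries ground-truth activation
#' (synthetic recordings do); otherwise a robust baseline, the 1st percentile
#' of the trace, is used so that rest-free signals are not shifted.
#'
#' @param recording an `emg_recording` with a `force` vector (an
#'   `activation_truth` element, if present, identifies rest samples).
#' @param config a [force_preproc_config()].
#' @return numeric vector, same length as the input force.
#' @export
preprocess_force <- function(recording, config = force_preproc_config()) {
  stopifnot(inherits(config, "force_preproc_config"))
  f <- recording$force
  if (is.null(f)) stop_input("recording has no force channel")
  fs <- recording$sampling_rate
  nt <- design_notch(config$notch_freq, fs, config$notch_quality)
  x <- zero_phase_filter(nt$b, nt$a, f)
  act <- recording$activation_truth
  lp <- signal::butter(config$lowpass_order, config$lowpass_cutoff / (fs / 2),
                       type = "low")
  # the baseline is estimated on a low-passed copy: residual notch ringing at
  # the trace edges is out-of-band there, and the constant commutes with the
  # (unit-DC-gain) low-pass
  smooth <- zero_phase_filter(lp$b, lp$a, x)
  bias <- if (!is.null(act) && any(act == 0)) median(smooth[act == 0])
          else quantile(smooth, 0.01, names = FALSE)
  x <- x - bias
  if (config$rectify) x <- pmax(x, 0)
  x <- zero_phase_filter(lp$b, lp$a, x)
  if (config$normalize) {
    m <- max(x)
    if (m > .Machine$double.eps) x <- x / m
  }
  x
}

# ---- diagnostics -----------------------------------------------------------

#' Magnitude response of the linear EMG pre-filter chain
#'
#' Composes the designed DC-blocking band-pass and notch stages (the linear
#' part of the chain, before the nonlinear rectification) and evaluates the
#' magnitude response on a frequency grid. With `zero_phase = TRUE` (the
#' default, matching how filters are applied) the single-pass magnitude is
#' squared.
#'
#' @param config an [emg_preproc_config()].
#' @param sampling_rate sampling frequency in Hz.
#' @param freqs frequencies in Hz at which to evaluate.
#' @param zero_phase square the magnitude (forward-backward application).
#' @return data.frame with columns `freq_hz`, `gain`, `gain_db`.
#' @export
#' @examples
#' fr <- frequency_response(emg_preproc_config(), 1000, freqs = c(5, 50, 150))
#' fr$gain_db
frequency_response <- function(config = emg_preproc_config(), sampling_rate = 1000,
                               freqs = seq(1, 0.45 * sampling_rate, by = 1),
                               zero_phase = TRUE) {
  stopifnot(inherits(config, "emg_preproc_config"))
  bp <- design_bandpass(config, sampling_rate)
  nt <- design_notch(config$notch_freq, sampling_rate, config$notch_quality)
  H <- function(ba, f) {
    w <- 2 * pi * f / sampling_rate
    num <- vapply(w, function(wi) sum(ba$b * exp(-1i * wi * (seq_along(ba$b) - 1))), complex(1))
    den <- vapply(w, function(wi) sum(ba$a * exp(-1i * wi * (seq_along(ba$a) - 1))), complex(1))
    Mod(num / den)
  }
  g <- H(bp, freqs) * H(nt, freqs)
  if (zero_phase) g <- g^2
  data.frame(freq_hz = freqs, gain = g, gain_db = 20 * log10(pmax(g, 1e-300)))
}
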