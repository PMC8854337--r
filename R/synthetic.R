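# Synthetic recording generator: protocol-faithful sEMG + force traces with
# known ground-truth activation.

#' Recording protocol
#'
#' Describes the contraction/rest exercise protocol: the subject pushes against
#' the load cell for `on_duration` seconds, rests for `off_duration` seconds,
#' and repeats `repetitions` times. Defaults reproduce the acquisition setting
#' the package emulates: 5 s contraction, 5 s rest, 3 repetitions, three
#' quadriceps EMG channels sampled at 1 kHz, two trials per subject.
#'
#' @param on_duration contraction duration in seconds (> 0).
#' @param off_duration rest duration in seconds (> 0).
#' @param repetitions number of contraction/rest cycles (>= 1).
#' @param sampling_rate sampling frequency in Hz.
#' @param n_channels number of EMG channels.
#' @param trial_count trials recorded per subject.
#' @return an object of class `emg_protocol`.
#' @export
#' @examples
#' p <- emg_protocol()
#' p$repetitions
emg_protocol <- function(on_duration = 5, off_duration = 5, repetitions = 3,
                         sampling_rate = 1000, n_channels = 3, trial_count = 2) {
  assert_scalar_pos(on_duration, "on_duration")
  assert_scalar_pos(off_duration, "off_duration")
  assert_scalar_pos(sampling_rate, "sampling_rate")
  if (repetitions < 1) stop_input("`repetitions` must be >= 1")
  if (n_channels < 1) stop_input("`n_channels` must be >= 1")
  structure(list(on_duration = on_duration, off_duration = off_duration,
                 repetitions = as.integer(repetitions),
                 sampling_rate = sampling_rate,
                 n_channels = as.integer(n_channels),
                 trial_count = as.integer(trial_count)),
            class = "emg_protocol")
}

#' Noise model for simulated sEMG
#'
#' The simulated EMG of each channel is activation-modulated band-limited
#' Gaussian noise (the standard amplitude-modulation surrogate for surface
#' EMG interference patterns) plus the contaminants the pre-processing chain
#' is designed to remove: mains powerline interference, a DC offset, slow
#' baseline drift and broadband sensor noise. Amplitudes are in the same
#' arbitrary millivolt-like units as the per-channel gains.
#'
#' @param emg_band two-element vector, carrier band edges in Hz.
#' @param powerline_freq mains frequency, 50 or 60 Hz.
#' @param powerline_amplitude powerline sine amplitude (default 20% of a unit
#'   peak envelope).
#' @param dc_offset constant offset (default 5%).
#' @param baseline_drift_amplitude amplitude of the slow (< 0.25 Hz) drift.
#' @param sensor_noise_sd standard deviation of additive white sensor noise.
#' @return an object of class `emg_noise_model`.
#' @export
noise_model <- function(emg_band = c(20, 450), powerline_freq = 50,
                        powerline_amplitude = 0.2, dc_offset = 0.05,
                        baseline_drift_amplitude = 0.02,
                        sensor_noise_sd = 0.01) {
  if (length(emg_band) != 2 || emg_band[1] <= 0 || emg_band[2] <= emg_band[1]) {
    stop_input("`emg_band` must satisfy 0 < low < high")
  }
  if (!powerline_freq %in% c(50, 60)) stop_input("`powerline_freq` must be 50 or 60 Hz")
  structure(list(emg_band = as.numeric(emg_band),
                 powerline_freq = powerline_freq,
                 powerline_amplitude = powerline_amplitude,
                 dc_offset = dc_offset,
                 baseline_drift_amplitude = baseline_drift_amplitude,
                 sensor_noise_sd = sensor_noise_sd),
            class = "emg_noise_model")
}

#' Activation-to-force map for simulation
#'
#' The simulator needs a known, smooth, monotone map from muscle activation to
#' load-cell force so that force recovery by the regression models is
#' verifiable. Force is `max_force * lowpass(lagged_activation ^ exponent)`
#' where the low-pass is a first-order stage with time constant
#' `time_constant` seconds (muscle force develops more slowly than the EMG),
#' plus Gaussian measurement noise.
#'
#' @param max_force peak force in newtons.
#' @param activation_exponent exponent of the (dimensionless) activation,
#'   > 0; values > 1 make force rise slightly super-linearly with activation.
#' @param activation_lag electromechanical delay in seconds (>= 0).
#' @param time_constant first-order force dynamics time constant in seconds.
#' @param force_noise_sd load-cell noise standard deviation in newtons.
#' @param per_channel_gain positive per-channel EMG gains (arbitrary mV-like
#'   units).
#' @return an object of class `emg_force_model`.
#' @export
force_model <- function(max_force = 200, activation_exponent = 1.2,
                        activation_lag = 0.05, time_constant = 0.15,
                        force_noise_sd = 0.5,
                        per_channel_gain = c(1.0, 0.9, 0.8)) {
  assert_scalar_pos(max_force, "max_force")
  assert_scalar_pos(activation_exponent, "activation_exponent")
  if (activation_lag < 0) stop_input("`activation_lag` must be >= 0")
  if (any(per_channel_gain <= 0)) stop_input("`per_channel_gain` must be positive")
  structure(list(max_force = max_force,
                 activation_exponent = activation_exponent,
                 activation_lag = activation_lag,
                 time_constant = time_constant,
                 force_noise_sd = force_noise_sd,
                 per_channel_gain = as.numeric(per_channel_gain)),
            class = "emg_force_model")
}

default_channel_names <- function(n) {
  if (n == 3) c("vm", "vl", "rf") else paste0("ch", seq_len(n))
}

#' Trapezoidal activation trace for a protocol
#'
#' Builds the ground-truth activation profile: `repetitions` trapezoidal
#' pulses, each rising linearly from 0 to 1 over `rise_time`, holding the
#' plateau at 1, and falling back over `rise_time`, all inside the
#' `on_duration` window, separated by `off_duration` of rest. The trace is
#' fully deterministic (no randomness is involved, so no seed is taken).
#'
#' @param protocol an [emg_protocol()].
#' @param rise_time ramp duration in seconds; must be < `on_duration / 2`.
#'   `rise_time = 0` degenerates to an ideal square wave.
#' @return numeric vector in `[0, 1]` of length
#'   `repetitions * (on + off) * sampling_rate`.
#' @export
#' @examples
#' a <- make_activation(emg_protocol(), rise_time = 0.5)
#' length(a)  # 30000 samples
make_activation <- function(protocol, rise_time = 0.5) {
  stopifnot(inherits(protocol, "emg_protocol"))
  on <- protocol$on_duration; off <- protocol$off_duration
  fs <- protocol$sampling_rate
  if (rise_time < 0 || rise_time >= on / 2) {
    stop_input("`rise_time` must be in [0, on_duration/2)")
  }
  cycle <- on + off
  n <- round(protocol$repetitions * cycle * fs)
  t <- (seq_len(n) - 1) / fs
  tc <- t %% cycle
  a <- numeric(n)
  if (rise_time > 0) {
    up <- tc < rise_time
    a[up] <- tc[up] / rise_time
    plateau <- tc >= rise_time & tc < on - rise_time
    a[plateau] <- 1
    down <- tc >= on - rise_time & tc < on
    a[down] <- (on - tc[down]) / rise_time
  } else {
    a[tc < on] <- 1
  }
  a
}

# Unit-RMS Gaussian noise band-limited to `band` (Hz) by a zero-phase
# order-4 Butterworth band-pass. Exported because tests and users probing the
# carrier model need it directly.

#' Band-limited Gaussian noise carrier
#'
#' White Gaussian noise filtered into `band` by a zero-phase fourth-order
#' Butterworth band-pass and rescaled to unit RMS. This is the EMG carrier
#' used by [simulate_recording()].
#'
#' @param n number of samples.
#' @param sampling_rate sampling frequency in Hz.
#' @param band two-element band edges in Hz (must be below Nyquist).
#' @param seed optional integer seed.
#' @return numeric vector of length `n` with RMS 1.
#' @export
bandlimited_noise <- function(n, sampling_rate, band = c(20, 450), seed = NULL) {
  if (band[2] >= sampling_rate / 2) stop_input("`band` exceeds the Nyquist frequency")
  x <- with_seed_(seed, rnorm(n))
  bf <- signal::butter(4, band / (sampling_rate / 2), type = "pass")
  y <- zero_phase_filter(bf$b, bf$a, x)
  y / sqrt(mean(y^2))
}

#' Simulate one sEMG + force recording
#'
#' Generates a multi-channel raw recording following the protocol. For
#' channel `c` the EMG is
#' `gain_c * activation * carrier_c + dc + A * sin(2*pi*f_mains*t + phase) +
#' drift_c + sensor_noise_c`, where `carrier_c` is unit-RMS band-limited
#' Gaussian noise. Force is the smooth lagged power-law map of
#' [force_model()]. The result is bit-reproducible for a fixed seed.
#'
#' @param protocol an [emg_protocol()].
#' @param noise an [emg_noise_model()][noise_model()].
#' @param force an [emg_force_model()][force_model()]; its
#'   `per_channel_gain` is recycled/truncated to `protocol$n_channels`.
#' @param rise_time activation ramp in seconds (see [make_activation()]).
#' @param seed integer seed.
#' @param subject_id,trial_id identifier strings stored in the recording.
#' @return an object of class `emg_recording` with elements `time`, `emg`
#'   (channels x samples matrix), `force`, `activation_truth`,
#'   `sampling_rate`, `channel_names`, `subject_id`, `trial_id`.
#' @export
#' @examples
#' rec <- simulate_recording(seed = 1)
#' dim(rec$emg)
simulate_recording <- function(protocol = emg_protocol(), noise = noise_model(),
                               force = force_model(), rise_time = 0.5,
                               seed = NULL, subject_id = "S1", trial_id = "T1") {
  stopifnot(inherits(protocol, "emg_protocol"),
            inherits(noise, "emg_noise_model"),
            inherits(force, "emg_force_model"))
  fs <- protocol$sampling_rate
  if (noise$emg_band[2] >= fs / 2) stop_input("noise model `emg_band` exceeds Nyquist")
  a <- make_activation(protocol, rise_time)
  n <- length(a)
  t <- (seq_len(n) - 1) / fs
  nc <- protocol$n_channels
  gains <- rep_len(force$per_channel_gain, nc)

  out <- with_seed_(seed, {
    emg <- matrix(0, nrow = nc, ncol = n)
    pl_phase <- runif(1, 0, 2 * pi)  # powerline is common-mode across channels
    pl <- noise$powerline_amplitude * sin(2 * pi * noise$powerline_freq * t + pl_phase)
    for (c in seq_len(nc)) {
      carrier <- bandlimited_noise(n, fs, noise$emg_band)
      drift <- if (noise$baseline_drift_amplitude > 0) {
        noise$baseline_drift_amplitude *
          sin(2 * pi * runif(1, 0.05, 0.2) * t + runif(1, 0, 2 * pi))
      } else 0
      sn <- if (noise$sensor_noise_sd > 0) rnorm(n, sd = noise$sensor_noise_sd) else 0
      emg[c, ] <- gains[c] * a * carrier + noise$dc_offset + pl + drift + sn
    }
    lag_samp <- round(force$activation_lag * fs)
    a_lag <- if (lag_samp > 0) c(rep(0, lag_samp), a[seq_len(n - lag_samp)]) else a
    raw_f <- a_lag^force$activation_exponent
    # first-order low-pass (exponential smoothing), time constant in seconds
    alpha <- (1 / fs) / (force$time_constant + 1 / fs)
    f_smooth <- as.numeric(stats::filter(alpha * raw_f, 1 - alpha,
                                         method = "recursive", init = 0))
    fn <- if (force$force_noise_sd > 0) rnorm(n, sd = force$force_noise_sd) else 0
    list(emg = emg, force = force$max_force * f_smooth + fn)
  })

  ch <- default_channel_names(nc)
  rownames(out$emg) <- ch
  structure(list(time = t, emg = out$emg, force = out$force,
                 activation_truth = a, sampling_rate = fs,
                 channel_names = ch, subject_id = subject_id,
                 trial_id = trial_id),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %s/%s: %d channels (%s), %d samples @ %g Hz\n",
              x$subject_id, x$trial_id, nrow(x$emg),
              paste(x$channel_names, collapse = ", "),
              ncol(x$emg), x$sampling_rate))
  invisible(x)
}

#' Simulate a cohort of subjects
#'
#' Draws per-subject physiological/instrumental parameters (channel gains,
#' noise amplitudes, activation-force exponent, lag, peak force) from realistic
#' ranges, then simulates `protocol$trial_count` trials per subject that share
#' the subject's parameters but have independent noise realisations. All
#' randomness derives from the single master `seed` through deterministic
#' sub-seeds, so a cohort is exactly reproducible.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param protocol an [emg_protocol()].
#' @param seed master integer seed.
#' @param rise_time activation ramp in seconds.
#' @return list of `emg_recording` objects with ids `S1..Sn` x `T1..Tk`.
#' @export
#' @examples
#' cohort <- generate_cohort(2, seed = 1)
#' sapply(cohort, function(r) paste(r$subject_id, r$trial_id))
generate_cohort <- function(n_subjects, protocol = emg_protocol(), seed = NULL,
                            rise_time = 0.5) {
  if (n_subjects < 1) stop_input("`n_subjects` must be >= 1")
  nt <- protocol$trial_count
  seeds <- derive_seeds(seed, n_subjects * (nt + 1L))
  recs <- vector("list", n_subjects * nt)
  k <- 0L
  for (s in seq_len(n_subjects)) {
    pars <- with_seed_(seeds[(s - 1L) * (nt + 1L) + 1L], {
      list(gains = runif(protocol$n_channels, 0.6, 1.2),
           sensor_sd = runif(1, 0.005, 0.02),
           powerline = runif(1, 0.1, 0.3),
           dc = runif(1, 0.02, 0.08),
           drift = runif(1, 0.01, 0.03),
           exponent = runif(1, 1.0, 1.4),
           lag = runif(1, 0.02, 0.08),
           max_force = runif(1, 150, 300))
    })
    nm <- noise_model(powerline_amplitude = pars$powerline, dc_offset = pars$dc,
                      baseline_drift_amplitude = pars$drift,
                      sensor_noise_sd = pars$sensor_sd)
    fm <- force_model(max_force = pars$max_force,
                      activation_exponent = pars$exponent,
                      activation_lag = pars$lag,
                      per_channel_gain = pars$gains)
    for (tr in seq_len(nt)) {
      k <- k + 1L
      recs[[k]] <- simulate_recording(
        protocol, nm, fm, rise_time = rise_time,
        seed = seeds[(s - 1L) * (nt + 1L) + 1L + tr],
        subject_id = paste0("S", s), trial_id = paste0("T", tr))
    }
  }
  recs
}
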