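# Windowing, time-domain features, labelling, delay alignment.

test_that("segment counts follow the closed form", {
  expect_identical(nrow(segment(30000, window_spec(0.2, 0.1), 1000)), 299L)
  # one window exactly when L = S = n
  expect_identical(nrow(segment(500, window_spec(0.5, 0.5), 1000)), 1L)
  # sliding by one sample: n - L + 1 windows
  expect_identical(nrow(segment(100, window_spec(0.02, 0.001), 1000)), 81L)
  expect_error(segment(10, window_spec(0.2, 0.1), 1000), "shorter")
  # half-open ranges of the right length
  w <- segment(1000, window_spec(0.2, 0.1), 1000)
  expect_true(all(w$end - w$start + 1L == 200L))
})

test_that("features have their closed-form values on constant windows", {
  for (c_val in c(0, 0.5, 2)) {
    f <- window_features(rep(c_val, 50))
    expect_equal(unname(f[c("mav", "rms", "var", "wl", "zc")]),
                 c(c_val, c_val, 0, 0, 0))
    expect_equal(unname(f["iemg"]), 50 * c_val)
  }
})

test_that("alternating +-1 window gives WL = 6 and ZC = 3", {
  f <- window_features(c(1, -1, 1, -1), deadband = 0)
  expect_equal(unname(f["wl"]), 6)
  expect_equal(unname(f["zc"]), 3)
  expect_equal(unname(f["ssc"]), 2)
})

test_that("amplitude features are homogeneous in the signal scale", {
  withr::with_seed(7, x <- rnorm(200))
  f1 <- window_features(x)
  fk <- window_features(3 * x)
  expect_equal(unname(fk[c("mav", "rms", "iemg", "wl")]),
               unname(3 * f1[c("mav", "rms", "iemg", "wl")]))
  expect_equal(unname(fk["var"]), unname(9 * f1["var"]))
})

test_that("feature matrix dimensions match segmentation and channel count", {
  rec <- simulate_recording(seed = 2)
  env <- suppressMessages(preprocess_emg(rec))
  ft <- compute_features(env)
  expect_identical(nrow(ft), 299L)
  expect_identical(ncol(ft), 3L * 7L)
  fm <- build_feature_matrix(env, preprocess_force(rec))
  expect_identical(nrow(fm), 299L)
  expect_false(anyNA(fm))
  expect_true(all(fm$label %in% c(0L, 1L)))
})

test_that("labels reproduce the protocol schedule near the edges", {
  # idealised trapezoid force: threshold crossing sits within one window of
  # each protocol edge
  act <- make_activation(emg_protocol(), rise_time = 0.5)
  w <- segment(30000, window_spec(), 1000)
  fw <- vapply(seq_len(nrow(w)), function(i) mean(act[w$start[i]:w$end[i]]),
               numeric(1))
  lab <- label_windows(fw, 0.1)
  truth <- as.integer(vapply(seq_len(nrow(w)),
                             function(i) any(act[w$start[i]:w$end[i]] > 0),
                             logical(1)))
  flips <- which(lab != truth)
  # flipped windows hug an on/off edge (ramp portion below threshold)
  edges_s <- c(0, 5, 10, 15, 20, 25) * 1000
  near_edge <- vapply(flips, function(i) {
    min(abs(c(w$start[i], w$end[i]) - rep(edges_s, each = 2))) <= 600
  }, logical(1))
  expect_lte(length(flips), 12)
  expect_true(all(near_edge))

  # end-to-end: simulated force (with dynamics) stays close to the schedule
  rec <- simulate_recording(seed = 15)
  env <- suppressMessages(preprocess_emg(rec))
  frc <- preprocess_force(rec)
  frc <- align_force(frc, estimate_delay(env, frc), 1000)
  fm <- build_feature_matrix(env, frc, label_threshold = 0.1)
  truth2 <- vapply(seq_len(nrow(w)),
                   function(i) mean(rec$activation_truth[w$start[i]:w$end[i]]) > 0.1,
                   logical(1))
  expect_lte(sum(fm$label != as.integer(truth2)), 6 * 3)  # <= 3 per edge
})

test_that("labelling respects thresholds and degenerate inputs", {
  f <- c(0, 0, 1, 1, 0.04)
  expect_identical(label_windows(f, 0.5), c(0L, 0L, 1L, 1L, 0L))
  expect_identical(label_windows(f, 0.99), c(0L, 0L, 1L, 1L, 0L))
  expect_warning(l0 <- label_windows(rep(0, 4)), "all zero")
  expect_identical(l0, rep(0L, 4))
  expect_error(label_windows(f, 1.2), "threshold_fraction")
})

test_that("active and rest windows are separable by MAV alone", {
  fm <- cohort_feature_table(1, seed = 31)
  mav <- fm$vm_mav
  # best single threshold on the dominant channel's MAV
  ths <- quantile(mav, seq(0.05, 0.95, by = 0.01))
  acc <- vapply(ths, function(th) mean((mav > th) == (fm$label == 1)), numeric(1))
  expect_gt(max(acc), 0.95)
})

test_that("delay estimation recovers the simulated electromechanical lag", {
  fmod <- force_model(activation_lag = 0.08, force_noise_sd = 0)
  rec <- simulate_recording(force = fmod, seed = 41)
  env <- suppressMessages(preprocess_emg(rec))
  frc <- preprocess_force(rec)
  d <- estimate_delay(env, frc)
  # lag + first-order smoothing mean delay (~tau) modulo envelope smoothing
  expect_gt(d, 0.05)
  expect_lt(d, 0.35)
  aligned <- align_force(frc, d, 1000)
  expect_length(aligned, length(frc))
  expect_gt(cor(colMeans(env$values), aligned), cor(colMeans(env$values), frc))
})

test_that("sample-mode matrix decimates and labels consistently", {
  rec <- simulate_recording(seed = 16)
  env <- suppressMessages(preprocess_emg(rec))
  frc <- preprocess_force(rec)
  sm <- sample_matrix(env, frc, decimate_to = 50)
  expect_identical(nrow(sm), 1500L)
  expect_identical(ncol(sm), 3L + 4L)
  expect_true(all(sm$label %in% c(0L, 1L)))
})
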