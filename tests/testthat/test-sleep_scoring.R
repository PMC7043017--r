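test_that("band_power matches the analytic power of pure sinusoids", {
  fs <- 250
  tt <- seq(0, 10 - 1 / fs, 1 / fs)
  x <- 3 * sin(2 * pi * 2 * tt)
  expect_equal(band_power(x, fs, 0.5, 4), 3^2 / 2, tolerance = 0.01)
  expect_lt(band_power(x, fs, 4, 8), 1e-6)       # leakage only
  expect_equal(band_power(rep(0, fs * 10), fs, 0.5, 4), 0)
  # additivity over disjoint bands
  set.seed(2)
  y <- rnorm(fs * 10)
  expect_equal(band_power(y, fs, 0.5, 4) + band_power(y, fs, 4, 25),
               band_power(y, fs, 0.5, 25), tolerance = 1e-10)
  expect_error(band_power(y, fs, 10, 200), "domain error")
})

test_that("epoch_features recovers the analytic spectrum of toy epochs", {
  rec <- toy_recording(n_epochs = 2, fs = 200, eeg_freq = c(2, 6),
                       emg_sd = c(0, 0), activity = c(0, 0))
  f <- epoch_features(rec)
  expect_gt(f$delta_ratio[1], 0.99)              # 2 Hz epoch: all delta
  expect_lt(f$theta_ratio[1], 0.01)
  expect_gt(f$theta_ratio[2], 100)               # 6 Hz epoch: all theta
  expect_equal(f$emg_amplitude, c(0, 0))         # flat EMG
  expect_true(all(f$delta_ratio >= 0 & f$delta_ratio <= 1))
})

test_that("score_epoch implements the decision tree (truth-table oracle)", {
  th <- scoring_thresholds(emg_wake = 20, activity_wake = 1,
                           delta_ratio_sws = 0.5, theta_ratio_rem = 2)
  grid <- expand.grid(emg_amplitude = c(5, 25),
                      activity_count = c(0, 2),
                      delta_ratio = c(0.2, 0.8),
                      theta_ratio = c(0.5, 3))
  # independent exhaustive evaluation of the stated rules
  oracle <- apply(grid, 1, function(r) {
    if (r["emg_amplitude"] >= 20 || r["activity_count"] >= 1) "W"
    else if (r["delta_ratio"] >= 0.5) "S"
    else if (r["theta_ratio"] >= 2) "P"
    else "W"
  })
  expect_equal(score_epoch(grid, th), unname(oracle))
  # clear-cut cases for each rule
  expect_equal(score_epoch(data.frame(emg_amplitude = 100,
                                      activity_count = 5,
                                      delta_ratio = 0.9,
                                      theta_ratio = 5), th), "W")
  expect_equal(score_epoch(data.frame(emg_amplitude = 5,
                                      activity_count = 0,
                                      delta_ratio = 0.8,
                                      theta_ratio = 0.1), th), "S")
  expect_equal(score_epoch(data.frame(emg_amplitude = 5,
                                      activity_count = 0,
                                      delta_ratio = 0.2,
                                      theta_ratio = 3), th), "P")
})

test_that("raising the EMG threshold never increases wake epochs", {
  cfg <- sim_config(seed = 21, duration_h = 1)
  sim <- simulate_recording(cfg)
  f <- epoch_features(sim$recording)
  n_w <- sapply(c(5, 10, 20, 40, 80), function(e)
    sum(score_epoch(f, scoring_thresholds(emg_wake = e)) == "W"))
  expect_true(all(diff(n_w) <= 0))
})

test_that("calibration places the EMG threshold between the modes and honours overrides", {
  cfg <- sim_config(seed = 22, duration_h = 2)
  sim <- simulate_recording(cfg)
  f <- epoch_features(sim$recording)
  th <- calibrate_thresholds(sim$recording, f)
  # strictly between the sleep (10/5 uV) and wake (30 uV) EMG levels
  expect_gt(th$emg_wake, 10)
  expect_lt(th$emg_wake, 30)
  expect_equal(th$delta_ratio_sws, 0.5)
  expect_equal(th$theta_ratio_rem, 2)
  # full override is returned unchanged, no data needed
  th2 <- calibrate_thresholds(sim$recording,
                              overrides = list(emg_wake = 42,
                                               activity_wake = 2,
                                               delta_ratio_sws = 0.4,
                                               theta_ratio_rem = 1.5))
  expect_equal(unclass(th2),
               list(emg_wake = 42, activity_wake = 2,
                    delta_ratio_sws = 0.4, theta_ratio_rem = 1.5))
  # degenerate EMG falls back to a percentile with a warning
  flat <- recording("flat", eeg = rnorm(360000), fs_eeg = 100,
                    emg = rep(1, 360000), fs_emg = 100,
                    activity = rep(0, 360), start_clock = "2024-01-01 07:00:00")
  expect_warning(calibrate_thresholds(flat), "not clearly bimodal")
})

test_that("smoothing rules relabel wake-entered REM and flanked singletons", {
  # (a) P entered from W is relabeled W
  expect_equal(smooth_stages(c("S", "W", "P", "P", "S")),
               c("S", "W", "W", "W", "S"))
  # P entered from S is kept
  expect_equal(smooth_stages(c("W", "S", "P", "P", "W")),
               c("W", "S", "P", "P", "W"))
  # (b) isolated singleton flanked by identical stages
  expect_equal(smooth_stages(c("S", "W", "S")), c("S", "S", "S"))
  expect_equal(smooth_stages(c("W", "S", "W")), c("W", "W", "W"))
  # smoothing off reproduces raw decisions exactly
  cfg <- sim_config(seed = 23, duration_h = 1)
  sim <- simulate_recording(cfg)
  f <- epoch_features(sim$recording)
  th <- calibrate_thresholds(sim$recording, f)
  raw <- score_recording(sim$recording, th, smooth = FALSE, features = f)
  expect_equal(raw$stages, score_epoch(f, th))
})

test_that("scoring is deterministic for fixed thresholds", {
  cfg <- sim_config(seed = 24, duration_h = 1)
  sim <- simulate_recording(cfg)
  th <- scoring_thresholds(emg_wake = 18)
  h1 <- score_recording(sim$recording, th)
  h2 <- score_recording(sim$recording, th)
  expect_identical(h1$stages, h2$stages)
})
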