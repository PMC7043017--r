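test_that("sim_config validates its stochastic structure", {
  expect_s3_class(sim_config(), "sim_config")
  bad <- matrix(c(0, 0.5, 0.5, 1, 0, 0, 1, 0, 0), 3, 3, byrow = TRUE,
                dimnames = list(c("W", "S", "P"), c("W", "S", "P")))
  expect_error(sim_config(trans_light = bad), "W -> P")
  bad2 <- bad; bad2["W", ] <- c(0, 0.4, 0)
  expect_error(sim_config(trans_light = bad2), "row-stochastic")
})

test_that("hypnogram simulation is seed-deterministic and respects structure", {
  cfg <- sim_config(seed = 41, duration_h = 6)
  h1 <- simulate_hypnogram(cfg)
  h2 <- simulate_hypnogram(cfg)
  expect_identical(h1$stages, h2$stages)
  expect_equal(n_epochs(h1), 6 * 360)
  # generated hypnograms never contain a W -> P transition
  s <- h1$stages
  expect_false(any(s[-length(s)] == "W" & s[-1] == "P"))
  # wake-absorbing chain gives an all-W hypnogram
  absorbing <- matrix(c(1, 0, 0, 1, 0, 0, 1, 0, 0), 3, 3, byrow = TRUE,
                      dimnames = list(c("W", "S", "P"), c("W", "S", "P")))
  # (self-transition allowed here: W bout restarts forever)
  cfg_w <- sim_config(seed = 1, duration_h = 1, trans_light = absorbing,
                      trans_dark = absorbing, seq_rem_cluster_prob = 0)
  expect_true(all(simulate_hypnogram(cfg_w)$stages == "W"))
})

test_that("stage fractions match the semi-Markov stationary distribution", {
  # stationary time fraction of a semi-Markov chain: pi_i * m_i
  # normalized, with pi the embedded-chain stationary distribution
  h <- simulate_hypnogram(sim_config(seed = 43, duration_h = 240,
                                     start_clock = "2024-03-01 19:00:00",
                                     seq_rem_cluster_prob = 0))
  # restrict to dark epochs so a single transition regime applies
  dark <- clip_window(h, "19:00", "07:00")
  P <- sim_config()$trans_dark
  ev <- eigen(t(P))
  pi_embed <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi_embed <- pi_embed / sum(pi_embed)
  m <- sim_config()$bout_means_dark
  frac <- pi_embed * m / sum(pi_embed * m)
  emp <- as.numeric(table(factor(dark$stages, c("W", "S", "P")))) /
    n_epochs(dark)
  expect_lt(max(abs(emp - frac)), 0.02)
})

test_that("synthesized signals carry the state-conditioned structure", {
  cfg <- sim_config(seed = 44, duration_h = 1)
  h <- simulate_hypnogram(cfg)
  rec <- synthesize_signals(h, cfg)
  expect_identical(synthesize_signals(h, cfg)$eeg, rec$eeg)  # determinism
  f <- epoch_features(rec)
  s <- h$stages
  # SWS epochs: delta-dominant EEG
  expect_gt(min(f$delta_ratio[s == "S"]), 0.5)
  # REM epochs: zero activity, lowest EMG level
  expect_true(all(f$activity_count[s == "P"] == 0))
  expect_lt(mean(f$emg_amplitude[s == "P"]), mean(f$emg_amplitude[s == "S"]))
  expect_lt(mean(f$emg_amplitude[s == "S"]), mean(f$emg_amplitude[s == "W"]))
  # EEG total power close to the configured RMS^2
  expect_equal(mean(f$total_power), cfg$eeg_rms^2, tolerance = 0.1)
})

test_that("injected arousals are designed positives/negatives for the detector", {
  cfg <- sim_config(seed = 45, duration_h = 2)
  h <- simulate_hypnogram(cfg)
  aw <- detect_awakenings(h)
  ev <- data.frame(clock = aw$transition_clock[1:4],
                   peak_uv = c(320, 400, 100, 350),
                   with_activity = c(TRUE, TRUE, TRUE, FALSE))
  rec <- synthesize_signals(h, cfg, events = ev)
  res <- classify_exaggerated(detect_awakenings(h), rec)
  res <- res[match(ev$clock, res$transition_clock), ]
  expect_equal(res$exaggerated, c(TRUE, TRUE, FALSE, FALSE))
  # injection off a transition errors
  bad <- data.frame(clock = h$epoch_starts[which(h$stages == "S")[5]],
                    peak_uv = 300, with_activity = TRUE)
  expect_error(synthesize_signals(h, cfg, events = bad), "injection error")
})

test_that("latency simulation caps at 900 s and recovers the component means", {
  d <- simulate_latencies(seed = 46)
  expect_identical(d, simulate_latencies(seed = 46))
  expect_true(all(d$latency_s > 0 & d$latency_s <= 900))
  expect_equal(nrow(d), 7 * 23)
  # cap fixed point (sd -> 0 limit): draws at/above the mean hit the
  # 900 s cap exactly, the rest sit within sd of it
  d9 <- simulate_latencies(n_passive = 2, n_active = 2, mu_passive = 900,
                           mu_active = 900, sd = 1e-9, seed = 1)
  expect_true(all(abs(d9$latency_s - 900) < 1e-6))
  expect_true(any(d9$latency_s == 900))
  # law of large numbers on the per-animal means
  big <- simulate_latencies(n_passive = 1000, n_active = 1000, seed = 47)
  m <- tapply(big$latency_s, big$animal_id, mean)
  grp <- tapply(big$true_group, big$animal_id, `[`, 1)
  expect_lt(abs(mean(m[grp == "passive"]) - 540), 2)
  expect_lt(abs(mean(m[grp == "active"]) - 776), 2)
})

test_that("metric panels are balanced, deterministic, and carry effects", {
  d0 <- simulate_metric_panel(effects = 0, intercept_sd = 0, noise_sd = 0,
                              seed = 1)
  expect_true(all(d0$value == 0))
  expect_identical(simulate_metric_panel(seed = 2),
                   simulate_metric_panel(seed = 2))
  d <- simulate_metric_panel(groups = c("a", "b"),
                             effects = matrix(c(0, 0, 0, 0, 5, 5, 5, 5),
                                              2, 4, byrow = TRUE),
                             n_per_group = 8, seed = 3)
  expect_lt(mixed_anova(d)$table$p[1], 0.001)
  expect_equal(unname(table(d$group, d$timepoint))[1, 1], 8)
})

test_that("staging agreement degrades as band contrast is removed", {
  agree_at <- function(wS, wP, seed = 48) {
    w <- matrix(c(0, 0, 1,
                  wS, 0.1 * wS / 0.75, 1 - wS - 0.1 * wS / 0.75,
                  0.1 * wP / 0.75, wP, 1 - wP - 0.1 * wP / 0.75),
                3, 3, byrow = TRUE,
                dimnames = list(c("W", "S", "P"),
                                c("delta", "theta", "broad")))
    cfg <- sim_config(seed = seed, duration_h = 2, eeg_band_weights = w)
    sim <- simulate_recording(cfg)
    hyp <- score_recording(sim$recording)
    mean(hyp$stages == sim$hypnogram$stages)
  }
  a_hi <- agree_at(0.75, 0.75)
  a_md <- agree_at(0.40, 0.40)
  a_lo <- agree_at(0.15, 0.15)
  expect_gte(a_hi, a_md)
  expect_gte(a_md, a_lo)
  expect_gt(a_hi, 0.9)
})
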