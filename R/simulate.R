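# Ground-truth synthetic data: semi-Markov hypnograms with light/dark
# modulation, state-conditioned EEG/EMG/activity signals, injected
# arousal events, and bimodal defeat-latency tables. Every generator is
# a pure function of its configuration (which carries the seed).

#' Simulation configuration
#'
#' Defines a synthetic animal: the semi-Markov stage dynamics (embedded
#' transition matrices and mean bout lengths, separately for the light
#' and dark photoperiods), the state-conditioned signal model (EEG band
#' weights, EMG RMS levels, activity rates), REM clustering, and any
#' arousal events to inject. Defaults give roughly 70% sleep in the
#' light period and 70% wake in the dark period, delta-dominant EEG in
#' SWS, theta-dominant EEG in REM, broadband EEG in wake, high muscle
#' tone awake and atonia in REM.
#'
#' @param seed Integer seed; all generators derive their randomness
#'   from it.
#' @param duration_h Recording length in hours (default 24).
#' @param fs_eeg,fs_emg Sampling rates in Hz (default 250).
#' @param epoch_len_s Epoch length in seconds (default 10).
#' @param start_clock Clock time of the first sample.
#' @param lights_on,lights_off Light schedule (07:00 / 19:00).
#' @param trans_light,trans_dark 3x3 row-stochastic embedded transition
#'   matrices over (W, S, P), zero diagonal, with `W -> P` forbidden
#'   (REM is entered only from SWS).
#' @param bout_means_light,bout_means_dark Mean bout lengths in epochs,
#'   named `W`, `S`, `P`.
#' @param eeg_band_weights 3x3 matrix (rows W, S, P) of relative EEG
#'   power in the delta (0.5-4 Hz), theta (4-8 Hz) and broad
#'   (0.5-25 Hz) bands; rows sum to 1.
#' @param eeg_rms Total EEG RMS amplitude in microvolts.
#' @param emg_rms Named EMG RMS per state in microvolts
#'   (wake high, SWS low, REM lowest).
#' @param activity_rate Named Poisson rate of activity counts per epoch
#'   (zero for the sleep states).
#' @param seq_rem_cluster_prob Probability that a REM bout is followed,
#'   after a short (<= 180 s) SWS gap, by another REM bout.
#' @param arousal_events Optional data.frame of events to inject (see
#'   [synthesize_signals()]): columns `clock`, `peak_uv`,
#'   `with_activity`.
#' @param animal_id Identifier for the simulated animal.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, duration_h = 24, fs_eeg = 250,
                       fs_emg = 250, epoch_len_s = 10,
                       start_clock = "2024-03-01 07:00:00",
                       lights_on = "07:00", lights_off = "19:00",
                       trans_light = NULL, trans_dark = NULL,
                       bout_means_light = c(W = 9, S = 18, P = 6),
                       bout_means_dark = c(W = 30, S = 10, P = 4),
                       eeg_band_weights = NULL, eeg_rms = 100,
                       emg_rms = c(W = 30, S = 10, P = 5),
                       activity_rate = c(W = 3, S = 0, P = 0),
                       seq_rem_cluster_prob = 0.3,
                       arousal_events = NULL, animal_id = "sim") {
  def_trans <- matrix(c(0, 1, 0,
                        0.6, 0, 0.4,
                        0.5, 0.5, 0), 3, 3, byrow = TRUE,
                      dimnames = list(STAGES, STAGES))
  trans_light <- trans_light %||% def_trans
  trans_dark <- trans_dark %||% def_trans
  eeg_band_weights <- eeg_band_weights %||%
    matrix(c(0.00, 0.00, 1.00,
             0.75, 0.10, 0.15,
             0.10, 0.75, 0.15), 3, 3, byrow = TRUE,
           dimnames = list(STAGES, c("delta", "theta", "broad")))
  for (m in list(trans_light, trans_dark)) {
    if (any(abs(rowSums(m) - 1) > 1e-9) || any(m < 0))
      stop("config error: transition matrices must be row-stochastic")
    if (m["W", "P"] > 0)
      stop("config error: REM must be entered only from SWS (W -> P ",
           "transitions are forbidden)")
  }
  if (any(abs(rowSums(eeg_band_weights) - 1) > 1e-9))
    stop("config error: EEG band weight rows must sum to 1")
  if (any(c(bout_means_light, bout_means_dark) < 1))
    stop("config error: mean bout lengths must be >= 1 epoch")
  if (any(c(emg_rms, activity_rate, eeg_rms) < 0))
    stop("config error: rates and amplitudes must be >= 0")
  structure(list(seed = as.integer(seed), duration_h = duration_h,
                 fs_eeg = fs_eeg, fs_emg = fs_emg,
                 epoch_len_s = epoch_len_s, start_clock = start_clock,
                 lights_on = lights_on, lights_off = lights_off,
                 trans_light = trans_light, trans_dark = trans_dark,
                 bout_means_light = bout_means_light,
                 bout_means_dark = bout_means_dark,
                 eeg_band_weights = eeg_band_weights, eeg_rms = eeg_rms,
                 emg_rms = emg_rms, activity_rate = activity_rate,
                 seq_rem_cluster_prob = seq_rem_cluster_prob,
                 arousal_events = arousal_events,
                 animal_id = animal_id),
            class = "sim_config")
}

#' Simulate a ground-truth hypnogram
#'
#' Draws a semi-Markov stage sequence: bout lengths are geometric with
#' the photoperiod- and state-specific means, and the next state is
#' drawn from the photoperiod's embedded transition matrix (evaluated at
#' the bout's first epoch). After a REM bout, with probability
#' `seq_rem_cluster_prob` a short SWS gap of at most 18 epochs (180 s)
#' is inserted and REM resumes, producing the clustering of sequential
#' REM episodes seen in rodent sleep.
#'
#' @param cfg A [sim_config()].
#' @return A [hypnogram()] of `duration_h * 360` epochs.
#' @export
simulate_hypnogram <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- floor(cfg$duration_h * 3600 / cfg$epoch_len_s)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  start <- parse_clock(cfg$start_clock)
  tod0 <- tod_of(start)
  on_s <- parse_tod(cfg$lights_on); off_s <- parse_tod(cfg$lights_off)
  stages <- character(n)
  i <- 1L; state <- "W"
  while (i <= n) {
    tod_i <- (tod0 + (i - 1) * cfg$epoch_len_s) %% 86400
    light <- in_tod_window(tod_i, on_s, off_s)
    bm <- if (light) cfg$bout_means_light else cfg$bout_means_dark
    tm <- if (light) cfg$trans_light else cfg$trans_dark
    len <- stats::rgeom(1, 1 / bm[state]) + 1L
    j <- min(i + len - 1L, n)
    stages[i:j] <- state
    i <- j + 1L
    if (state == "P" && stats::runif(1) < cfg$seq_rem_cluster_prob) {
      gap <- sample.int(18L, 1)
      j <- min(i + gap - 1L, n)
      if (i <= n) stages[i:j] <- "S"
      i <- j + 1L
      state <- "P"
    } else {
      state <- sample(STAGES, 1, prob = tm[state, ])
    }
  }
  hypnogram(stages, start_clock = start, animal_id = cfg$animal_id,
            epoch_len_s = cfg$epoch_len_s)
}

# Per-bin one-sided PSD gain vector for an epoch of n samples at fs,
# realizing band weights w = (delta, theta, broad) at total power rms^2.
.psd_gain <- function(n, fs, w, rms) {
  bands <- list(c(0.5, 4), c(4, 8), c(0.5, 25))
  kmax <- floor(n / 2)
  f <- (1:kmax) * fs / n
  p <- numeric(kmax)
  for (b in 1:3) {
    sel <- f >= bands[[b]][1] & f < bands[[b]][2]
    if (w[b] > 0) p[sel] <- p[sel] + w[b] * rms^2 / sum(sel)
  }
  g <- numeric(n)
  g[2:(kmax + 1)] <- sqrt(p * n / 2)
  if (n %% 2 == 0) {
    g[kmax + 1] <- sqrt(p[kmax] * n)          # unique Nyquist bin
    if (kmax > 1) g[n:(n - kmax + 2)] <- g[2:kmax]
  } else g[n:(n - kmax + 1)] <- g[2:(kmax + 1)]
  g
}

#' Synthesize EEG/EMG/activity signals for a hypnogram
#'
#' Per epoch, conditioned on its stage: the EEG is Gaussian noise
#' spectrally shaped to the stage's band weights (white noise filtered
#' in the frequency domain), the EMG is white noise at the stage's RMS
#' level, and the activity count is Poisson at the stage's rate.
#' Arousal events listed in `events` (or in the configuration) add a
#' one-second EMG burst with the requested peak amplitude, starting 2 s
#' after a designated sleep-to-wake transition; events with
#' `with_activity = TRUE` guarantee a positive activity count in the
#' transition epoch, events with `with_activity = FALSE` force it to
#' zero. An event whose clock time is not a sleep-to-wake transition of
#' the hypnogram is an error.
#'
#' @param hyp A [hypnogram()] (typically from [simulate_hypnogram()]).
#' @param cfg The [sim_config()].
#' @param events Optional arousal-event data.frame with columns `clock`
#'   (POSIXct or string), `peak_uv`, `with_activity`; defaults to
#'   `cfg$arousal_events`.
#' @return A [recording()].
#' @export
synthesize_signals <- function(hyp, cfg, events = cfg$arousal_events) {
  stopifnot(inherits(cfg, "sim_config"))
  n_ep <- n_epochs(hyp)
  ns_eeg <- round(cfg$fs_eeg * cfg$epoch_len_s)
  ns_emg <- round(cfg$fs_emg * cfg$epoch_len_s)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 1L)
  eeg <- numeric(n_ep * ns_eeg)
  emg <- stats::rnorm(n_ep * ns_emg) *
    rep(cfg$emg_rms[hyp$stages], each = ns_emg)
  activity <- stats::rpois(n_ep, cfg$activity_rate[hyp$stages])
  chunk <- 512L
  for (st in STAGES) {
    idx <- which(hyp$stages == st)
    if (!length(idx)) next
    g <- .psd_gain(ns_eeg, cfg$fs_eeg, cfg$eeg_band_weights[st, ],
                   cfg$eeg_rms)
    for (lo in seq(1L, length(idx), by = chunk)) {
      ii <- idx[lo:min(lo + chunk - 1L, length(idx))]
      W <- matrix(stats::rnorm(ns_eeg * length(ii)), nrow = ns_eeg)
      X <- stats::mvfft(W) * g
      Y <- Re(stats::mvfft(X, inverse = TRUE)) / ns_eeg
      pos <- as.vector(outer(seq_len(ns_eeg), (ii - 1) * ns_eeg, "+"))
      eeg[pos] <- as.vector(Y)
    }
  }
  if (!is.null(events) && nrow(events)) {
    ev_clock <- parse_clock(events$clock)
    ep0 <- as.numeric(hyp$epoch_starts[1])
    for (k in seq_len(nrow(events))) {
      j <- round((as.numeric(ev_clock[k]) - ep0) / cfg$epoch_len_s) + 1L
      ok <- j >= 2 && j <= n_ep &&
        abs(as.numeric(hyp$epoch_starts[j]) - as.numeric(ev_clock[k])) < 1e-6 &&
        hyp$stages[j] == "W" && hyp$stages[j - 1] %in% c("S", "P")
      if (!ok)
        stop("injection error: event ", format_clock(ev_clock[k]),
             " is not at a sleep-to-wake transition")
      t_burst <- round(2 * cfg$fs_emg)
      nb <- round(1 * cfg$fs_emg)
      env <- 0.5 - 0.5 * cos(2 * pi * seq_len(nb) / nb)
      burst <- events$peak_uv[k] * env * sin(2 * pi * 20 * seq_len(nb) / cfg$fs_emg)
      pos <- (j - 1L) * ns_emg + t_burst + seq_len(nb)
      emg[pos] <- emg[pos] + burst
      activity[j] <- if (isTRUE(events$with_activity[k]))
        max(1, activity[j]) else 0
    }
  }
  recording(animal_id = hyp$animal_id, eeg = eeg, fs_eeg = cfg$fs_eeg,
            emg = emg, fs_emg = cfg$fs_emg, activity = activity,
            activity_interval_s = cfg$epoch_len_s,
            start_clock = hyp$epoch_starts[1],
            lights_on = cfg$lights_on, lights_off = cfg$lights_off)
}

#' Simulate a hypnogram and its recording together
#'
#' @param cfg A [sim_config()].
#' @return List with elements `hypnogram` (ground truth) and
#'   `recording`.
#' @export
simulate_recording <- function(cfg) {
  hyp <- simulate_hypnogram(cfg)
  list(hypnogram = hyp, recording = synthesize_signals(hyp, cfg))
}

#' Simulate bimodal defeat-latency sessions
#'
#' Seven daily sessions per animal. Each day's latency is normal around
#' the animal's group mean, floored at 1 s and capped at 900 s (the
#' no-defeat cap of the resident-intruder protocol). Defaults use the
#' passive/active group means of 540 s and 776 s.
#'
#' @param n_passive,n_active Animals per generating component.
#' @param mu_passive,mu_active Component means in seconds (in
#'   (0, 900]).
#' @param sd Daily latency standard deviation in seconds.
#' @param seed Integer seed.
#' @return Data.frame with columns `animal_id`, `true_group`, `day`,
#'   `latency_s` (7 rows per animal).
#' @export
simulate_latencies <- function(n_passive = 15, n_active = 8,
                               mu_passive = 540, mu_active = 776,
                               sd = 80, seed = 1L) {
  if (any(c(mu_passive, mu_active) <= 0 | c(mu_passive, mu_active) > 900))
    stop("component means must lie in (0, 900]")
  if (sd <= 0) stop("sd must be > 0")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- n_passive + n_active
  grp <- rep(c("passive", "active"), c(n_passive, n_active))
  mu <- rep(c(mu_passive, mu_active), c(n_passive, n_active))
  lat <- pmin(900, pmax(1, stats::rnorm(7 * n, rep(mu, each = 7), sd)))
  data.frame(animal_id = rep(sprintf("rat%02d", seq_len(n)), each = 7),
             true_group = rep(grp, each = 7),
             day = rep(1:7, n), latency_s = lat)
}

#' Simulate a balanced outcome panel for the mixed ANOVA
#'
#' `value = cell effect + animal random intercept + noise`, with a
#' balanced group-by-timepoint design.
#'
#' @param groups Character vector of group labels.
#' @param timepoints Character vector of timepoint labels.
#' @param effects Matrix of cell means (`length(groups)` x
#'   `length(timepoints)`), or a single number recycled.
#' @param n_per_group Animals per group.
#' @param intercept_sd SD of the per-animal random intercept.
#' @param noise_sd Residual SD.
#' @param seed Integer seed.
#' @return Long data.frame with columns `animal_id`, `group`,
#'   `timepoint`, `value`.
#' @export
simulate_metric_panel <- function(groups = c("control", "passive", "active"),
                                  timepoints = c("day1", "day4", "day7",
                                                 "twoweeks"),
                                  effects = 0, n_per_group = 8,
                                  intercept_sd = 1, noise_sd = 1,
                                  seed = 1L) {
  ng <- length(groups); nt <- length(timepoints)
  eff <- matrix(effects, ng, nt)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- ng * n_per_group
  ids <- sprintf("a%03d", seq_len(n))
  grp <- rep(groups, each = n_per_group)
  b <- stats::rnorm(n, 0, intercept_sd)
  out <- expand.grid(animal_id = ids, timepoint = timepoints,
                     stringsAsFactors = FALSE)
  out$group <- grp[match(out$animal_id, ids)]
  gi <- match(out$group, groups); ti <- match(out$timepoint, timepoints)
  out$value <- eff[cbind(gi, ti)] + b[match(out$animal_id, ids)] +
    stats::rnorm(nrow(out), 0, noise_sd)
  out[, c("animal_id", "group", "timepoint", "value")]
}
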