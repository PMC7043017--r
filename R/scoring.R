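# Automated sleep staging: per-epoch spectral/EMG/activity features and
# a deterministic threshold decision tree assigning W / S / P.

#' Band power of a signal slice
#'
#' Integrated one-sided periodogram power over `[lo, hi)` Hz, computed
#' from a single Hann-tapered FFT of the slice, in the squared units of
#' the input (microvolts squared for EEG). Bins are assigned to a band
#' by their center frequency, so power is additive over disjoint bands.
#'
#' @param x Numeric signal slice (one scoring epoch).
#' @param fs Sampling rate in Hz.
#' @param lo,hi Band edges in Hz; `0 <= lo < hi <= fs/2`.
#' @return Band power (variance units).
#' @export
#' @examples
#' fs <- 250; t <- seq(0, 10 - 1/fs, 1/fs)
#' band_power(3 * sin(2 * pi * 2 * t), fs, 0.5, 4)  # ~ 3^2/2 = 4.5
band_power <- function(x, fs, lo, hi) {
  if (lo < 0 || hi <= lo || hi > fs / 2 + 1e-9)
    stop("domain error: band must satisfy 0 <= lo < hi <= fs/2")
  as.numeric(.band_powers(matrix(x, ncol = 1), fs, list(c(lo, hi))))
}

# One-sided Hann periodogram band powers for epochs stored column-wise.
# Returns a length(bands) x ncol(xmat) matrix.
.band_powers <- function(xmat, fs, bands) {
  n <- nrow(xmat)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)   # Hann taper
  xmat <- sweep(xmat, 2, colMeans(xmat)) * w
  X <- stats::mvfft(xmat)
  kmax <- floor(n / 2)
  pw <- 2 * (Mod(X[2:(kmax + 1), , drop = FALSE])^2) / (n * sum(w^2))
  if (n %% 2 == 0) pw[kmax, ] <- pw[kmax, ] / 2     # Nyquist bin unique
  f <- (1:kmax) * fs / n
  out <- matrix(0, length(bands), ncol(xmat))
  for (b in seq_along(bands)) {
    sel <- f >= bands[[b]][1] & f < bands[[b]][2]
    out[b, ] <- colSums(pw[sel, , drop = FALSE])
  }
  out
}

#' Per-epoch staging features
#'
#' For every 10-s epoch of the recording: delta-band power, theta-band
#' power, total power, the delta ratio (delta / total power, the SWS
#' indicator), the theta ratio (theta / delta power, the REM indicator),
#' the EMG amplitude (RMS of the mean-subtracted EMG slice) and the
#' activity count.
#'
#' @param rec A [recording()].
#' @param epochs Optional epoch table from [epochize()] (recomputed if
#'   omitted).
#' @param delta,theta,total Band edges in Hz. The delta band defaults to
#'   0.5-4 Hz so that the delta ratio stays in `[0, 1]`; a wider
#'   0.05-4 Hz variant can be selected by passing `delta = c(0.05, 4)`.
#' @param chunk Epochs per FFT block (memory control).
#' @return A data.frame with one row per epoch: `epoch`, `start_clock`,
#'   `delta_power`, `theta_power`, `total_power`, `delta_ratio`,
#'   `theta_ratio`, `emg_amplitude`, `activity_count`.
#' @export
epoch_features <- function(rec, epochs = NULL,
                           delta = c(0.5, 4), theta = c(4, 8),
                           total = c(0.5, 25), chunk = 1024L) {
  if (is.null(epochs)) epochs <- epochize(rec)
  n_ep <- nrow(epochs)
  if (n_ep == 0) stop("no epochs to featurize")
  ns_eeg <- epochs$i1_eeg[1] - epochs$i0_eeg[1] + 1L
  ns_emg <- epochs$i1_emg[1] - epochs$i0_emg[1] + 1L
  bands <- list(delta, theta, total)
  pw <- matrix(NA_real_, 3, n_ep)
  emg_amp <- numeric(n_ep)
  for (lo_ep in seq(1L, n_ep, by = chunk)) {
    hi_ep <- min(lo_ep + chunk - 1L, n_ep)
    idx <- lo_ep:hi_ep
    eeg_m <- matrix(rec$eeg[epochs$i0_eeg[lo_ep]:epochs$i1_eeg[hi_ep]],
                    nrow = ns_eeg)
    if (anyNA(eeg_m))
      stop("feature error: NaN samples in epoch ",
           idx[which(colSums(is.na(eeg_m)) > 0)[1]])
    pw[, idx] <- .band_powers(eeg_m, rec$fs_eeg, bands)
    emg_m <- matrix(rec$emg[epochs$i0_emg[lo_ep]:epochs$i1_emg[hi_ep]],
                    nrow = ns_emg)
    emg_amp[idx] <- sqrt(colMeans(sweep(emg_m, 2, colMeans(emg_m))^2))
  }
  delta_ratio <- ifelse(pw[3, ] > 0, pw[1, ] / pw[3, ], 0)
  theta_ratio <- ifelse(pw[1, ] > 0, pw[2, ] / pw[1, ],
                        ifelse(pw[2, ] > 0, Inf, 0))
  data.frame(epoch = epochs$epoch, start_clock = epochs$start_clock,
             delta_power = pw[1, ], theta_power = pw[2, ],
             total_power = pw[3, ], delta_ratio = delta_ratio,
             theta_ratio = theta_ratio, emg_amplitude = emg_amp,
             activity_count = epochs$activity_count)
}

#' Staging thresholds
#'
#' The free parameters of the staging decision tree: an epoch is scored
#' wake when its EMG amplitude or activity count reaches the wake
#' thresholds; otherwise SWS when the delta ratio is high, REM when the
#' theta ratio is high, and wake as the fallback.
#'
#' @param emg_wake EMG RMS amplitude (microvolts) at or above which an
#'   epoch is wake. Usually set by [calibrate_thresholds()].
#' @param activity_wake Activity counts at or above which an epoch is
#'   wake (default 1, i.e. any movement).
#' @param delta_ratio_sws Delta-ratio threshold for SWS (default 0.5).
#' @param theta_ratio_rem Theta-ratio threshold for REM (default 2).
#' @return An object of class `scoring_thresholds`.
#' @export
scoring_thresholds <- function(emg_wake, activity_wake = 1,
                               delta_ratio_sws = 0.5,
                               theta_ratio_rem = 2) {
  if (emg_wake <= 0 || delta_ratio_sws <= 0 || theta_ratio_rem <= 0 ||
      activity_wake < 1)
    stop("thresholds must be positive (activity threshold >= 1 count)")
  structure(list(emg_wake = emg_wake, activity_wake = activity_wake,
                 delta_ratio_sws = delta_ratio_sws,
                 theta_ratio_rem = theta_ratio_rem),
            class = "scoring_thresholds")
}

#' @export
print.scoring_thresholds <- function(x, ...) {
  cat(sprintf(paste0("<scoring_thresholds> EMG wake >= %.3g uV; ",
                     "activity wake >= %g; delta ratio SWS >= %.3g; ",
                     "theta ratio REM >= %.3g\n"),
              x$emg_wake, x$activity_wake, x$delta_ratio_sws,
              x$theta_ratio_rem))
  invisible(x)
}

#' Score epochs from features
#'
#' Applies the staging decision tree, vectorized over epochs:
#' (1) high EMG amplitude or any activity implies wake (W);
#' (2) otherwise a high delta ratio implies slow-wave sleep (S);
#' (3) otherwise a high theta ratio implies REM sleep (P);
#' (4) otherwise the epoch falls back to W (conservative against
#' inflating sleep). Deterministic for fixed thresholds.
#'
#' @param features Data.frame from [epoch_features()] (or any frame with
#'   columns `emg_amplitude`, `activity_count`, `delta_ratio`,
#'   `theta_ratio`).
#' @param th A [scoring_thresholds()].
#' @return Character vector of stages over `{"W","S","P"}`.
#' @export
score_epoch <- function(features, th) {
  stopifnot(inherits(th, "scoring_thresholds"))
  ifelse(features$emg_amplitude >= th$emg_wake |
           features$activity_count >= th$activity_wake, "W",
         ifelse(features$delta_ratio >= th$delta_ratio_sws, "S",
                ifelse(features$theta_ratio >= th$theta_ratio_rem, "P",
                       "W")))
}

#' Calibrate staging thresholds from a recording
#'
#' The EMG wake threshold is data-driven: the per-epoch log EMG
#' amplitudes of a recording that samples both wake and sleep are
#' bimodal (high muscle tone awake, low tone asleep), and the threshold
#' is placed at the midpoint between the two modes (estimated by
#' two-means on the log amplitudes). If the distribution is degenerate
#' or the modes are not separated, the 60th percentile is used instead,
#' with a warning. The ratio thresholds default to 0.5 (delta) and 2
#' (theta). All four values can be overridden.
#'
#' @param rec A [recording()] of at least one hour.
#' @param features Optional precomputed [epoch_features()] table.
#' @param overrides Named list giving any of `emg_wake`,
#'   `activity_wake`, `delta_ratio_sws`, `theta_ratio_rem` to fix.
#' @return A [scoring_thresholds()].
#' @export
calibrate_thresholds <- function(rec, features = NULL, overrides = list()) {
  defaults <- list(activity_wake = 1, delta_ratio_sws = 0.5,
                   theta_ratio_rem = 2)
  if (!is.null(overrides$emg_wake)) {
    v <- utils::modifyList(defaults, overrides)
    return(scoring_thresholds(v$emg_wake, v$activity_wake,
                              v$delta_ratio_sws, v$theta_ratio_rem))
  }
  if (duration_s(rec) < 3600)
    stop("calibration requires at least 1 h of recording")
  if (is.null(features)) features <- epoch_features(rec)
  amp <- features$emg_amplitude
  lamp <- log(pmax(amp, 1e-12))
  emg_wake <- NULL
  if (stats::sd(lamp) > 1e-8) {
    km <- tryCatch(stats::kmeans(lamp, centers = stats::quantile(lamp, c(0.25, 0.75)),
                                 iter.max = 100),
                   error = function(e) NULL)
    if (!is.null(km) && abs(diff(sort(km$centers))) > log(1.5))
      emg_wake <- exp(mean(km$centers))
  }
  if (is.null(emg_wake)) {
    warning("EMG amplitude distribution not clearly bimodal; ",
            "falling back to the 60th percentile")
    emg_wake <- as.numeric(stats::quantile(amp, 0.60))
    if (emg_wake <= 0) emg_wake <- 1e-6
  }
  v <- utils::modifyList(c(defaults, list(emg_wake = emg_wake)), overrides)
  scoring_thresholds(v$emg_wake, v$activity_wake, v$delta_ratio_sws,
                     v$theta_ratio_rem)
}

#' Hypnogram smoothing rules
#'
#' Two post-rules applied in order: (a) any P epoch whose previous non-P
#' stage is W is relabeled W, enforcing that REM is entered only from
#' SWS; (b) an isolated single-epoch stage flanked on both sides by an
#' identical stage is relabeled to the flanking stage.
#'
#' @param stages Character vector over `{"W","S","P"}`.
#' @return Smoothed stage vector of the same length.
#' @export
smooth_stages <- function(stages) {
  n <- length(stages)
  # (a) previous non-P stage, from the raw sequence
  last_non_p <- NA_character_
  for (i in seq_len(n)) {
    if (stages[i] == "P") {
      if (identical(last_non_p, "W")) stages[i] <- "W"
    } else last_non_p <- stages[i]
  }
  # (b) flanked singletons, simultaneous pass
  if (n >= 3) {
    i <- 2:(n - 1)
    fix <- stages[i - 1] == stages[i + 1] & stages[i] != stages[i - 1]
    stages[i][fix] <- stages[i - 1][fix]
  }
  stages
}

#' Score a whole recording into a hypnogram
#'
#' Computes per-epoch features, calibrates thresholds unless supplied,
#' applies the staging decision tree to every epoch, and optionally the
#' smoothing rules of [smooth_stages()]. Smoothing is off by default so
#' that metric computations see the raw per-epoch decisions.
#'
#' @param rec A [recording()].
#' @param th Optional [scoring_thresholds()]; calibrated from the
#'   recording when `NULL`.
#' @param smooth Apply [smooth_stages()] (default `FALSE`).
#' @param features Optional precomputed [epoch_features()] table.
#' @return A [hypnogram()].
#' @export
score_recording <- function(rec, th = NULL, smooth = FALSE,
                            features = NULL) {
  epochs <- epochize(rec)
  if (is.null(features)) features <- epoch_features(rec, epochs)
  if (is.null(th)) th <- calibrate_thresholds(rec, features)
  stages <- score_epoch(features, th)
  if (smooth) stages <- smooth_stages(stages)
  hypnogram(stages, start_clock = rec$start_clock,
            animal_id = rec$animal_id)
}
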