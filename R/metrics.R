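# Hypnogram-level outcome measures: state-time percentages, awakenings,
# exaggerated motor responses at awakening, and REM-sleep continuity
# (single vs sequential episodes).

#' State-time percentages in a window
#'
#' Percent of window time in wake, SWS and REM, computed from epoch
#' counts. Because epochs partition the window, the three percentages
#' sum to exactly 100.
#'
#' @param hyp A [hypnogram()].
#' @param window Optional time-of-day window `c(start, end)` passed to
#'   [clip_window()]; `NULL` uses the whole hypnogram.
#' @return Named numeric vector `c(pct_wake, pct_sws, pct_rem)`.
#' @export
#' @examples
#' h <- hypnogram(c(rep("W",6), rep("S",3), "P"))
#' state_percentages(h)  # 60 30 10
state_percentages <- function(hyp, window = NULL) {
  if (!is.null(window)) hyp <- clip_window(hyp, window[1], window[2])
  n <- n_epochs(hyp)
  if (n == 0) stop("empty window")
  cnt <- table(factor(hyp$stages, STAGES))
  out <- 100 * as.numeric(cnt) / n
  # the REM share is taken as the complement so the partition identity
  # pct_wake + pct_sws + pct_rem == 100 holds exactly in floating point
  out[3] <- 100 - out[1] - out[2]
  names(out) <- c("pct_wake", "pct_sws", "pct_rem")
  out
}

#' Change from baseline in percentage points
#'
#' @param day_pct,baseline_pct Percentages in `[0, 100]`. The baseline
#'   value is conventionally the mean over the two baseline days.
#' @return `day_pct - baseline_pct` (percentage points).
#' @export
change_from_baseline <- function(day_pct, baseline_pct) {
  if (any(day_pct < 0 | day_pct > 100 | baseline_pct < 0 | baseline_pct > 100))
    stop("percentages must lie in [0, 100]")
  day_pct - baseline_pct
}

#' Detect awakenings (sleep-to-wake transitions)
#'
#' An awakening is any transition from a sleep epoch (S or P) to a W
#' epoch, at epoch resolution. The transition is attributed to the
#' clock time of the first W epoch, which must lie inside the window;
#' the prior stage is the stage of the epoch immediately before.
#'
#' @param hyp A [hypnogram()].
#' @param window Optional time-of-day window `c(start, end)` filtering
#'   transitions (half-open, wraps midnight).
#' @return A data.frame with one row per awakening: `transition_clock`
#'   (POSIXct), `prior_stage` (`"S"` or `"P"`).
#' @export
detect_awakenings <- function(hyp, window = NULL) {
  s <- hyp$stages
  n <- length(s)
  idx <- which(s[-n] %in% c("S", "P") & s[-1] == "W") + 1L
  if (!is.null(window)) {
    w <- parse_tod(window)
    idx <- idx[in_tod_window(tod_of(hyp$epoch_starts[idx]), w[1], w[2])]
  }
  data.frame(transition_clock = hyp$epoch_starts[idx],
             prior_stage = s[idx - 1L])
}

#' Classify awakenings as exaggerated motor responses
#'
#' An awakening is exaggerated when, within the first `horizon` seconds
#' after the transition, the nuchal EMG burst crosses the preset
#' threshold (default 200 microvolts, applied to the absolute value of
#' the mean-subtracted EMG) AND there is concurrent locomotor activity
#' (any positive activity count in the same horizon). Both criteria are
#' required.
#'
#' @param events Awakening table from [detect_awakenings()].
#' @param rec The [recording()] providing EMG and activity.
#' @param threshold EMG threshold in microvolts (default 200).
#' @param horizon Seconds after the transition to examine (default 10).
#' @return `events` with added columns `peak_emg_10s`,
#'   `concurrent_activity`, `exaggerated`.
#' @export
classify_exaggerated <- function(events, rec, threshold = 200,
                                 horizon = 10) {
  validate_recording(rec)
  n_ev <- nrow(events)
  peak <- conc <- rep(NA_real_, n_ev)
  t0 <- as.numeric(events$transition_clock) - as.numeric(rec$start_clock)
  n_emg <- length(rec$emg)
  truncated <- FALSE
  for (k in seq_len(n_ev)) {
    i0 <- floor(t0[k] * rec$fs_emg) + 1
    i1 <- min(floor((t0[k] + horizon) * rec$fs_emg), n_emg)
    if (i0 > n_emg) stop("awakening lies outside the recording")
    if (i1 < floor((t0[k] + horizon) * rec$fs_emg)) truncated <- TRUE
    seg <- rec$emg[i0:i1]
    peak[k] <- max(abs(seg - mean(seg)))
    a0 <- floor(t0[k] / rec$activity_interval_s) + 1
    a1 <- min(ceiling((t0[k] + horizon) / rec$activity_interval_s),
              length(rec$activity))
    conc[k] <- sum(rec$activity[a0:a1]) > 0
  }
  if (truncated)
    warning("EMG horizon truncated at end of recording; ",
            "evaluated on the available span")
  events$peak_emg_10s <- peak
  events$concurrent_activity <- as.logical(conc)
  events$exaggerated <- peak > threshold & events$concurrent_activity
  events
}

#' Segment REM episodes and label them single or sequential
#'
#' A REM episode is a maximal run of P epochs. Episodes with at least
#' one epoch inside the window are kept; gaps are computed from the full
#' episode extents. An episode is sequential (`seq`) when the next kept
#' episode starts 180 s (3 min) or less after it ends, and single
#' (`sin`) when the gap is longer. The last episode in the window has
#' no follower and is labeled `sin`.
#'
#' @param hyp A [hypnogram()].
#' @param window Optional time-of-day window `c(start, end)`.
#' @return A data.frame with one row per episode: `start_clock`,
#'   `end_clock`, `n_epochs`, `gap_to_next_s` (NA for the last), `label`
#'   (`"sin"` or `"seq"`).
#' @export
segment_rem_episodes <- function(hyp, window = NULL) {
  s <- hyp$stages
  r <- rle(s == "P")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  if (!is.null(window)) {
    w <- parse_tod(window)
    tod <- tod_of(hyp$epoch_starts)
    inside <- in_tod_window(tod, w[1], w[2])
    hit <- vapply(seq_along(starts),
                  function(k) any(inside[starts[k]:ends[k]]), logical(1))
    starts <- starts[hit]; ends <- ends[hit]
  }
  n_epi <- length(starts)
  if (n_epi == 0)
    return(data.frame(start_clock = hyp$epoch_starts[0],
                      end_clock = hyp$epoch_starts[0],
                      n_epochs = integer(), gap_to_next_s = numeric(),
                      label = character()))
  start_clock <- hyp$epoch_starts[starts]
  end_clock <- hyp$epoch_starts[ends] + hyp$epoch_len_s
  gap <- c(as.numeric(start_clock[-1]) - as.numeric(end_clock[-n_epi]),
           NA_real_)
  label <- ifelse(!is.na(gap) & gap <= 180, "seq", "sin")
  data.frame(start_clock = start_clock, end_clock = end_clock,
             n_epochs = ends - starts + 1L, gap_to_next_s = gap,
             label = label)
}

#' Count single and sequential REM episodes
#'
#' @param episodes Episode table from [segment_rem_episodes()].
#' @return Named integer vector `c(n_sin, n_seq)`; the two counts sum to
#'   the total number of episodes.
#' @export
count_sin_seq <- function(episodes) {
  c(n_sin = sum(episodes$label == "sin"),
    n_seq = sum(episodes$label == "seq"))
}

#' Latency to REM sleep
#'
#' Time from `from_clock` to the start of the first P epoch at or after
#' it.
#'
#' @param hyp A [hypnogram()].
#' @param from_clock POSIXct (or string) origin; defaults to the start
#'   of the hypnogram. Must land on the epoch grid.
#' @return Latency in seconds, or `NA` if no REM epoch follows.
#' @export
rem_latency <- function(hyp, from_clock = NULL) {
  from_clock <- if (is.null(from_clock)) hyp$epoch_starts[1]
                else parse_clock(from_clock)
  off <- as.numeric(from_clock) - as.numeric(hyp$epoch_starts[1])
  if (abs(off %% hyp$epoch_len_s) > 1e-6 &&
      abs(off %% hyp$epoch_len_s - hyp$epoch_len_s) > 1e-6)
    stop("alignment error: from_clock must land on the epoch grid")
  cand <- which(hyp$stages == "P" &
                  as.numeric(hyp$epoch_starts) >= as.numeric(from_clock))
  if (length(cand) == 0) return(NA_real_)
  as.numeric(hyp$epoch_starts[cand[1]]) - as.numeric(from_clock)
}
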