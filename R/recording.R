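# Recording container: synchronized EEG/EMG/activity channels from one
# telemetry session, anchored to clock time.

#' Construct a telemetry recording
#'
#' A `recording` bundles the three synchronized channels of a rodent
#' telemetry session: cortical EEG (microvolts), nuchal EMG (microvolts)
#' and locomotor activity (counts per fixed interval), together with the
#' clock time of the first sample and the light-cycle schedule.
#'
#' @param animal_id Character scalar identifying the animal.
#' @param eeg,emg Numeric vectors of samples in microvolts.
#' @param fs_eeg,fs_emg Sampling rates in Hz (> 0).
#' @param activity Non-negative integer counts, one per interval.
#' @param activity_interval_s Seconds per activity count (default 10).
#' @param start_clock Clock time of the first sample: POSIXct or a
#'   `"YYYY-MM-DD HH:MM:SS"` string (interpreted in UTC).
#' @param lights_on,lights_off Light-cycle switch times of day
#'   (defaults 07:00 / 19:00).
#' @return An object of class `recording`.
#' @export
recording <- function(animal_id, eeg, fs_eeg, emg, fs_emg, activity,
                      activity_interval_s = 10,
                      start_clock = "2024-01-01 07:00:00",
                      lights_on = "07:00", lights_off = "19:00") {
  rec <- structure(list(
    animal_id = as.character(animal_id),
    eeg = as.numeric(eeg), fs_eeg = as.numeric(fs_eeg),
    emg = as.numeric(emg), fs_emg = as.numeric(fs_emg),
    activity = as.numeric(activity),
    activity_interval_s = as.numeric(activity_interval_s),
    start_clock = parse_clock(start_clock),
    lights_on = parse_tod(lights_on),
    lights_off = parse_tod(lights_off)
  ), class = "recording")
  validate_recording(rec)
}

#' Validate a recording's invariants
#'
#' Checks positive sampling rates, non-negative activity counts, distinct
#' light switch times, absence of missing samples, and channel durations
#' that agree within one activity interval.
#'
#' @param rec A `recording`.
#' @return `rec`, invisibly usable, after passing all checks.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (rec$fs_eeg <= 0 || rec$fs_emg <= 0)
    stop("sampling rates must be strictly positive")
  if (rec$activity_interval_s <= 0)
    stop("activity interval must be strictly positive")
  if (anyNA(rec$eeg) || anyNA(rec$emg) || anyNA(rec$activity))
    stop("missing samples are rejected, not imputed")
  if (any(rec$activity < 0)) stop("activity counts must be >= 0")
  if (rec$lights_on == rec$lights_off)
    stop("lights_on and lights_off must differ")
  durs <- c(eeg = length(rec$eeg) / rec$fs_eeg,
            emg = length(rec$emg) / rec$fs_emg,
            activity = length(rec$activity) * rec$activity_interval_s)
  if (max(durs) - min(durs) > rec$activity_interval_s)
    stop("alignment error: channel durations disagree by more than one ",
         "activity interval (", paste(sprintf("%s=%.1fs", names(durs), durs),
                                      collapse = ", "), ")")
  rec
}

#' Recording duration in seconds
#' @param rec A `recording`.
#' @return Duration of the EEG channel in seconds.
#' @export
duration_s <- function(rec) length(rec$eeg) / rec$fs_eeg

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> animal %s: %.1f h from %s\n", x$animal_id,
              duration_s(x) / 3600, format_clock(x$start_clock)))
  cat(sprintf("  EEG %d samples @ %g Hz; EMG %d samples @ %g Hz; ",
              length(x$eeg), x$fs_eeg, length(x$emg), x$fs_emg))
  cat(sprintf("activity %d x %gs bins\n", length(x$activity),
              x$activity_interval_s))
  invisible(x)
}

#' Cut a recording into 10-second scoring epochs
#'
#' Tiles the recording with non-overlapping epochs anchored at the first
#' sample. A trailing partial epoch is dropped (with a message). The
#' returned table holds, per epoch, the clock time and the sample index
#' ranges into the EEG and EMG channels plus the summed activity count,
#' so that epoch slices can be taken without copying the signals.
#'
#' @param rec A `recording`.
#' @param epoch_len_s Epoch length in seconds (default 10).
#' @return A data.frame with columns `epoch` (1-based index),
#'   `start_clock`, `i0_eeg`, `i1_eeg`, `i0_emg`, `i1_emg`,
#'   `activity_count`.
#' @export
epochize <- function(rec, epoch_len_s = 10) {
  validate_recording(rec)
  dur <- duration_s(rec)
  n_ep <- floor(dur / epoch_len_s)
  if (n_ep == 0) {
    warning("recording shorter than one epoch; returning zero epochs")
    return(data.frame(epoch = integer(), start_clock = rec$start_clock[0],
                      i0_eeg = integer(), i1_eeg = integer(),
                      i0_emg = integer(), i1_emg = integer(),
                      activity_count = numeric()))
  }
  if (dur - n_ep * epoch_len_s > 1e-9)
    message(sprintf("dropping trailing partial epoch (%.1f s)",
                    dur - n_ep * epoch_len_s))
  ns_eeg <- round(rec$fs_eeg * epoch_len_s)
  ns_emg <- round(rec$fs_emg * epoch_len_s)
  i <- seq_len(n_ep)
  # activity counts summed over the intervals covering each epoch
  if (abs(rec$activity_interval_s - epoch_len_s) < 1e-9) {
    act <- rec$activity[i]
    act[is.na(act)] <- 0
  } else {
    per <- epoch_len_s / rec$activity_interval_s
    if (abs(per - round(per)) > 1e-9)
      stop("epoch length must be a multiple of the activity interval")
    per <- round(per)
    idx <- rep(i, each = per)
    a <- rec$activity[seq_len(min(length(rec$activity), n_ep * per))]
    act <- as.numeric(tapply(a, idx[seq_along(a)], sum))
    act <- c(act, rep(0, n_ep - length(act)))
  }
  data.frame(
    epoch = i,
    start_clock = rec$start_clock + (i - 1) * epoch_len_s,
    i0_eeg = (i - 1) * ns_eeg + 1L, i1_eeg = i * ns_eeg,
    i0_emg = (i - 1) * ns_emg + 1L, i1_emg = i * ns_emg,
    activity_count = act
  )
}

#' Read a recording from file
#'
#' Two on-disk formats are supported: long CSV (columns `channel`,
#' `clock_time_iso8601`, `value`, one row per sample) and EDF (European
#' Data Format, 16-bit; see [write_recording()]). Channel names are
#' matched through `channel_map`, so files using different labels can be
#' read without rewriting them.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"edf"`; default guessed from the extension.
#' @param channel_map Named list mapping the roles `eeg`, `emg`,
#'   `activity` to the channel labels used in the file.
#' @param animal_id Animal identifier; defaults to the file base name
#'   (CSV) or the EDF patient field.
#' @param lights_on,lights_off Light schedule to attach.
#' @return A validated `recording`.
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"),
                           channel_map = list(eeg = "EEG", emg = "EMG",
                                              activity = "ACT"),
                           animal_id = NULL,
                           lights_on = "07:00", lights_off = "19:00") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv")
    read_recording_csv(path, channel_map, animal_id, lights_on, lights_off)
  else
    read_recording_edf(path, channel_map, animal_id, lights_on, lights_off)
}

read_recording_csv <- function(path, channel_map, animal_id,
                               lights_on, lights_off) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel", "clock_time_iso8601", "value")
  if (!all(need %in% names(df)))
    stop("format error: CSV must have columns ", paste(need, collapse = ", "))
  get_chan <- function(role) {
    lab <- channel_map[[role]]
    sub <- df[df$channel == lab, , drop = FALSE]
    if (nrow(sub) == 0)
      stop("format error: missing channel '", lab, "' (", role, ")")
    t <- parse_clock(sub$clock_time_iso8601)
    o <- order(t)
    list(t = t[o], v = sub$value[o])
  }
  eeg <- get_chan("eeg"); emg <- get_chan("emg"); act <- get_chan("activity")
  infer_fs <- function(ch, role) {
    if (length(ch$t) < 2) stop("channel too short: ", role)
    dt <- diff(as.numeric(ch$t))
    med <- stats::median(dt)
    if (any(abs(dt - med) > med / 2))
      stop("alignment error: non-uniform sample spacing in ", role,
           " channel (missing samples are rejected, not imputed)")
    fs <- 1 / med
    # timestamps are printed with finite precision; snap to a clean rate
    if (abs(fs - round(fs)) < 1e-3 * max(fs, 1)) fs <- round(fs)
    else if (abs(1 / fs - round(1 / fs)) < 1e-3) fs <- 1 / round(1 / fs)
    fs
  }
  fs_eeg <- infer_fs(eeg, "eeg"); fs_emg <- infer_fs(emg, "emg")
  fs_act <- infer_fs(act, "activity")
  recording(
    animal_id = animal_id %||% sub("\\.[^.]*$", "", basename(path)),
    eeg = eeg$v, fs_eeg = fs_eeg, emg = emg$v, fs_emg = fs_emg,
    activity = act$v, activity_interval_s = 1 / fs_act,
    start_clock = min(eeg$t[1], emg$t[1], act$t[1]),
    lights_on = lights_on, lights_off = lights_off
  )
}

#' Write a recording to file
#'
#' The CSV writer emits the long format read by [read_recording()]
#' (lossless up to printed precision). The EDF writer produces a
#' standard EDF file with one data record per activity interval and
#' 16-bit samples, so signals round-trip within one quantization step of
#' their amplitude range.
#'
#' @param rec A `recording`.
#' @param path Output path.
#' @param format `"csv"` or `"edf"`; default guessed from the extension.
#' @param channel_map Channel labels to write (roles `eeg`, `emg`,
#'   `activity`).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "csv", "edf"),
                            channel_map = list(eeg = "EEG", emg = "EMG",
                                               activity = "ACT")) {
  validate_recording(rec)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "csv") write_recording_csv(rec, path, channel_map)
  else write_recording_edf(rec, path, channel_map)
  invisible(path)
}

write_recording_csv <- function(rec, path, channel_map) {
  stamp <- function(n, fs) rec$start_clock + (seq_len(n) - 1) / fs
  df <- rbind(
    data.frame(channel = channel_map$eeg,
               clock_time_iso8601 = format_clock(stamp(length(rec$eeg), rec$fs_eeg), 4),
               value = rec$eeg),
    data.frame(channel = channel_map$emg,
               clock_time_iso8601 = format_clock(stamp(length(rec$emg), rec$fs_emg), 4),
               value = rec$emg),
    data.frame(channel = channel_map$activity,
               clock_time_iso8601 = format_clock(
                 stamp(length(rec$activity), 1 / rec$activity_interval_s), 4),
               value = rec$activity)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
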