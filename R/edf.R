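# Minimal EDF (European Data Format) support for telemetry recordings:
# fixed 256-byte ASCII header + 256 bytes per signal, then interleaved
# 16-bit little-endian data records. One data record per activity
# interval, so the activity channel carries exactly one sample per record.

.edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

write_recording_edf <- function(rec, path, channel_map) {
  rd <- rec$activity_interval_s          # record duration, seconds
  n_rec <- floor(duration_s(rec) / rd)
  if (n_rec < 1) stop("recording shorter than one EDF data record")
  spr <- c(round(rec$fs_eeg * rd), round(rec$fs_emg * rd), 1L)
  if (abs(spr[1] - rec$fs_eeg * rd) > 1e-9 || abs(spr[2] - rec$fs_emg * rd) > 1e-9)
    stop("sampling rate times record duration must be integer for EDF")
  sigs <- list(rec$eeg[seq_len(n_rec * spr[1])],
               rec$emg[seq_len(n_rec * spr[2])],
               rec$activity[seq_len(n_rec)])
  labels <- c(channel_map$eeg, channel_map$emg, channel_map$activity)
  units <- c("uV", "uV", "counts")
  pmin <- pmax_ <- numeric(3)
  dig <- vector("list", 3)
  for (k in 1:3) {
    r <- max(abs(sigs[[k]]), 1e-6) * 1.0001
    if (k == 3) { pmin[k] <- 0; pmax_[k] <- max(32767, ceiling(r)) }
    else { pmin[k] <- -r; pmax_[k] <- r }
    dig[[k]] <- as.integer(round((sigs[[k]] - pmin[k]) /
                                   (pmax_[k] - pmin[k]) * 65535 - 32768))
  }
  st <- rec$start_clock
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad(rec$animal_id, 80),
    .edf_pad("somnotype recording", 80),
    format(st, "%d.%m.%y", tz = "UTC"),
    format(st, "%H.%M.%S", tz = "UTC"),
    .edf_pad(256 * (1 + 3), 8),
    .edf_pad("", 44),
    .edf_pad(n_rec, 8),
    .edf_pad(format(rd, scientific = FALSE), 8),
    .edf_pad(3, 4),
    paste(.edf_pad(labels, 16), collapse = ""),
    paste(.edf_pad(rep("", 3), 80), collapse = ""),
    paste(.edf_pad(units, 8), collapse = ""),
    paste(.edf_pad(formatC(pmin, format = "g", digits = 7), 8), collapse = ""),
    paste(.edf_pad(formatC(pmax_, format = "g", digits = 7), 8), collapse = ""),
    paste(.edf_pad(rep(-32768L, 3), 8), collapse = ""),
    paste(.edf_pad(rep(32767L, 3), 8), collapse = ""),
    paste(.edf_pad(rep("", 3), 80), collapse = ""),
    paste(.edf_pad(spr, 8), collapse = ""),
    paste(.edf_pad(rep("", 3), 32), collapse = "")
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  # interleave: record-major, signal-minor
  blk <- integer(sum(spr))
  off <- c(0, cumsum(spr))
  for (r in seq_len(n_rec)) {
    for (k in 1:3)
      blk[(off[k] + 1):off[k + 1]] <-
        dig[[k]][((r - 1) * spr[k] + 1):(r * spr[k])]
    writeBin(blk, con, size = 2, endian = "little")
  }
  invisible(path)
}

read_recording_edf <- function(path, channel_map, animal_id,
                               lights_on, lights_off) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_str <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- rd_str(8)
  patient <- rd_str(80); rd_str(80)
  startdate <- rd_str(8); starttime <- rd_str(8)
  rd_str(8); rd_str(44)
  n_rec <- as.integer(rd_str(8))
  rec_dur <- as.numeric(rd_str(8))
  ns <- as.integer(rd_str(4))
  field <- function(w) vapply(seq_len(ns), function(i) rd_str(w), character(1))
  labels <- field(16); field(80); field(8)
  pmin <- as.numeric(field(8)); pmax_ <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  field(80)
  spr <- as.integer(field(8)); field(32)
  start <- as.POSIXct(paste(startdate, starttime), tz = "UTC",
                      format = "%d.%m.%y %H.%M.%S")
  tot <- sum(spr)
  raw16 <- readBin(con, "integer", n = n_rec * tot, size = 2,
                   signed = TRUE, endian = "little")
  if (length(raw16) < n_rec * tot) stop("truncated EDF data section")
  chan_phys <- function(role) {
    lab <- channel_map[[role]]
    k <- match(lab, labels)
    if (is.na(k))
      stop("format error: missing channel '", lab, "' (", role,
           "); file has: ", paste(labels, collapse = ", "))
    off <- c(0, cumsum(spr))[k]
    idx <- as.vector(outer(seq_len(spr[k]) + off, (seq_len(n_rec) - 1) * tot, "+"))
    d <- raw16[idx]
    (d - dmin[k]) / (dmax[k] - dmin[k]) * (pmax_[k] - pmin[k]) + pmin[k]
  }
  keeg <- match(channel_map$eeg, labels); kemg <- match(channel_map$emg, labels)
  if (is.na(keeg)) stop("format error: missing channel '", channel_map$eeg, "' (eeg)")
  if (is.na(kemg)) stop("format error: missing channel '", channel_map$emg, "' (emg)")
  recording(
    animal_id = animal_id %||% patient,
    eeg = chan_phys("eeg"), fs_eeg = spr[keeg] / rec_dur,
    emg = chan_phys("emg"), fs_emg = spr[kemg] / rec_dur,
    activity = round(chan_phys("activity")),
    activity_interval_s = rec_dur,
    start_clock = start, lights_on = lights_on, lights_off = lights_off
  )
}
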