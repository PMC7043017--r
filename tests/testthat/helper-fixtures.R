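# Shared fixtures built in code.

# A tiny deterministic recording: EEG of known sinusoids per epoch, flat
# or noisy EMG, explicit activity counts.
toy_recording <- function(n_epochs = 6, fs = 200,
                          eeg_freq = rep(2, n_epochs),
                          eeg_amp = rep(50, n_epochs),
                          emg_sd = rep(0, n_epochs),
                          activity = rep(0, n_epochs),
                          start_clock = "2024-01-01 10:00:00",
                          seed = 1) {
  set.seed(seed)
  ns <- fs * 10
  tt <- seq(0, 10 - 1 / fs, 1 / fs)
  eeg <- unlist(lapply(seq_len(n_epochs), function(i)
    eeg_amp[i] * sin(2 * pi * eeg_freq[i] * tt)))
  emg <- unlist(lapply(seq_len(n_epochs), function(i)
    rnorm(ns, 0, max(emg_sd[i], 0)) + if (emg_sd[i] == 0) 0 else 0))
  recording("toy", eeg = eeg, fs_eeg = fs, emg = emg, fs_emg = fs,
            activity = activity, start_clock = start_clock)
}

# Random stage sequences for oracle comparisons.
random_stages <- function(n, p = c(0.4, 0.4, 0.2)) {
  sample(c("W", "S", "P"), n, replace = TRUE, prob = p)
}

# Brute-force scan oracles (deliberately naive, loop-based).
oracle_awakenings <- function(stages) {
  out <- integer(0)
  for (i in seq_len(length(stages) - 1))
    if (stages[i] %in% c("S", "P") && stages[i + 1] == "W")
      out <- c(out, i + 1L)
  out
}

oracle_sin_seq <- function(stages, epoch_len = 10) {
  # find maximal P runs, then label from inter-episode gaps
  runs <- list()
  i <- 1
  while (i <= length(stages)) {
    if (stages[i] == "P") {
      j <- i
      while (j < length(stages) && stages[j + 1] == "P") j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(runs)) return(c(n_sin = 0L, n_seq = 0L))
  lab <- character(length(runs))
  for (k in seq_along(runs)) {
    if (k == length(runs)) { lab[k] <- "sin"; next }
    gap <- (runs[[k + 1]][1] - runs[[k]][2] - 1) * epoch_len
    lab[k] <- if (gap <= 180) "seq" else "sin"
  }
  c(n_sin = sum(lab == "sin"), n_seq = sum(lab == "seq"))
}
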