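# Hypnogram: an ordered sequence of 10-second epochs, each labeled
# W (wake), S (slow-wave sleep) or P (REM / paradoxical sleep),
# anchored to clock time.

STAGES <- c("W", "S", "P")

#' Construct a hypnogram
#'
#' @param stages Character vector over `{"W","S","P"}`, one per epoch.
#' @param start_clock Clock time of the first epoch (POSIXct or string).
#' @param animal_id Animal identifier.
#' @param epoch_len_s Epoch length in seconds (default 10).
#' @param epoch_starts Optional explicit POSIXct start time per epoch
#'   (used by [clip_window()]); defaults to the contiguous grid
#'   `start_clock + epoch_len_s * (i - 1)`.
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(stages, start_clock = "2024-01-01 07:00:00",
                      animal_id = "animal", epoch_len_s = 10,
                      epoch_starts = NULL) {
  stages <- as.character(stages)
  if (length(stages) == 0) stop("stages must be non-empty")
  bad <- setdiff(unique(stages), STAGES)
  if (length(bad))
    stop("unknown stage symbol(s): ", paste(bad, collapse = ", "))
  start_clock <- parse_clock(start_clock)
  if (is.null(epoch_starts))
    epoch_starts <- start_clock + (seq_along(stages) - 1) * epoch_len_s
  if (length(epoch_starts) != length(stages))
    stop("epoch_starts must match stages in length")
  structure(list(animal_id = as.character(animal_id),
                 epoch_len_s = epoch_len_s,
                 start_clock = start_clock,
                 epoch_starts = epoch_starts,
                 stages = stages),
            class = "hypnogram")
}

#' Number of epochs in a hypnogram
#' @param hyp A `hypnogram`.
#' @return Integer epoch count.
#' @export
n_epochs <- function(hyp) length(hyp$stages)

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, STAGES))
  cat(sprintf("<hypnogram> animal %s: %d x %gs epochs from %s (W %d, S %d, P %d)\n",
              x$animal_id, n_epochs(x), x$epoch_len_s,
              format_clock(x$start_clock), tab["W"], tab["S"], tab["P"]))
  invisible(x)
}

#' @export
as.data.frame.hypnogram <- function(x, ...) {
  data.frame(epoch_index = seq_along(x$stages) - 1L,
             start_clock = format_clock(x$epoch_starts),
             stage = x$stages)
}

#' Clip a hypnogram to a time-of-day window
#'
#' Keeps the epochs whose start time of day lies in the half-open window
#' `[start, end)`. Windows with `end <= start` wrap across midnight
#' (e.g. the dark period 19:00-06:00). The window must land on the epoch
#' grid anchored at the first epoch; otherwise an alignment error is
#' raised (no resampling is ever performed).
#'
#' @param hyp A `hypnogram`.
#' @param start,end Window edges as times of day (`"HH:MM[:SS]"` or
#'   seconds since midnight).
#' @return A `hypnogram` containing the selected epochs (with their
#'   original clock times).
#' @export
#' @examples
#' h <- hypnogram(rep(c("W","S"), 180), start_clock = "2024-01-01 10:00:00")
#' n_epochs(clip_window(h, "10:00", "10:30"))  # 180
clip_window <- function(hyp, start, end) {
  start_s <- parse_tod(start); end_s <- parse_tod(end)
  tod0 <- tod_of(hyp$epoch_starts[1])
  mis <- c((start_s - tod0) %% hyp$epoch_len_s,
           (end_s - tod0) %% hyp$epoch_len_s)
  if (any(abs(mis) > 1e-6 & abs(mis - hyp$epoch_len_s) > 1e-6))
    stop("alignment error: window [", format_tod(start_s), ", ",
         format_tod(end_s), ") does not land on the epoch grid")
  keep <- in_tod_window(tod_of(hyp$epoch_starts), start_s, end_s)
  if (!any(keep)) stop("window contains no epochs")
  hypnogram(hyp$stages[keep], start_clock = hyp$epoch_starts[keep][1],
            animal_id = hyp$animal_id, epoch_len_s = hyp$epoch_len_s,
            epoch_starts = hyp$epoch_starts[keep])
}

#' Read a hypnogram from TSV
#'
#' Expects the dialect written by [write_hypnogram()]: a header line
#' `epoch_index<TAB>start_clock<TAB>stage` followed by one row per epoch
#' with stages in `{W, S, P}`. Unknown stage symbols raise a parse error
#' naming the offending line.
#'
#' @param path Path to the TSV file.
#' @param animal_id Optional identifier override (default: file name).
#' @return A `hypnogram`.
#' @export
read_hypnogram <- function(path, animal_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("epoch_index", "start_clock", "stage")
  if (!all(need %in% names(df)))
    stop("parse error: expected header ", paste(need, collapse = "\t"))
  bad <- which(!df$stage %in% STAGES)
  if (length(bad))
    stop("parse error: unknown stage symbol '", df$stage[bad[1]],
         "' at line ", bad[1] + 1L)
  starts <- parse_clock(df$start_clock)
  hypnogram(df$stage, start_clock = starts[1],
            animal_id = animal_id %||% sub("\\.[^.]*$", "", basename(path)),
            epoch_starts = starts)
}

#' Write a hypnogram to TSV
#'
#' @param hyp A `hypnogram`.
#' @param path Output path.
#' @return `path`, invisibly. Round-trips losslessly through
#'   [read_hypnogram()].
#' @export
write_hypnogram <- function(hyp, path) {
  utils::write.table(as.data.frame(hyp), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
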