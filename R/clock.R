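# Clock-time helpers. All absolute times are POSIXct in UTC; times of day
# are numeric seconds since midnight in [0, 86400).

#' Parse a time of day
#'
#' Converts `"HH:MM"` or `"HH:MM:SS"` strings (or numbers already in
#' seconds) to seconds since midnight.
#'
#' @param x Character vector of clock times, or a numeric vector of seconds.
#' @return Numeric vector of seconds since midnight.
#' @export
#' @examples
#' parse_tod("10:00")      # 36000
#' parse_tod("19:30:10")
parse_tod <- function(x) {
  if (is.numeric(x)) {
    if (any(x < 0 | x >= 86400)) stop("time of day must be in [0, 86400)")
    return(as.numeric(x))
  }
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (!length(p) %in% 2:3 || anyNA(suppressWarnings(as.numeric(p))))
      stop("cannot parse time of day: ", paste(p, collapse = ":"))
    p <- as.numeric(p)
    s <- p[1] * 3600 + p[2] * 60 + if (length(p) == 3) p[3] else 0
    if (s < 0 || s >= 86400) stop("time of day out of range")
    s
  }, numeric(1))
}

#' Format seconds since midnight as HH:MM:SS
#' @param s Numeric seconds since midnight.
#' @return Character vector.
#' @export
format_tod <- function(s) {
  s <- round(s)
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}

#' Time of day of absolute times
#' @param t POSIXct vector (UTC).
#' @return Seconds since midnight.
#' @export
tod_of <- function(t) as.numeric(t) %% 86400

# Membership in a half-open time-of-day window [start, end); windows with
# end <= start wrap across midnight.
in_tod_window <- function(tod, start_s, end_s) {
  if (start_s < end_s) tod >= start_s & tod < end_s
  else tod >= start_s | tod < end_s
}

# Window length in seconds, honouring midnight wrap.
tod_window_len <- function(start_s, end_s) (end_s - start_s) %% 86400

#' Photoperiod of absolute times
#'
#' @param t POSIXct vector.
#' @param lights_on,lights_off Times of day (string or seconds) at which
#'   lights switch on and off. Defaults 07:00 / 19:00.
#' @return Character vector, `"light"` or `"dark"`.
#' @export
photoperiod_of <- function(t, lights_on = "07:00", lights_off = "19:00") {
  on <- parse_tod(lights_on); off <- parse_tod(lights_off)
  if (on == off) stop("lights_on and lights_off must differ")
  ifelse(in_tod_window(tod_of(t), on, off), "light", "dark")
}

# Parse an absolute clock time string "YYYY-MM-DD HH:MM:SS" to POSIXct UTC.
parse_clock <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(x, tz = "UTC"))
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS"))
  if (anyNA(out)) stop("cannot parse clock time: ", x[which(is.na(out))[1]])
  out
}

format_clock <- function(t, digits = 0) {
  if (digits > 0) format(t, "%Y-%m-%dT%H:%M:%OS4", tz = "UTC")
  else format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}
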