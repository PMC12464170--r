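# Clock-time helpers. All timestamps are naive local time carried as
# POSIXct in UTC; day/night windows are defined on the local clock.

DAY_START_HOUR <- 6L    # day window 06:00-20:59
NIGHT_START_HOUR <- 21L # night window 21:00-05:59
MINUTES_PER_DAY <- 1440L
DAY_WINDOW_MINUTES <- 900L
NIGHT_WINDOW_MINUTES <- 540L

#' Day/night window assignment for minute timestamps
#'
#' Minutes whose clock hour falls in 06:00--20:59 belong to the day window;
#' 21:00--05:59 is night. The two windows partition the 24-h day.
#'
#' @param timestamps POSIXct vector (minute resolution).
#' @return Logical vector, `TRUE` for day-window minutes.
#' @export
is_day_minute <- function(timestamps) {
  h <- as.POSIXlt(timestamps, tz = "UTC")$hour
  h >= DAY_START_HOUR & h < NIGHT_START_HOUR
}

#' @rdname is_day_minute
#' @return `hour_of()` returns the integer clock hour (0--23).
#' @export
hour_of <- function(timestamps) {
  as.POSIXlt(timestamps, tz = "UTC")$hour
}

minute_of_day <- function(timestamps) {
  lt <- as.POSIXlt(timestamps, tz = "UTC")
  lt$hour * 60L + lt$min
}

#' Week index within a season
#'
#' Weeks are consecutive 7-day blocks counted from the first day of the
#' season's sampling window (not ISO calendar weeks); the first block is
#' week 1.
#'
#' @param dates Date or POSIXct vector.
#' @param season_start Date, first day of the season window.
#' @return Integer week indices (>= 1).
#' @export
week_index <- function(dates, season_start) {
  d <- as.integer(as.Date(dates, tz = "UTC") - as.Date(season_start))
  as.integer(d %/% 7L) + 1L
}

as_naive_posix <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  as.POSIXct(x, tz = "UTC")
}

minute_seq <- function(start, n) {
  as_naive_posix(start) + 60 * (seq_len(n) - 1)
}
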