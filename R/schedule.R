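# Release schedule: calendar bookkeeping for the propagule release design.
# Dates are handled as day-of-year on a fixed 365-day calendar; leap days are
# irrelevant at the precision of the drift model.

.MONTH_DAYS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

#' Convert an "MM-DD" string to day-of-year (365-day calendar)
#' @keywords internal
#' @noRd
.doy <- function(mmdd) {
  if (is.numeric(mmdd)) return(as.integer(mmdd))
  parts <- as.integer(strsplit(mmdd, "-", fixed = TRUE)[[1L]])
  if (length(parts) != 2L || anyNA(parts) || parts[1L] < 1L || parts[1L] > 12L)
    stop("date must be an \"MM-DD\" string, got: ", mmdd)
  if (parts[2L] < 1L || parts[2L] > .MONTH_DAYS[parts[1L]])
    stop("invalid day of month in: ", mmdd)
  sum(.MONTH_DAYS[seq_len(parts[1L] - 1L)]) + parts[2L]
}

#' Propagule release schedule
#'
#' Describes the annual release design: releases start at `window_start` and
#' recur every `step` days for all offsets strictly inside a window of
#' `window_length` days; propagules are tracked until `tracking_end`. The
#' default reproduces the eastern Bering Sea design: every-other-day releases
#' over an 80-day window starting March 15 (40 release events), tracked to
#' September 30.
#'
#' @param window_start First release date, `"MM-DD"` string or day-of-year.
#' @param window_length Length of the release window in days.
#' @param step Days between consecutive releases.
#' @param tracking_end Last tracked date, `"MM-DD"` string or day-of-year.
#' @return An object of class `ss_schedule` with elements `window_start`
#'   (day-of-year), `window_length`, `step`, `n_releases`, `release_doys`
#'   (day-of-year of each release event) and `tracking_end` (day-of-year).
#' @examples
#' sch <- release_schedule()
#' sch$n_releases   # 40
#' @export
release_schedule <- function(window_start = "03-15", window_length = 80L,
                             step = 2L, tracking_end = "09-30") {
  start <- .doy(window_start)
  end <- .doy(tracking_end)
  step <- as.integer(step)
  window_length <- as.integer(window_length)
  if (step < 1L) stop("step must be >= 1 day")
  if (window_length < 1L) stop("window_length must be >= 1 day")
  offsets <- seq.int(0L, window_length - 1L, by = step)
  release_doys <- start + offsets
  if (end <= max(release_doys))
    stop("tracking_end must fall after the last release date")
  structure(list(
    window_start = start,
    window_length = window_length,
    step = step,
    n_releases = length(offsets),
    release_doys = release_doys,
    tracking_end = end
  ), class = "ss_schedule")
}

#' @export
print.ss_schedule <- function(x, ...) {
  cat(sprintf(
    "Release schedule: %d releases every %d d over a %d-day window (doy %d-%d), tracked to doy %d\n",
    x$n_releases, x$step, x$window_length, x$window_start,
    max(x$release_doys), x$tracking_end))
  invisible(x)
}

#' Maximum recorded day offset for a release event
#'
#' Number of days from release event `d` to the tracking end; positions with
#' `day_offset` in `0:max_offset(schedule, d)` contribute to exposure.
#' @param schedule An `ss_schedule`.
#' @param d Release event index (vectorised).
#' @return Integer vector of maximal day offsets.
#' @export
max_offset <- function(schedule, d) {
  stopifnot(inherits(schedule, "ss_schedule"))
  schedule$tracking_end - schedule$release_doys[d]
}
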