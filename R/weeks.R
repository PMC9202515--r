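#' Weekly date grid on the Sunday-start convention
#'
#' Google Health Trends reports weekly search volumes on Sunday-start weeks.
#' `week_grid()` returns every Sunday in `[start_date, end_date]`, beginning
#' with the first Sunday on or after `start_date`. With the default study
#' windows this yields 157 weeks for 2017--2019 and 52 full weeks for 2020.
#'
#' @param start_date,end_date `Date` (or ISO-8601 string) bounds, inclusive.
#' @return A `Date` vector of consecutive Sundays, spaced exactly 7 days.
#' @examples
#' length(week_grid("2017-01-01", "2019-12-31")) # 157
#' length(week_grid("2020-01-01", "2020-12-31")) # 52
#' @export
week_grid <- function(start_date, end_date) {
  start_date <- as_iso_date(start_date, "start_date")
  end_date <- as_iso_date(end_date, "end_date")
  if (start_date >= end_date) {
    abort("`start_date` must be strictly before `end_date`.")
  }
  # %u gives ISO weekday Mon=1..Sun=7
  first <- start_date + (7L - as.integer(format(start_date, "%u"))) %% 7L
  if (first > end_date) {
    abort("no Sunday falls inside the requested window.")
  }
  seq(first, end_date, by = 7L)
}

#' Fractional week of year
#'
#' Maps a date to a continuous week-of-year coordinate: day-of-year 1 maps to
#' week 1, and each subsequent 7 days add 1. The value is real-valued in
#' `[1, 54)` so that Sunday grids falling on different weekdays across years
#' land on slightly different coordinates, as they do in the source data.
#'
#' @param date `Date` vector.
#' @return Numeric vector in `[1, 54)`.
#' @export
week_of_year <- function(date) {
  (as.integer(format(as.Date(date), "%j")) - 1) / 7 + 1
}

as_iso_date <- function(x, arg = "date") {
  if (inherits(x, "Date")) {
    return(x)
  }
  out <- tryCatch(as.Date(x, format = "%Y-%m-%d"), error = function(e) NA)
  if (any(is.na(out))) {
    abort(sprintf("`%s` must be a Date or ISO-8601 (YYYY-MM-DD) string.", arg))
  }
  out
}
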