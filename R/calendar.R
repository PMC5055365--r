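# Calendar machinery: time-stratified referent days and US public holidays.

#' Time-stratified referent days for an injury date
#'
#' Returns every date in the injury's calendar month that falls on the same
#' weekday, excluding the injury date itself. Months contain four or five of
#' each weekday, so the set always has three or four members. Sampling the
#' referents from the event's own month-by-weekday stratum avoids the overlap
#' bias of unidirectional referent windows.
#'
#' @param injury_date A `Date` (or ISO-8601 string), length 1.
#' @return A sorted `Date` vector of length 3 or 4.
#' @examples
#' referent_days(as.Date("2010-07-14"))  # the other July 2010 Wednesdays
#' @export
referent_days <- function(injury_date) {
  injury_date <- as.Date(injury_date)
  stopifnot(length(injury_date) == 1L, !is.na(injury_date))
  lt <- as.POSIXlt(injury_date)
  first <- injury_date - (lt$mday - 1L)
  month_days <- seq(first, by = "1 day",
                    length.out = .days_in_month(lt$year + 1900L, lt$mon + 1L))
  same_wd <- month_days[as.POSIXlt(month_days)$wday == lt$wday]
  same_wd[same_wd != injury_date]
}

.days_in_month <- function(year, month) {
  nxt <- if (month == 12L) as.Date(sprintf("%d-01-01", year + 1L)) else
    as.Date(sprintf("%d-%02d-01", year, month + 1L))
  as.integer(nxt - as.Date(sprintf("%d-%02d-01", year, month)))
}

# Saturday/Sunday flag (POSIXlt wday: 0 = Sunday, 6 = Saturday).
.is_weekend <- function(date) as.POSIXlt(as.Date(date))$wday %in% c(0L, 6L)

# nth occurrence of a weekday (0=Sun..6=Sat) in a month; n = -1 means last.
.nth_weekday <- function(year, month, wday, n) {
  first <- as.Date(sprintf("%d-%02d-01", year, month))
  offset <- (wday - as.POSIXlt(first)$wday) %% 7L
  if (n > 0L) {
    first + offset + 7L * (n - 1L)
  } else {
    d <- first + offset + 7L * 4L
    if (as.POSIXlt(d)$mon + 1L != month) d <- d - 7L
    d
  }
}

# Fixed-date federal holiday with observed-date shift (Sat -> Fri, Sun -> Mon).
.observed <- function(date) {
  w <- as.POSIXlt(date)$wday
  date + ifelse(w == 6L, -1L, ifelse(w == 0L, 1L, 0L))
}

.us_holidays_in_year <- function(year) {
  fixed <- c(
    as.Date(sprintf("%d-01-01", year)),              # New Year's Day
    as.Date(sprintf("%d-07-04", year)),              # Independence Day
    as.Date(sprintf("%d-11-11", year)),              # Veterans Day
    as.Date(sprintf("%d-12-25", year))               # Christmas Day
  )
  if (year >= 2021L) {
    fixed <- c(fixed, as.Date(sprintf("%d-06-19", year)))  # Juneteenth
  }
  floating <- c(
    .nth_weekday(year, 1L, 1L, 3L),   # MLK Day: 3rd Monday of January
    .nth_weekday(year, 2L, 1L, 3L),   # Washington's Birthday: 3rd Mon of Feb
    .nth_weekday(year, 5L, 1L, -1L),  # Memorial Day: last Monday of May
    .nth_weekday(year, 9L, 1L, 1L),   # Labor Day: 1st Monday of September
    .nth_weekday(year, 10L, 1L, 2L),  # Columbus Day: 2nd Monday of October
    .nth_weekday(year, 11L, 4L, 4L)   # Thanksgiving: 4th Thursday of November
  )
  sort(unique(c(.observed(fixed), floating)))
}

#' US federal public holiday flag
#'
#' Computes the US federal holiday set algorithmically (fixed-date holidays
#' with observed-date shifts when they fall on a weekend, plus the floating
#' Monday/Thursday holidays). An approximation of the holiday calendars
#' shipped by calendar libraries, adequate for day-level exclusion rules.
#'
#' @param day `Date` vector; years must lie in 1990-2030.
#' @return Logical vector.
#' @examples
#' is_us_public_holiday(as.Date(c("2012-07-04", "2012-07-05", "2012-11-22")))
#' @export
is_us_public_holiday <- function(day) {
  day <- as.Date(day)
  yrs <- as.POSIXlt(day)$year + 1900L
  if (any(yrs < 1990L | yrs > 2030L, na.rm = TRUE)) {
    stop("is_us_public_holiday: year outside 1990-2030")
  }
  hol <- do.call(c, lapply(sort(unique(yrs)), .us_holidays_in_year))
  day %in% hol
}
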