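#' Add whole years to a date
#'
#' Anniversary arithmetic used for landmark ages: the result keeps the month
#' and day of the input. A 29 February birthday in a non-leap target year
#' anniversaries on 1 March.
#'
#' @param dates Date vector.
#' @param years integer number of years to add (scalar or vector).
#' @return Date vector.
#' @export
add_years <- function(dates, years) {
  lt <- as.POSIXlt(dates)
  leap_day <- lt$mon == 1L & lt$mday == 29L
  lt$year <- lt$year + years
  out <- as.Date(lt)
  if (any(leap_day)) {
    # POSIXlt rolls Feb 29 to Mar 1 in non-leap years already, but be explicit
    # so behaviour does not depend on platform strftime quirks.
    y <- lt$year[leap_day] + 1900L
    non_leap <- !((y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0)
    if (any(non_leap)) {
      idx <- which(leap_day)[non_leap]
      out[idx] <- as.Date(sprintf("%04d-03-01", y[non_leap]))
    }
  }
  out
}

#' First day of the month of a date
#'
#' @param dates Date vector.
#' @return Date vector with day-of-month 1.
#' @export
month_start <- function(dates) {
  lt <- as.POSIXlt(dates)
  lt$mday <- 1L
  as.Date(lt)
}

#' Index date for a landmark age
#'
#' A person enters a landmark-age dataset on the first day of the month in
#' which they reach that age.
#'
#' @param birth_date Date vector of birth dates.
#' @param landmark_age integer landmark age in years (40--74 in the default
#'   design; any non-negative age is accepted).
#' @return Date vector of index dates (always day 1 of a month).
#' @export
index_date <- function(birth_date, landmark_age) {
  month_start(add_years(birth_date, landmark_age))
}
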