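#' Assemble combined date-time values from separate date and time fields
#'
#' Administrative extracts store calendar date and clock time in separate
#' columns; temporal linkage needs a single combined timestamp per event.
#' `assemble_datetime()` composes the two at minute resolution (seconds, if
#' present in the time field, are truncated). Timestamps are wall-clock and
#' timezone-naive — administrative systems record local clock time, so no
#' daylight-saving arithmetic is applied (internally a fixed UTC offset is
#' used as a plain calendar).
#'
#' A missing (empty or `NA`) time field is handled by `missing_time` policy:
#' `"impute"` substitutes midnight (00:00) and flags the record, keeping it
#' available for the join while marking the uncertainty; `"drop"` marks the
#' record for removal. An unparseable *date* is always a record-level error,
#' returned in the `errors` element rather than raised, so callers can
#' itemise affected rows.
#'
#' @param date character vector of calendar dates.
#' @param time character vector of clock times (`"HH:MM"` or `"HH:MM:SS"`);
#'   empty strings and `NA` denote a missing time.
#' @param missing_time `"impute"` (default) or `"drop"`.
#' @param date_format `strptime` format of the date field.
#' @return a list with elements
#'   \describe{
#'     \item{datetime}{`POSIXct` vector, minute resolution; `NA` where the
#'       date failed to parse or the time was missing under `"drop"`.}
#'     \item{flagged}{logical, `TRUE` where midnight was imputed.}
#'     \item{dropped}{logical, `TRUE` where the `"drop"` policy removed a
#'       missing-time record.}
#'     \item{errors}{data frame of `(row, field, value)` for unparseable
#'       dates or times.}
#'   }
#' @examples
#' assemble_datetime("2010-03-01", "10:35")$datetime
#' assemble_datetime("2010-03-01", "", missing_time = "impute")
#' assemble_datetime("2010-13-40", "10:00")$errors
#' @export
assemble_datetime <- function(date, time,
                              missing_time = c("impute", "drop"),
                              date_format = "%Y-%m-%d") {
  missing_time <- match.arg(missing_time)
  n <- max(length(date), length(time))
  date <- rep_len(as.character(date), n)
  time <- rep_len(as.character(time), n)

  d <- as.Date(date, format = date_format)
  bad_date <- is.na(d) & !is.na(date) & nzchar(date)
  no_date <- is.na(date) | !nzchar(date)

  time_trim <- trimws(ifelse(is.na(time), "", time))
  no_time <- !nzchar(time_trim)
  # accept HH:MM or HH:MM:SS; seconds truncated
  ok_time <- grepl("^\\d{1,2}:\\d{2}(:\\d{2})?$", time_trim)
  bad_time <- !no_time & !ok_time
  hhmm <- sub("^(\\d{1,2}:\\d{2}).*$", "\\1", time_trim)
  hh <- suppressWarnings(as.integer(sub(":.*$", "", hhmm)))
  mm <- suppressWarnings(as.integer(sub("^[^:]*:", "", hhmm)))
  oob <- ok_time & (hh > 23L | mm > 59L)
  bad_time <- bad_time | (oob %in% TRUE)

  usable <- !is.na(d) & ok_time & !(oob %in% TRUE)
  dt <- rep(as.POSIXct(NA, tz = "UTC"), n)
  dt[usable] <- as.POSIXct(as.numeric(as.POSIXct(d[usable], tz = "UTC")) +
                             hh[usable] * 3600 + mm[usable] * 60,
                           origin = "1970-01-01", tz = "UTC")

  flagged <- rep(FALSE, n)
  dropped <- rep(FALSE, n)
  imputable <- !is.na(d) & no_time
  if (missing_time == "impute") {
    dt[imputable] <- as.POSIXct(d[imputable], tz = "UTC")
    flagged[imputable] <- TRUE
  } else {
    dropped[imputable] <- TRUE
  }

  err_row <- which(bad_date | no_date | bad_time)
  errors <- data.frame(
    row = err_row,
    field = ifelse(bad_date[err_row] | no_date[err_row], "date", "time"),
    value = ifelse(bad_date[err_row] | no_date[err_row],
                   date[err_row], time[err_row]),
    stringsAsFactors = FALSE
  )
  list(datetime = floor_minute(dt), flagged = flagged,
       dropped = dropped, errors = errors)
}

# Format helpers used by the writers; inverse of assemble_datetime at
# minute resolution.
format_date_col <- function(dt) format(dt, "%Y-%m-%d", tz = "UTC")
format_time_col <- function(dt) format(dt, "%H:%M", tz = "UTC")
format_dt <- function(dt) format(dt, "%Y-%m-%d %H:%M", tz = "UTC")

parse_dt <- function(x) {
  floor_minute(as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M"))
}

# Construct a POSIXct (UTC wall clock) from an ISO string; test/fixture aid.
#' Parse an ISO "YYYY-MM-DD HH:MM" string to a minute-resolution timestamp
#'
#' Convenience for building timestamps in examples and fixtures on the same
#' timezone-naive clock the package uses internally.
#'
#' @param x character vector, `"YYYY-MM-DD HH:MM"`.
#' @return `POSIXct` vector (UTC-as-naive wall clock).
#' @export
wallclock <- function(x) parse_dt(x)
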