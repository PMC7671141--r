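# Shared time helpers. All timestamps in this package live in a fixed-offset
# local standard time zone (no DST inside a deployment); clock-time filters
# such as the 15:00-23:00 onset window are civil clock times in that zone.

#' Fixed-offset time zone string for a UTC offset
#'
#' Returns an Olson `Etc/GMT` identifier for a whole-hour UTC offset.
#' Note the sign inversion in the Etc convention: UTC-7 is `"Etc/GMT+7"`.
#'
#' @param tz_offset_h Hours east of UTC (e.g. -7 for Mountain Standard Time).
#' @return A time zone string usable with [as.POSIXct()].
#' @export
tz_fixed <- function(tz_offset_h) {
  stopifnot(is.numeric(tz_offset_h), length(tz_offset_h) == 1L)
  if (tz_offset_h != round(tz_offset_h)) {
    abort("tz_offset_h must be a whole number of hours for a fixed-offset zone")
  }
  if (tz_offset_h == 0) return("UTC")
  sprintf("Etc/GMT%+d", -as.integer(tz_offset_h))
}

#' Local clock time of day in hours
#' @param time POSIXct vector.
#' @return Numeric hours since local midnight, in `[0, 24)`.
#' @keywords internal
clock_hours <- function(time) {
  lt <- as.POSIXlt(time)
  lt$hour + lt$min / 60 + lt$sec / 3600
}

#' Assign timestamps to noon-to-noon nights
#'
#' Nocturnal activity spans midnight, so nightly metrics are computed on
#' noon-to-noon "nights" labelled by the calendar date of the opening noon
#' boundary: a sample at 13:00 on Jan 1 and one at 11:00 on Jan 2 belong to
#' the same night, `"Jan 1"`.
#'
#' @param time POSIXct vector in local standard time.
#' @param boundary_h Local clock hour opening the night (default 12).
#' @return A `Date` vector of night labels, same length as `time`.
#' @export
night_of <- function(time, boundary_h = 12) {
  d <- as.Date(format(time, "%Y-%m-%d"))
  ifelse_date(clock_hours(time) >= boundary_h, d, d - 1L)
}

ifelse_date <- function(test, yes, no) {
  out <- yes
  out[!test] <- no[!test]
  out
}

#' @keywords internal
stop_bad_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  invisible(path)
}
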