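# Civil twilight from solar geometry (NOAA-style hour-angle inversion).
#
# Civil dawn/dusk are the times at which the geometric centre of the sun
# crosses 6 degrees below the horizon (zenith angle 96 degrees); the
# definition is geometric, so no refraction correction is applied. Accuracy
# contract: within +/- 2 min of an independent ephemeris at mid latitudes.

#' Define an observation site
#'
#' @param lat Latitude in decimal degrees north. Must satisfy `|lat| < 66.5`
#'   so that civil twilight exists on every date (polar sites rejected).
#' @param lon Longitude in decimal degrees east (west negative).
#' @param tz_offset_h Local standard time offset from UTC in hours.
#' @return A `site` object (list with `lat`, `lon`, `tz_offset_h`, `tz`).
#' @examples
#' # the Flagstaff, AZ study area (35 deg 11' 57" N, 111 deg 37' 52" W, MST)
#' flagstaff <- site(35.19917, -111.63111, -7)
#' @export
site <- function(lat, lon, tz_offset_h) {
  stopifnot(is.numeric(lat), is.numeric(lon), is.numeric(tz_offset_h))
  if (abs(lat) >= 66.5) {
    abort("site latitude must satisfy |lat| < 66.5 deg: civil twilight is not guaranteed at polar latitudes")
  }
  structure(
    list(lat = lat, lon = lon, tz_offset_h = tz_offset_h,
         tz = tz_fixed(tz_offset_h)),
    class = "odba_site"
  )
}

#' Default study site (Flagstaff, Arizona)
#'
#' Suburban Flagstaff, AZ (35.19917 N, 111.63111 W, 2170 m, Mountain
#' Standard Time). Elevation is ignored: at the -6 deg civil-twilight
#' depression it shifts crossing times by well under a minute.
#' @return A `site` object.
#' @export
flagstaff_site <- function() site(35.19917, -111.63111, -7)

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# NOAA fractional-year solar coefficients: equation of time (minutes) and
# solar declination (radians) at fractional year gamma (radians).
solar_eqtime_decl <- function(gamma) {
  eqtime <- 229.18 * (0.000075 +
    0.001868 * cos(gamma) - 0.032077 * sin(gamma) -
    0.014615 * cos(2 * gamma) - 0.040849 * sin(2 * gamma))
  decl <- 0.006918 -
    0.399912 * cos(gamma) + 0.070257 * sin(gamma) -
    0.006758 * cos(2 * gamma) + 0.000907 * sin(2 * gamma) -
    0.002697 * cos(3 * gamma) + 0.00148 * sin(3 * gamma)
  list(eqtime = eqtime, decl = decl)
}

year_length <- function(year) {
  if ((year %% 4 == 0 && year %% 100 != 0) || year %% 400 == 0) 366 else 365
}

# Hour angle (degrees, positive) at which the sun reaches zenith `zen` deg.
# NA when the sun never reaches that zenith on the date (polar day/night).
solar_hour_angle <- function(lat_rad, decl, zen_deg) {
  cos_ha <- cos(deg2rad(zen_deg)) / (cos(lat_rad) * cos(decl)) -
    tan(lat_rad) * tan(decl)
  ifelse(abs(cos_ha) > 1, NA_real_, rad2deg(acos(cos_ha)))
}

#' Civil twilight times for a site
#'
#' Computes civil dawn and civil dusk (sun 6 deg below the horizon) for each
#' date from solar declination, the equation of time, and hour-angle
#' inversion, with a second refinement pass that re-evaluates the solar
#' coefficients at the first-pass event time (sub-minute stability).
#'
#' @param site A [site()] object.
#' @param dates A `Date` vector (or something coercible by [as.Date()]).
#' @return A tibble (`twilight_table`) with columns `date`, `civil_dawn`,
#'   `civil_dusk` (POSIXct in the site's fixed local standard time) and
#'   `solar_noon`.
#' @examples
#' tw <- civil_twilight(flagstaff_site(), as.Date("2016-06-21"))
#' @export
civil_twilight <- function(site, dates) {
  stopifnot(inherits(site, "odba_site"))
  dates <- as.Date(dates)
  if (length(dates) == 0) abort("no dates supplied")
  lat <- deg2rad(site$lat)

  one_event <- function(date, rising) {
    doy <- as.integer(format(date, "%j"))
    yl <- year_length(as.integer(format(date, "%Y")))
    # pass 1: coefficients at local solar noon
    gamma <- 2 * pi / yl * (doy - 1 + 0.5)
    est <- NA_real_
    for (pass in 1:2) {
      sc <- solar_eqtime_decl(gamma)
      ha <- solar_hour_angle(lat, sc$decl, 96)
      if (is.na(ha)) {
        abort(sprintf(
          "no civil twilight at lat %.2f on %s: sun does not cross -6 deg",
          site$lat, format(date)))
      }
      sgn <- if (rising) +1 else -1
      # minutes UTC since midnight; lon in deg E
      est <- 720 - 4 * (site$lon + sgn * ha) - sc$eqtime
      gamma <- 2 * pi / yl * (doy - 1 + (est / 60 - 12) / 24)
    }
    est # minutes UTC
  }

  dawn_utc <- vapply(seq_along(dates), function(i) one_event(dates[i], TRUE), 0)
  dusk_utc <- vapply(seq_along(dates), function(i) one_event(dates[i], FALSE), 0)
  noon_utc <- (dawn_utc + dusk_utc) / 2

  base <- as.POSIXct(paste(format(dates), "00:00:00"), tz = "UTC")
  to_local <- function(min_utc) {
    t <- base + min_utc * 60
    attr(t, "tzone") <- site$tz
    t
  }
  out <- tibble::tibble(
    date = dates,
    civil_dawn = to_local(dawn_utc),
    civil_dusk = to_local(dusk_utc),
    solar_noon = to_local(noon_utc)
  )
  class(out) <- c("twilight_table", class(out))
  attr(out, "site") <- site
  out
}

#' Read / write a twilight table
#'
#' File format: CSV with header `date,civil_dawn,civil_dusk`, ISO 8601 local
#' timestamps in the site's fixed local standard time.
#'
#' @param path File path.
#' @param tz_offset_h UTC offset of the timestamps in the file.
#' @return `read_twilight()` returns a `twilight_table` tibble.
#' @export
read_twilight <- function(path, tz_offset_h) {
  stop_bad_file(path)
  tz <- tz_fixed(tz_offset_h)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("date", "civil_dawn", "civil_dusk")
  if (!all(need %in% names(raw))) {
    abort(sprintf("twilight file must have columns %s", paste(need, collapse = ", ")))
  }
  out <- tibble::tibble(
    date = as.Date(raw$date),
    civil_dawn = as.POSIXct(raw$civil_dawn, tz = tz, format = "%Y-%m-%dT%H:%M:%S"),
    civil_dusk = as.POSIXct(raw$civil_dusk, tz = tz, format = "%Y-%m-%dT%H:%M:%S")
  )
  if (anyNA(out$civil_dawn) || anyNA(out$civil_dusk)) {
    abort("unparseable timestamps in twilight file (expected ISO 8601, e.g. 2016-03-01T05:45:00)")
  }
  class(out) <- c("twilight_table", class(out))
  out
}

#' @rdname read_twilight
#' @param twilight A `twilight_table`.
#' @export
write_twilight <- function(twilight, path) {
  df <- tibble::tibble(
    date = format(twilight$date),
    civil_dawn = format(twilight$civil_dawn, "%Y-%m-%dT%H:%M:%S"),
    civil_dusk = format(twilight$civil_dusk, "%Y-%m-%dT%H:%M:%S")
  )
  readr::write_csv(df, path)
  invisible(path)
}
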