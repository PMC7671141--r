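# Weather alignment. Station records arrive at a 5-min cadence
# (timestamp, temp_c, wind_ms, precip_mm, snow_cm); snow depth is a daily
# value replicated across the day's records. Two analysis alignments:
# calendar-day covariate means for the ODBA models, and 5-h windows centred
# on civil twilight for the timing models.

#' Read / write a weather-station log
#'
#' CSV with header `timestamp,temp_c,wind_ms,precip_mm,snow_cm`, ISO 8601
#' local timestamps at a 5-min cadence; `precip_mm` is the depth accumulated
#' in the interval.
#'
#' @param path File path.
#' @param tz_offset_h UTC offset of the timestamps.
#' @return A `weather_series` tibble.
#' @export
read_weather <- function(path, tz_offset_h = 0) {
  stop_bad_file(path)
  tz <- tz_fixed(tz_offset_h)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           timestamp = readr::col_character(),
                           .default = readr::col_double()))
  need <- c("timestamp", "temp_c", "wind_ms", "precip_mm", "snow_cm")
  if (!all(need %in% names(raw))) {
    abort(sprintf("weather file must have columns %s", paste(need, collapse = ", ")))
  }
  time <- as.POSIXct(raw$timestamp, tz = tz, format = "%Y-%m-%dT%H:%M:%S")
  if (anyNA(time)) abort("unparseable timestamp in weather file")
  if (any(raw$precip_mm < 0, na.rm = TRUE)) abort("negative precipitation")
  if (any(raw$snow_cm < 0, na.rm = TRUE)) abort("negative snow depth")
  out <- tibble::tibble(time = time, temp_c = raw$temp_c, wind_ms = raw$wind_ms,
                        precip_mm = raw$precip_mm, snow_cm = raw$snow_cm)
  class(out) <- c("weather_series", class(out))
  out
}

#' @rdname read_weather
#' @param weather A `weather_series`.
#' @export
write_weather <- function(weather, path) {
  df <- tibble::tibble(
    timestamp = format(weather$time, "%Y-%m-%dT%H:%M:%S"),
    temp_c = round(weather$temp_c, 3),
    wind_ms = round(weather$wind_ms, 3),
    precip_mm = round(weather$precip_mm, 4),
    snow_cm = round(weather$snow_cm, 2)
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' Daily weather covariates
#'
#' Calendar-day means of temperature and wind, the square root of the daily
#' precipitation total (rainfall distributions are strongly right-skewed),
#' and the categorical snow depth (`ge8cm` when depth >= 8 cm — boundary
#' inclusive — else `lt8cm`). Days with cadence coverage below
#' `min_coverage` are flagged `ok = FALSE`.
#'
#' @param weather A `weather_series`.
#' @param min_coverage Minimum fraction of the 288 expected 5-min records.
#' @param snow_threshold_cm Categorisation boundary (default 8).
#' @return A tibble keyed by `date` with `temp_c`, `wind_ms`, `precip_sqrt`,
#'   `snow_cm`, `snow_cat`, `temp_x_wind`, `coverage`, `ok`.
#' @export
daily_covariates <- function(weather, min_coverage = 0.8, snow_threshold_cm = 8) {
  out <- weather |>
    dplyr::mutate(date = as.Date(format(.data$time, "%Y-%m-%d"))) |>
    dplyr::summarise(
      temp_c = mean(.data$temp_c, na.rm = TRUE),
      wind_ms = mean(.data$wind_ms, na.rm = TRUE),
      precip_total = sum(.data$precip_mm, na.rm = TRUE),
      snow_cm = max(.data$snow_cm, na.rm = TRUE),
      n = dplyr::n(),
      .by = "date") |>
    dplyr::mutate(
      precip_sqrt = sqrt(.data$precip_total),
      snow_cat = factor(ifelse(.data$snow_cm >= snow_threshold_cm, "ge8cm", "lt8cm"),
                        levels = c("lt8cm", "ge8cm")),
      temp_x_wind = wind_chill_interaction(.data$temp_c, .data$wind_ms),
      coverage = .data$n / 288,
      ok = .data$coverage >= min_coverage) |>
    dplyr::arrange(.data$date)
  dplyr::select(out, "date", "temp_c", "wind_ms", "precip_total", "precip_sqrt",
                "snow_cm", "snow_cat", "temp_x_wind", "coverage", "ok")
}

#' Weather averaged over a twilight-centred window
#'
#' Means of temperature, wind and precipitation over
#' `[t - width_h/2, t + width_h/2]` (inclusive; 61 records at the default
#' 5-h width and 5-min cadence). Partial windows are reported with their
#' coverage fraction and flagged.
#'
#' @param weather A `weather_series`.
#' @param times POSIXct vector of twilight times (one window per element).
#' @param width_h Window width in hours (default 5).
#' @return A tibble with one row per window: `window_center`, `temp_c`,
#'   `wind_ms`, `precip_total`, `precip_sqrt`, `n`, `coverage`, `ok`.
#' @export
twilight_window_covariates <- function(weather, times, width_h = 5) {
  half <- width_h * 3600 / 2
  expected <- width_h * 12 + 1
  tn <- as.numeric(weather$time)
  rows <- purrr::map(as.numeric(times), function(tc) {
    if (is.na(tc)) {
      return(tibble::tibble(temp_c = NA_real_, wind_ms = NA_real_,
                            precip_total = NA_real_, n = 0L))
    }
    sel <- tn >= tc - half & tn <= tc + half
    tibble::tibble(
      temp_c = if (any(sel)) mean(weather$temp_c[sel], na.rm = TRUE) else NA_real_,
      wind_ms = if (any(sel)) mean(weather$wind_ms[sel], na.rm = TRUE) else NA_real_,
      precip_total = if (any(sel)) sum(weather$precip_mm[sel], na.rm = TRUE) else NA_real_,
      n = sum(sel))
  })
  out <- dplyr::bind_rows(rows)
  out$window_center <- times
  out$precip_sqrt <- sqrt(out$precip_total)
  out$coverage <- out$n / expected
  out$ok <- out$coverage >= 1 - 1e-9
  dplyr::select(out, "window_center", "temp_c", "wind_ms", "precip_total",
                "precip_sqrt", "n", "coverage", "ok")
}

#' Temperature-by-wind interaction (wind chill effect)
#'
#' The wind-chill effect enters the activity models as a plain product
#' interaction term, temperature times wind speed, not as a formal
#' wind-chill index.
#'
#' @param temp_c Temperature in deg C.
#' @param wind_ms Wind speed in m/s.
#' @return `temp_c * wind_ms`.
#' @export
wind_chill_interaction <- function(temp_c, wind_ms) temp_c * wind_ms
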