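# Independent oracles. Each re-derives the quantity it checks by a route
# disjoint from the package implementation: direct loops for running means
# and ODBA, base-R group-by for aggregation, and the Michalsky (1988)
# Astronomical-Almanac solar position with a dense grid scan for twilight.

oracle_running_mean <- function(x, w) {
  h <- (w - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    win <- x[max(1, i - h):min(n, i + h)]
    mean(win, na.rm = TRUE)
  }, 0)
}

oracle_odba <- function(x, y, z, w) {
  abs(x - oracle_running_mean(x, w)) +
    abs(y - oracle_running_mean(y, w)) +
    abs(z - oracle_running_mean(z, w))
}

# --- Michalsky solar position -------------------------------------------

# Geometric solar elevation (degrees) at POSIXct `time` for lat/lon in deg.
oracle_solar_elevation <- function(time, lat, lon) {
  tu <- as.numeric(time, tz = "UTC")
  # days from J2000.0 (2000-01-01 12:00 UT)
  n <- (tu - 946728000) / 86400
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- (357.528 + 0.9856003 * n) %% 360 * pi / 180
  l <- (L + 1.915 * sin(g) + 0.020 * sin(2 * g)) * pi / 180
  ep <- (23.439 - 4e-7 * n) * pi / 180
  ra <- atan2(cos(ep) * sin(l), cos(l))
  dec <- asin(sin(ep) * sin(l))
  gmst_h <- (18.697374558 + 24.06570982441908 * n) %% 24
  lmst <- gmst_h * 15 + lon             # degrees
  ha <- (lmst - ra * 180 / pi) * pi / 180
  latr <- lat * pi / 180
  asin(sin(dec) * sin(latr) + cos(dec) * cos(latr) * cos(ha)) * 180 / pi
}

# Civil dawn/dusk by grid scan + linear interpolation of the -6 deg crossing.
oracle_civil_event <- function(date, lat, lon, tz, rising, step_s = 10) {
  midnight <- as.POSIXct(paste(as.Date(date), "00:00:00"), tz = tz)
  grid <- midnight + seq(0, 86400 - step_s, by = step_s)
  elev <- oracle_solar_elevation(grid, lat, lon)
  above <- elev > -6
  d <- diff(above)
  idx <- if (rising) which(d == 1) else which(d == -1)
  if (length(idx) == 0) return(NA)
  i <- idx[1]
  # linear interpolation between grid[i] and grid[i+1]
  e0 <- elev[i]; e1 <- elev[i + 1]
  frac <- (-6 - e0) / (e1 - e0)
  grid[i] + frac * step_s
}

# --- small builders ------------------------------------------------------

make_trace <- function(n, rate_hz = 1, start = "2016-03-01 00:00:00",
                       tz = "Etc/GMT+7", animal_id = "t1", sex = "female",
                       x = NULL, y = NULL, z = NULL) {
  t0 <- as.POSIXct(start, tz = tz)
  accel_trace(t0 + (seq_len(n) - 1) / rate_hz,
              x = x %||% rnorm(n, sd = 0.1),
              y = y %||% rnorm(n, sd = 0.1),
              z = z %||% (1 + rnorm(n, sd = 0.1)),
              animal_id = animal_id, sex = sex, rate_hz = rate_hz)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One noon-to-noon night of 1-min bins with a square-wave bout.
square_night <- function(night_date = as.Date("2016-03-01"),
                         active_from_h = 19, active_to_h = 29,
                         high = 1, rest = 0, tz = "Etc/GMT+7") {
  t0 <- as.POSIXct(paste(night_date, "12:00:00"), tz = tz)
  time <- t0 + 60 * (0:1439)
  h <- as.numeric(time - as.POSIXct(paste(night_date, "00:00:00"), tz = tz),
                  units = "hours")
  act <- ifelse(h >= active_from_h & h < active_to_h, high, rest)
  tibble::tibble(time = time, activity = act,
                 smoothed = smooth_gaussian(act, 5, 1))
}
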