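# Overall dynamic body acceleration.
#
# Gravity (static acceleration) is removed per axis by subtracting a centred
# running mean — 5 s at 1 Hz, 3 s at 10 Hz — and ODBA is the sum over the
# three axes of the absolute residuals. The window shrinks at record edges
# so output length equals input length.

#' Running-mean window length in samples for a sampling rate
#'
#' 5 s at 1 Hz and 3 s at 10 Hz by default. The length in samples,
#' `round(window_s * rate_hz)`, is forced odd (incremented by one if even)
#' so the window can be centred: 5 samples at 1 Hz, 31 at 10 Hz.
#'
#' @param rate_hz Sampling rate in Hz.
#' @param window_s_by_rate Named map from rate to window length in seconds.
#' @return Odd integer window length in samples.
#' @export
odba_window_samples <- function(rate_hz,
                                window_s_by_rate = c(`1` = 5, `3` = NA, `10` = 3)) {
  key <- as.character(rate_hz)
  if (!key %in% names(window_s_by_rate) || is.na(window_s_by_rate[[key]])) {
    abort(sprintf("no running-mean window configured for rate %g Hz", rate_hz))
  }
  w <- as.integer(round(window_s_by_rate[[key]] * rate_hz))
  if (w < 1) abort("window must span at least one sample")
  if (w %% 2 == 0) w <- w + 1L
  w
}

#' Centred running mean with edge shrinkage
#'
#' Element `i` is the mean of the samples within a centred window of
#' `window_samples`, truncated (shrunk) at the record edges; NA samples are
#' excluded from the local mean (NA where no sample is available).
#'
#' @param signal Numeric vector.
#' @param window_samples Odd window length in samples, >= 1.
#' @return Numeric vector, same length as `signal`.
#' @export
running_mean <- function(signal, window_samples) {
  n <- length(signal)
  if (n == 0) abort("empty signal")
  stopifnot(window_samples >= 1, window_samples %% 2 == 1)
  if (window_samples == 1) return(as.numeric(signal))
  h <- (window_samples - 1L) %/% 2L
  ok <- !is.na(signal)
  x0 <- ifelse(ok, signal, 0)
  cs <- c(0, cumsum(x0))
  ck <- c(0, cumsum(as.numeric(ok)))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  tot <- cs[hi + 1L] - cs[lo]
  cnt <- ck[hi + 1L] - ck[lo]
  out <- tot / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Compute ODBA from a tri-axial trace
#'
#' Per sample, `ODBA = |x - xbar| + |y - ybar| + |z - zbar|` where the bars
#' are centred running means at the rate-specific window (see
#' [odba_window_samples()]). A constant orientation contributes nothing:
#' adding a constant to any axis leaves interior ODBA unchanged.
#'
#' @param trace An [accel_trace()].
#' @param window_s Optional override of the window length in seconds.
#' @return An `odba_series` tibble with columns `time`, `odba` (g), carrying
#'   the trace metadata plus `window_s` as attributes.
#' @export
compute_odba <- function(trace, window_s = NULL) {
  rate <- trace_rate(trace)
  w <- if (is.null(window_s)) {
    odba_window_samples(rate)
  } else {
    wi <- as.integer(round(window_s * rate))
    if (wi %% 2 == 0) wi <- wi + 1L
    max(wi, 1L)
  }
  odba <- abs(trace$x - running_mean(trace$x, w)) +
    abs(trace$y - running_mean(trace$y, w)) +
    abs(trace$z - running_mean(trace$z, w))
  out <- tibble::tibble(time = trace$time, odba = odba)
  structure(out,
            class = c("odba_series", class(out)),
            animal_id = trace_animal(trace), sex = trace_sex(trace),
            rate_hz = rate, window_samples = w, window_s = w / rate)
}

#' @export
print.odba_series <- function(x, ...) {
  cat(sprintf("<odba_series> animal %s, %g Hz, window %d samples, %d samples\n",
              attr(x, "animal_id"), attr(x, "rate_hz"),
              attr(x, "window_samples"), nrow(x)))
  NextMethod()
}

#' Hourly and daily mean ODBA
#'
#' Arithmetic means of per-sample ODBA per clock hour or calendar day.
#' Coverage is the fraction of expected samples present; days (or hours)
#' with coverage below `min_coverage` are flagged `ok = FALSE` and should be
#' excluded from daily means (gaps shorter than 5 min are simply averaged
#' over, as the mean uses available samples only).
#'
#' @param series An `odba_series`.
#' @param min_coverage Minimum fraction of expected samples (default 0.8).
#' @return A tibble keyed by `hour` (POSIXct floor) or `date`, with columns
#'   `mean_odba`, `n`, `coverage`, `ok`.
#' @export
odba_hourly <- function(series, min_coverage = 0.8) {
  rate <- attr(series, "rate_hz")
  series |>
    dplyr::mutate(hour = as.POSIXct(trunc(.data$time, "hours"))) |>
    dplyr::summarise(
      mean_odba = mean(.data$odba, na.rm = TRUE),
      n = sum(!is.na(.data$odba)),
      .by = "hour") |>
    dplyr::mutate(coverage = .data$n / (3600 * rate),
                  ok = .data$coverage >= min_coverage,
                  mean_odba = ifelse(.data$n == 0, NA_real_, .data$mean_odba)) |>
    dplyr::arrange(.data$hour)
}

#' @rdname odba_hourly
#' @export
odba_daily <- function(series, min_coverage = 0.8) {
  rate <- attr(series, "rate_hz")
  series |>
    dplyr::mutate(date = as.Date(format(.data$time, "%Y-%m-%d"))) |>
    dplyr::summarise(
      mean_odba = mean(.data$odba, na.rm = TRUE),
      n = sum(!is.na(.data$odba)),
      .by = "date") |>
    dplyr::mutate(coverage = .data$n / (86400 * rate),
                  ok = .data$coverage >= min_coverage,
                  mean_odba = ifelse(.data$n == 0, NA_real_, .data$mean_odba)) |>
    dplyr::arrange(.data$date)
}

#' 1 Hz vs 10 Hz sampling equivalence check
#'
#' Decimates a 10 Hz trace to 1 Hz (every 10th sample, instantaneous
#' subsampling), computes ODBA at each rate with its own running-mean window,
#' and regresses the 1 Hz hourly means on the 10 Hz hourly means by ordinary
#' least squares. Near-identity (slope ~ 1, r^2 ~ 1) indicates the two
#' sampling rates measure the same activity signal.
#'
#' @param trace_10hz An [accel_trace()] at 10 Hz spanning >= 2 full hours.
#' @return A list with `intercept`, `slope`, `r2`, `n_hours`, and the paired
#'   hourly table `hourly`.
#' @export
compare_rates <- function(trace_10hz) {
  if (trace_rate(trace_10hz) != 10) abort("compare_rates() expects a 10 Hz trace")
  keep <- seq(1, nrow(trace_10hz), by = 10L)
  trace_1hz <- accel_trace(trace_10hz$time[keep], trace_10hz$x[keep],
                           trace_10hz$y[keep], trace_10hz$z[keep],
                           animal_id = trace_animal(trace_10hz),
                           sex = trace_sex(trace_10hz), rate_hz = 1)
  h10 <- odba_hourly(compute_odba(trace_10hz))
  h1 <- odba_hourly(compute_odba(trace_1hz))
  paired <- dplyr::inner_join(
    dplyr::select(h10, "hour", odba_10hz = "mean_odba", ok10 = "ok"),
    dplyr::select(h1, "hour", odba_1hz = "mean_odba", ok1 = "ok"),
    by = "hour") |>
    dplyr::filter(.data$ok10, .data$ok1)
  if (nrow(paired) < 2) abort("need at least 2 complete hourly pairs for the rate regression")
  if (sd(paired$odba_10hz) == 0) {
    return(list(intercept = NA_real_, slope = NA_real_, r2 = NA_real_,
                n_hours = nrow(paired), degenerate = TRUE, hourly = paired))
  }
  fit <- lm(odba_1hz ~ odba_10hz, data = paired)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       r2 = summary(fit)$r.squared, n_hours = nrow(paired),
       degenerate = FALSE, hourly = paired)
}
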