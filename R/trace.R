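# Tri-axial acceleration traces. A trace is a tibble with columns
# time (POSIXct, fixed local standard time), x, y, z (acceleration in g),
# uniformly sampled at rate_hz; gaps are explicit missing samples (NA axes),
# never silent time jumps. Metadata travel as attributes.

#' Construct an acceleration trace
#'
#' @param time POSIXct vector, strictly increasing, uniformly spaced at
#'   `rate_hz` (gaps must be explicit NA rows, not missing rows; use
#'   [read_trace()] for files with dropped rows).
#' @param x,y,z Numeric acceleration in g, same length as `time`.
#' @param animal_id Animal / deployment label.
#' @param sex `"female"` or `"male"`.
#' @param rate_hz Sampling frequency in Hz (1 or 10 in this workflow, any
#'   positive value accepted).
#' @return An `accel_trace` tibble.
#' @export
accel_trace <- function(time, x, y, z, animal_id, sex = NA_character_, rate_hz) {
  n <- length(time)
  if (n < 1) abort("trace must contain at least one sample")
  if (!all(lengths(list(x, y, z)) == n)) {
    abort("x, y, z must have the same length as time")
  }
  if (!is.numeric(rate_hz) || rate_hz <= 0) abort("rate_hz must be > 0")
  dt <- diff(as.numeric(time))
  if (any(dt <= 0)) abort("timestamps must be strictly increasing (duplicate or out-of-order rows)")
  step <- 1 / rate_hz
  if (n > 1 && abs(median(dt) - step) / step > 0.01) {
    abort(sprintf(
      "declared rate %g Hz (step %.3fs) does not match inferred median spacing %.3fs",
      rate_hz, step, median(dt)))
  }
  out <- tibble::tibble(time = time, x = as.numeric(x), y = as.numeric(y),
                        z = as.numeric(z))
  structure(out,
            class = c("accel_trace", class(out)),
            animal_id = animal_id, sex = sex, rate_hz = rate_hz)
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> animal %s (%s), %g Hz, %d samples\n",
              attr(x, "animal_id"), attr(x, "sex") %||% "?",
              attr(x, "rate_hz"), nrow(x)))
  NextMethod()
}

#' Trace metadata accessors
#' @param trace An `accel_trace`.
#' @return Scalar metadata value.
#' @export
trace_rate <- function(trace) attr(trace, "rate_hz")

#' @rdname trace_rate
#' @export
trace_animal <- function(trace) attr(trace, "animal_id")

#' @rdname trace_rate
#' @export
trace_sex <- function(trace) attr(trace, "sex")

#' Read a tri-axial accelerometer log
#'
#' File format: CSV, header `timestamp,x,y,z`, ISO 8601 local timestamps
#' (`2016-03-01T18:00:00` or with fractional seconds at 10 Hz), axes in g.
#' Out-of-order or duplicated timestamps are rejected; rows whose spacing
#' implies a gap are expanded into explicit NA samples; a >1% mismatch
#' between the declared rate and the inferred median spacing is an error.
#'
#' @param path File path.
#' @param rate_hz Declared sampling frequency in Hz.
#' @param animal_id,sex Deployment metadata attached to the trace.
#' @param tz_offset_h UTC offset of the timestamps in the file.
#' @return An `accel_trace`.
#' @export
read_trace <- function(path, rate_hz, animal_id = basename(path),
                       sex = NA_character_, tz_offset_h = 0) {
  stop_bad_file(path)
  tz <- tz_fixed(tz_offset_h)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           timestamp = readr::col_character(),
                           x = readr::col_double(),
                           y = readr::col_double(),
                           z = readr::col_double()))
  need <- c("timestamp", "x", "y", "z")
  if (!all(need %in% names(raw))) {
    abort(sprintf("trace file must have columns %s", paste(need, collapse = ", ")))
  }
  time <- as.POSIXct(raw$timestamp, tz = tz, format = "%Y-%m-%dT%H:%M:%OS")
  if (anyNA(time)) {
    bad <- which(is.na(time))[1]
    abort(sprintf("malformed timestamp at data line %d: %s", bad, raw$timestamp[bad]))
  }
  tn <- as.numeric(time)
  dt <- diff(tn)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1] + 1L
    abort(sprintf("duplicated or out-of-order timestamp at data line %d", bad))
  }
  step <- 1 / rate_hz
  if (length(dt) > 0 && abs(median(dt) - step) / step > 0.01) {
    abort(sprintf(
      "declared rate %g Hz does not match file: median spacing %.4gs, expected %.4gs",
      rate_hz, median(dt), step))
  }
  # expand gaps (spacing > 1 step) into explicit NA samples
  if (length(dt) > 0 && any(dt > 1.5 * step)) {
    idx <- round((tn - tn[1]) / step)
    full <- seq(0L, idx[length(idx)])
    x <- y <- z <- rep(NA_real_, length(full))
    pos <- idx + 1L
    x[pos] <- raw$x; y[pos] <- raw$y; z[pos] <- raw$z
    time <- time[1] + full * step
  } else {
    x <- raw$x; y <- raw$y; z <- raw$z
  }
  accel_trace(time, x, y, z, animal_id = animal_id, sex = sex, rate_hz = rate_hz)
}

#' Write a trace in the canonical CSV format
#'
#' Round-trips with [read_trace()]: for canonical gap-free files,
#' `write_trace(read_trace(f))` reproduces the parsed content exactly.
#' Explicit NA gap samples are dropped on write (the file format represents
#' gaps as absent rows).
#'
#' @param trace An `accel_trace`.
#' @param path Output path.
#' @param digits Number of digits for axis values (default 6).
#' @export
write_trace <- function(trace, path, digits = 6) {
  keep <- !(is.na(trace$x) & is.na(trace$y) & is.na(trace$z))
  fmt_time <- if (trace_rate(trace) > 1) "%Y-%m-%dT%H:%M:%OS1" else "%Y-%m-%dT%H:%M:%S"
  df <- tibble::tibble(
    timestamp = format(trace$time[keep], fmt_time),
    x = round(trace$x[keep], digits),
    y = round(trace$y[keep], digits),
    z = round(trace$z[keep], digits)
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' Partition samples into noon-to-noon nights
#'
#' Adds a `night_date` column assigning every sample to exactly one
#' noon-to-noon night (see [night_of()]). Used for all nightly timing
#' metrics; calendar-day grouping is used for mean daily ODBA.
#'
#' @param df A tibble with a POSIXct `time` column (trace or ODBA series).
#' @param boundary_h Clock hour of the night boundary (default 12).
#' @return The input with a `night_date` column appended.
#' @export
to_activity_days <- function(df, boundary_h = 12) {
  if (nrow(df) == 0) abort("empty series")
  dplyr::mutate(tibble::as_tibble(df), night_date = night_of(.data$time, boundary_h))
}
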