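# Nightly activity onset/offset detection on ODBA series.
#
# The detector re-implements the classic actogram-tool approach: bin the
# ODBA series (1-min bins), smooth with a Gaussian kernel (SD = 5 min),
# threshold at the median of the animal's whole smoothed record, and take
# the first sustained upward crossing of a noon-to-noon night as onset and
# the last sustained downward crossing as offset. Plausibility filters keep
# onsets in 15:00-23:00 and offsets in 01:00-09:00 local clock time;
# filtered or undetectable nights are flagged, never silently dropped.

#' Detector configuration
#'
#' @param kernel_sd_min Gaussian smoothing SD in minutes (default 5).
#' @param threshold_rule `"median_of_record"` (median of the animal's whole
#'   smoothed deployment record) or `"median_of_night"`.
#' @param onset_window,offset_window Clock-hour intervals (inclusive) within
#'   which detections are plausible; defaults 15:00-23:00 and 01:00-09:00.
#' @param min_sustained_min Minutes the signal must stay on the crossing
#'   side of the threshold for a crossing to qualify (default 30); this
#'   makes the detector's failure mode on low or ultradian (fragmented)
#'   activity explicit: such nights yield `no_detection`.
#' @param bin_min Bin width in minutes (must divide 60, default 1).
#' @param min_night_coverage Minimum fraction of non-missing bins for a
#'   night to be scored (default 0.8).
#' @return A `detector_config` list.
#' @export
detector_config <- function(kernel_sd_min = 5,
                            threshold_rule = c("median_of_record", "median_of_night"),
                            onset_window = c(15, 23),
                            offset_window = c(1, 9),
                            min_sustained_min = 30,
                            bin_min = 1,
                            min_night_coverage = 0.8) {
  stopifnot(kernel_sd_min > 0, 60 %% bin_min == 0, min_sustained_min >= 0)
  if (onset_window[1] < offset_window[2] && onset_window[2] > offset_window[1]) {
    # windows share no clock hours by construction of the defaults; overlap
    # would make a single crossing attributable to both events
    if (!(onset_window[1] >= offset_window[2] || onset_window[2] <= offset_window[1])) {
      abort("onset and offset windows must not overlap")
    }
  }
  structure(list(kernel_sd_min = kernel_sd_min,
                 threshold_rule = match.arg(threshold_rule),
                 onset_window = onset_window, offset_window = offset_window,
                 min_sustained_min = min_sustained_min, bin_min = bin_min,
                 min_night_coverage = min_night_coverage),
            class = "detector_config")
}

#' Bin an ODBA series into fixed-width activity bins
#'
#' Mean per-sample ODBA per bin over a complete regular bin grid spanning
#' the record; bins with no samples are missing (NA), never zero.
#'
#' @param series An `odba_series`.
#' @param bin_min Bin width in minutes, must divide 60.
#' @return A tibble with `time` (bin start), `activity` (mean ODBA in g) and
#'   `n` (samples in bin).
#' @export
bin_activity <- function(series, bin_min = 1) {
  stopifnot(60 %% bin_min == 0)
  step <- bin_min * 60
  tn <- as.numeric(series$time)
  bin <- floor(tn / step) * step
  agg <- series |>
    dplyr::mutate(bin = bin) |>
    dplyr::summarise(activity = if (all(is.na(.data$odba))) NA_real_
                     else mean(.data$odba, na.rm = TRUE),
                     n = sum(!is.na(.data$odba)), .by = "bin")
  grid <- tibble::tibble(bin = seq(min(bin), max(bin), by = step))
  out <- dplyr::left_join(grid, agg, by = "bin") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  tz <- attr(series$time, "tzone") %||% "UTC"
  tibble::tibble(time = as.POSIXct(out$bin, tz = tz, origin = "1970-01-01"),
                 activity = out$activity, n = out$n)
}

#' Gaussian kernel smoothing with missing-aware renormalisation
#'
#' Convolves with a normalized Gaussian kernel truncated at +/- 4 SD.
#' Missing bins get zero weight and the kernel is renormalised over the
#' available weights (no imputation); the same renormalisation handles the
#' record edges.
#'
#' @param x Numeric vector (may contain NA).
#' @param sd_min Kernel SD in minutes.
#' @param bin_min Bin width of `x` in minutes.
#' @return Smoothed numeric vector, same length; NA where no data fall
#'   within +/- 4 SD.
#' @export
smooth_gaussian <- function(x, sd_min = 5, bin_min = 1) {
  if (all(is.na(x))) abort("cannot smooth an all-missing record")
  stopifnot(sd_min > 0)
  sd_bins <- sd_min / bin_min
  h <- ceiling(4 * sd_bins)
  k <- dnorm(seq(-h, h), sd = sd_bins)
  k <- k / sum(k)
  n <- length(x)
  ok <- !is.na(x)
  x0 <- ifelse(ok, x, 0)
  pad <- rep(0, h)
  xp <- c(pad, x0, pad)
  op <- c(pad, as.numeric(ok), pad)
  num <- stats::filter(xp, k, sides = 2)[(h + 1):(h + n)]
  den <- stats::filter(op, k, sides = 2)[(h + 1):(h + n)]
  out <- as.numeric(num / den)
  out[den == 0] <- NA_real_
  out
}

#' Is a timestamp inside a clock-hour window?
#'
#' Inclusive on both bounds; used for the onset (15:00-23:00) and offset
#' (01:00-09:00) plausibility filters.
#'
#' @param time POSIXct vector.
#' @param window Numeric `c(from_h, to_h)` in local clock hours.
#' @return Logical vector.
#' @export
in_clock_window <- function(time, window) {
  ch <- clock_hours(time)
  ch >= window[1] & ch <= window[2]
}

# Run-length representation of above-threshold state; NA treated as below
# (a missing bin cannot evidence sustained activity).
crossing_candidates <- function(above) {
  above[is.na(above)] <- FALSE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(value = r$values, start = starts, end = ends,
                 length = r$lengths)
}

#' Detect activity onset and offset within one noon-to-noon night
#'
#' Onset is the first upward threshold crossing of the night followed by at
#' least `min_sustained_min` above threshold; offset is the last downward
#' crossing preceded by at least `min_sustained_min` above threshold (its
#' time is the first below-threshold bin). Candidates falling outside the
#' plausibility windows are flagged (`onset_out_of_window` /
#' `offset_out_of_window`) and reported as absent. A run that begins at the
#' night boundary is not a crossing.
#'
#' @param night A tibble with `time` and `smoothed` covering one night.
#' @param threshold Numeric threshold (median of the smoothed record).
#' @param config A [detector_config()].
#' @return A one-row tibble: `onset`, `offset` (POSIXct or NA), flags
#'   `no_detection`, `onset_out_of_window`, `offset_out_of_window`.
#' @export
detect_onset_offset <- function(night, threshold, config = detector_config()) {
  sustain_bins <- ceiling(config$min_sustained_min / config$bin_min)
  cov <- mean(!is.na(night$smoothed))
  res <- tibble::tibble(onset = night$time[NA_integer_],
                        offset = night$time[NA_integer_],
                        no_detection = FALSE,
                        onset_out_of_window = FALSE,
                        offset_out_of_window = FALSE,
                        low_coverage = FALSE)
  if (cov < config$min_night_coverage) {
    res$no_detection <- TRUE
    res$low_coverage <- TRUE
    return(res)
  }
  runs <- crossing_candidates(night$smoothed > threshold)
  up <- runs[runs$value & runs$start > 1L & runs$length >= sustain_bins, ]
  down <- runs[runs$value & runs$end < nrow(night) & runs$length >= sustain_bins, ]
  onset_t <- if (nrow(up) > 0) night$time[up$start[1]] else NULL
  offset_t <- if (nrow(down) > 0) night$time[down$end[nrow(down)] + 1L] else NULL
  if (is.null(onset_t) && is.null(offset_t)) {
    res$no_detection <- TRUE
    return(res)
  }
  if (!is.null(onset_t)) {
    if (in_clock_window(onset_t, config$onset_window)) {
      res$onset <- onset_t
    } else {
      res$onset_out_of_window <- TRUE
    }
  }
  if (!is.null(offset_t)) {
    if (in_clock_window(offset_t, config$offset_window)) {
      res$offset <- offset_t
    } else {
      res$offset_out_of_window <- TRUE
    }
  }
  if (is.na(res$onset) && is.na(res$offset)) {
    res$no_detection <- is.null(onset_t) && is.null(offset_t)
  }
  res
}

#' Activity bout duration
#'
#' Difference between the time of activity offset and activity onset, in
#' decimal hours, correctly spanning midnight.
#'
#' @param onset,offset POSIXct (offset strictly after onset).
#' @return Duration in hours.
#' @export
bout_duration <- function(onset, offset) {
  d <- as.numeric(difftime(offset, onset, units = "hours"))
  if (any(!is.na(d) & d <= 0)) abort("offset must occur after onset")
  d
}

#' Event time relative to civil twilight
#'
#' Signed minutes, positive when the event occurs after its reference
#' twilight (onset after civil dusk, offset after civil dawn) and negative
#' before.
#'
#' @param event,twilight POSIXct vectors on the same night.
#' @return Signed minutes.
#' @export
relative_to_twilight <- function(event, twilight) {
  as.numeric(difftime(event, twilight, units = "mins"))
}

#' Score every night of a deployment
#'
#' Bins and smooths the whole ODBA record, thresholds at the record median
#' (or per-night median), detects onset/offset per noon-to-noon night, and
#' attaches twilight-relative times and bout durations. Nights at the record
#' boundaries (first/last partial nights) are scored like any other and will
#' typically come out flagged.
#'
#' @param series An `odba_series` for one deployment.
#' @param twilight A `twilight_table` covering the deployment dates; dusk is
#'   looked up on the night date and dawn on the following morning's date.
#' @param config A [detector_config()].
#' @return An `activity_days` tibble: one row per night with `animal_id`,
#'   `night_date`, `onset`, `offset`, `duration_h`, `onset_rel_dusk_min`,
#'   `offset_rel_dawn_min`, flags, and `snow_excluded` (initialised FALSE).
#' @export
detect_activity_days <- function(series, twilight, config = detector_config()) {
  bins <- bin_activity(series, config$bin_min)
  bins$smoothed <- smooth_gaussian(bins$activity, config$kernel_sd_min, config$bin_min)
  bins$night_date <- night_of(bins$time)
  record_threshold <- median(bins$smoothed, na.rm = TRUE)

  nights <- split(bins, bins$night_date)
  rows <- purrr::imap(nights, function(nb, nd) {
    thr <- if (config$threshold_rule == "median_of_record") record_threshold
           else median(nb$smoothed, na.rm = TRUE)
    det <- detect_onset_offset(nb, thr, config)
    det$night_date <- as.Date(nd)
    det$threshold <- thr
    det
  })
  out <- dplyr::bind_rows(rows)
  out$animal_id <- attr(series, "animal_id")
  out$sex <- attr(series, "sex")

  dusk <- twilight$civil_dusk[match(out$night_date, twilight$date)]
  dawn <- twilight$civil_dawn[match(out$night_date + 1L, twilight$date)]
  out$onset_rel_dusk_min <- relative_to_twilight(out$onset, dusk)
  out$offset_rel_dawn_min <- relative_to_twilight(out$offset, dawn)
  out$duration_h <- ifelse(!is.na(out$onset) & !is.na(out$offset),
                           as.numeric(difftime(out$offset, out$onset, units = "hours")),
                           NA_real_)
  if (any(!is.na(out$duration_h) & out$duration_h <= 0)) {
    abort("internal inconsistency: detected offset not after onset")
  }
  out$snow_excluded <- FALSE
  out <- dplyr::select(out, "animal_id", "sex", "night_date", "onset", "offset",
                       "duration_h", "onset_rel_dusk_min", "offset_rel_dawn_min",
                       "no_detection", "onset_out_of_window",
                       "offset_out_of_window", "low_coverage", "snow_excluded",
                       "threshold")
  class(out) <- c("activity_days", class(out))
  out
}

#' Exclude snow-covered days from timing analyses
#'
#' Nights whose snow depth is at or above `threshold_cm` (inclusive, i.e.
#' exactly 8 cm is excluded at the default) are flagged `snow_excluded`;
#' nights with no snow record are flagged and excluded conservatively.
#' Snow-excluded nights are removed from timing analyses but retained for
#' ODBA analyses.
#'
#' @param days An `activity_days` tibble.
#' @param snow_daily Tibble with `date` and `snow_cm` (daily depth).
#' @param threshold_cm Depth threshold in cm (default 8).
#' @param drop If TRUE (default) rows flagged `snow_excluded` are removed;
#'   if FALSE they are retained with the flag set.
#' @return The filtered (or flagged) `activity_days` tibble.
#' @export
exclude_snow_days <- function(days, snow_daily, threshold_cm = 8, drop = TRUE) {
  snow <- snow_daily$snow_cm[match(days$night_date, snow_daily$date)]
  days$snow_excluded <- is.na(snow) | snow >= threshold_cm
  if (drop) days[!days$snow_excluded, ] else days
}

#' Nights usable for timing models
#'
#' Keeps nights with both onset and offset detected, in-window, and not
#' snow-excluded.
#' @param days An `activity_days` tibble.
#' @return Filtered tibble.
#' @export
timing_days <- function(days) {
  days[!is.na(days$onset) & !is.na(days$offset) & !days$snow_excluded, ]
}
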