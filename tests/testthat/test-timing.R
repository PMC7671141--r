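test_that("binned activity equals an independent group-by and preserves missingness", {
  set.seed(61)
  n <- 3 * 3600
  tr <- make_trace(n, start = "2016-03-01 14:00:00")
  series <- compute_odba(tr)
  bins <- bin_activity(series, 1)
  ref <- tapply(series$odba, floor(as.numeric(series$time) / 60), mean)
  expect_equal(bins$activity, unname(c(ref)))
  expect_equal(nrow(bins), 180)

  # constant ODBA -> constant bins
  series$odba <- rep(0.3, n)
  expect_true(all(bin_activity(series, 5)$activity == 0.3))

  # an empty hour yields missing bins, not zeros
  gap <- series[format(series$time, "%H") != "15", ]
  class(gap) <- class(series)
  attr(gap, "rate_hz") <- 1
  bg <- bin_activity(gap, 1)
  gap_bins <- bg$activity[format(bg$time, "%H") == "15"]
  expect_equal(length(gap_bins), 60)
  expect_true(all(is.na(gap_bins)))
  expect_true(all(bg$n[format(bg$time, "%H") == "15"] == 0))
})

test_that("Gaussian smoothing is normalized, mass-preserving, and oracle-exact", {
  expect_equal(smooth_gaussian(rep(2, 100), 5, 1), rep(2, 100))

  # unit impulse spreads into a discrete Gaussian profile of mass 1
  x <- numeric(201); x[101] <- 1
  sm <- smooth_gaussian(x, 5, 1)
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  expect_equal(which.max(sm), 101)
  expect_equal(sm[101 + 5], sm[101 - 5])

  # step input: monotone sigmoid transition, midpoint at the step, matching
  # a brute-force truncated-kernel convolution
  x <- c(rep(0, 100), rep(1, 100))
  sm <- smooth_gaussian(x, 5, 1)
  core <- sm[30:170]
  expect_true(all(diff(core) >= -1e-12))
  # the step sits between bins 100 and 101: their mean is the 50% point
  expect_equal((sm[100] + sm[101]) / 2, 0.5, tolerance = 0.01)
  h <- ceiling(4 * 5)
  k <- dnorm(-h:h, sd = 5); k <- k / sum(k)
  brute <- vapply(seq_along(x), function(i) {
    j <- (i - h):(i + h)
    ok <- j >= 1 & j <= length(x)
    sum(k[ok] * x[j[ok]]) / sum(k[ok])
  }, 0)
  expect_equal(sm, brute, tolerance = 1e-12)

  # mass preservation for interior-supported signals
  set.seed(62)
  x <- numeric(500); x[100:400] <- runif(301)
  expect_equal(sum(smooth_gaussian(x, 5, 1)), sum(x), tolerance = 1e-9)

  # missing bins get zero weight, no imputation
  x <- rep(1, 100); x[40:45] <- NA
  sm <- smooth_gaussian(x, 5, 1)
  expect_equal(sm[!is.na(sm)], rep(1, sum(!is.na(sm))), tolerance = 1e-12)
  expect_error(smooth_gaussian(rep(NA_real_, 10), 5, 1), "all-missing")
})

test_that("square-wave nights are detected at the crossings, within one kernel SD", {
  night <- square_night(active_from_h = 19, active_to_h = 29, high = 1)
  det <- detect_onset_offset(night, threshold = 0.4)
  expect_false(det$no_detection)
  t0 <- as.POSIXct("2016-03-01 19:00:00", tz = "Etc/GMT+7")
  t1 <- as.POSIXct("2016-03-02 05:00:00", tz = "Etc/GMT+7")
  expect_lt(abs(as.numeric(difftime(det$onset, t0, units = "mins"))), 5)
  expect_lt(abs(as.numeric(difftime(det$offset, t1, units = "mins"))), 5)
  expect_equal(bout_duration(det$onset, det$offset), 10, tolerance = 0.1)
})

test_that("all-zero and ultradian nights yield flagged non-detections", {
  night <- square_night(high = 0)
  det <- detect_onset_offset(night, threshold = 0)
  expect_true(det$no_detection)
  expect_true(is.na(det$onset) && is.na(det$offset))

  # 15-min bursts never satisfy the 30-min sustained-crossing rule
  t0 <- as.POSIXct("2016-03-01 12:00:00", tz = "Etc/GMT+7")
  time <- t0 + 60 * (0:1439)
  act <- rep(0, 1440)
  for (s in seq(420, 1020, by = 60)) act[s:(s + 15)] <- 1
  night <- tibble::tibble(time = time, activity = act,
                          smoothed = smooth_gaussian(act, 5, 1))
  det <- detect_onset_offset(night, threshold = 0.5)
  expect_true(det$no_detection)
})

test_that("out-of-window candidates are flagged and reported absent", {
  # activity starting 14:30 -> onset candidate precedes the 15:00-23:00 window
  night <- square_night(active_from_h = 14.5, active_to_h = 29, high = 1)
  det <- detect_onset_offset(night, threshold = 0.4)
  expect_true(det$onset_out_of_window)
  expect_true(is.na(det$onset))
  expect_false(is.na(det$offset))       # 05:00 offset is in-window

  # offset at 10:30 -> outside 01:00-09:00
  night <- square_night(active_from_h = 19, active_to_h = 34.5, high = 1)
  det <- detect_onset_offset(night, threshold = 0.4)
  expect_true(det$offset_out_of_window)
  expect_true(is.na(det$offset))
  expect_false(is.na(det$onset))
})

test_that("nights with insufficient coverage are flagged, not scored", {
  night <- square_night(active_from_h = 19, active_to_h = 29, high = 1)
  night$smoothed[1:500] <- NA
  det <- detect_onset_offset(night, threshold = 0.4)
  expect_true(det$low_coverage)
  expect_true(det$no_detection)
})

test_that("bout duration spans midnight and rejects inverted events", {
  tz <- "Etc/GMT+7"
  on <- as.POSIXct("2016-03-01 19:00:00", tz = tz)
  off <- as.POSIXct("2016-03-02 05:00:00", tz = tz)
  expect_equal(bout_duration(on, off), 10)
  expect_equal(bout_duration(as.POSIXct("2016-03-01 18:26:00", tz = tz),
                             as.POSIXct("2016-03-02 06:02:00", tz = tz)),
               11.6)
  expect_error(bout_duration(on, on), "after onset")
  expect_error(bout_duration(off, on), "after onset")
})

test_that("twilight-relative times follow the positive-after convention", {
  tz <- "Etc/GMT+7"
  dusk <- as.POSIXct("2016-03-01 18:30:00", tz = tz)
  expect_equal(relative_to_twilight(dusk, dusk), 0)
  expect_equal(relative_to_twilight(dusk + 51 * 60, dusk), 51)
  dawn <- as.POSIXct("2016-03-02 06:00:00", tz = tz)
  expect_equal(relative_to_twilight(dawn + 75 * 60, dawn), 75)
  expect_equal(relative_to_twilight(dawn - 30 * 60, dawn), -30)
})

test_that("snow-day exclusion counts match hand counts and commutes with detection filters", {
  days <- tibble::tibble(
    animal_id = "a1",
    night_date = as.Date("2016-01-01") + 0:22,
    onset = as.POSIXct("2016-01-01 19:00:00", tz = "Etc/GMT+7") + (0:22) * 86400,
    offset = as.POSIXct("2016-01-02 05:00:00", tz = "Etc/GMT+7") + (0:22) * 86400,
    snow_excluded = FALSE)
  snow <- tibble::tibble(date = days$night_date,
                         snow_cm = c(rep(0, 10), 8, 9, 12, 8, rep(2, 9)))
  kept <- exclude_snow_days(days, snow)
  expect_equal(nrow(kept), 19)          # 23 days, 4 at >= 8 cm

  # boundary is inclusive: 8 cm excluded, 7.9 retained
  snow2 <- snow; snow2$snow_cm <- c(rep(7.9, 22), 8)
  expect_equal(nrow(exclude_snow_days(days, snow2)), 22)

  # zero-snow record: identity
  snow3 <- snow; snow3$snow_cm <- 0
  expect_equal(nrow(exclude_snow_days(days, snow3)), 23)

  # missing snow record: conservative exclusion
  snow4 <- snow[-3, ]
  flagged <- exclude_snow_days(days, snow4, drop = FALSE)
  expect_true(flagged$snow_excluded[3])

  # order independence with the detection-completeness filter
  days2 <- days
  days2$onset[5] <- NA                  # an undetected night
  a <- timing_days(exclude_snow_days(days2, snow, drop = FALSE))
  b <- exclude_snow_days(timing_days(days2), snow, drop = FALSE)
  b <- b[!b$snow_excluded, ]
  expect_equal(a$night_date, b$night_date)
  # idempotence
  expect_equal(exclude_snow_days(kept, snow), kept)
})

test_that("whole-deployment scoring recovers simulated nights end to end", {
  set.seed(63)
  cfg <- sim_config(seed = 63)
  dates <- seq(as.Date("2016-07-01"), by = "day", length.out = 5)
  sim <- simulate_trace(cfg, "a1", "female", "lactation", dates)
  series <- compute_odba(sim$trace)
  tw <- civil_twilight(flagstaff_site(), seq(min(dates) - 1, max(dates) + 1, by = "day"))
  days <- detect_activity_days(series, tw)
  expect_s3_class(days, "activity_days")

  full <- days[days$night_date %in% sim$truth$night_date[sim$truth$complete], ]
  got <- full[!is.na(full$onset) & !is.na(full$offset), ]
  expect_gte(nrow(got), 3)              # consolidated lactation nights detect reliably
  j <- merge(got, sim$truth, by = "night_date")
  err_on <- abs(as.numeric(difftime(j$onset, j$true_onset, units = "mins")))
  expect_lt(median(err_on), 30)         # median-threshold rule bias stays bounded
  expect_equal(got$duration_h,
               as.numeric(difftime(got$offset, got$onset, units = "hours")))
  # twilight-relative columns agree with direct recomputation
  dusk <- tw$civil_dusk[match(got$night_date, tw$date)]
  expect_equal(got$onset_rel_dusk_min,
               as.numeric(difftime(got$onset, dusk, units = "mins")))
})
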