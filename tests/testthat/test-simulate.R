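small_cfg <- function(...) {
  sim_config(n_animals = 2, days_per_stage = 2,
             stages = default_stages()[c(1, 4), ], ...)
}

test_that("identical config and seed give bit-identical studies", {
  a <- simulate_study(small_cfg(seed = 101))
  b <- simulate_study(small_cfg(seed = 101))
  expect_identical(a$truth, b$truth)
  expect_identical(a$weather, b$weather)
  for (k in names(a$traces)) expect_identical(a$traces[[k]], b$traces[[k]])
  c <- simulate_study(small_cfg(seed = 102))
  expect_false(identical(a$traces[[1]]$x, c$traces[[1]]$x))
})

test_that("deployment layout honors the no-males-in-lactation design", {
  cfg <- sim_config(n_animals = 6, days_per_stage = 3)
  layout <- deployment_layout(cfg)
  lact <- layout[layout$stage == "lactation", ]
  expect_true(all(lact$sex == "female"))
  expect_equal(nrow(lact), 3)
  other <- layout[layout$stage != "lactation", ]
  expect_equal(nrow(other), 3 * 6)
  # truth rows: one per deployment night (deployment days + the opening
  # partial night)
  study <- simulate_study(small_cfg(seed = 103))
  per_dep <- table(paste(study$truth$animal_id, study$truth$stage))
  expect_true(all(per_dep == 3))        # 2 days -> 3 noon-boundary nights
  expect_equal(sum(study$truth$complete),
               nrow(study$layout) * 1)  # days_per_stage - 1 interior nights
})

test_that("active-state ODBA calibration hits its target within 5%", {
  set.seed(104)
  cfg <- sim_config(rules = dplyr::mutate(default_activity_rules(), frag_prob = 0),
                    sd_night_g = 0, sd_animal_g = 0)
  dates <- seq(as.Date("2016-07-01"), by = "day", length.out = 2)
  sim <- simulate_trace(cfg, "a1", "female", "lactation", dates,
                        b_time = 0, b_int = 0)
  od <- compute_odba(sim$trace)
  tn <- as.numeric(od$time)
  tru <- sim$truth[sim$truth$complete, ][1, ]
  act <- tn >= as.numeric(tru$true_onset) + 60 & tn < as.numeric(tru$true_offset) - 60
  expect_gt(sum(act), 3600)
  realized <- mean(od$odba[act], na.rm = TRUE)
  expect_lt(abs(realized - tru$intensity_g) / tru$intensity_g, 0.05)

  # rest state is near-zero: daytime ODBA well below active
  hod <- as.integer(format(od$time, "%H"))
  rest <- od$odba[hod %in% 10:11]
  expect_lt(mean(rest, na.rm = TRUE), 0.1 * tru$intensity_g)
})

test_that("simulated weather has the advertised structure", {
  set.seed(105)
  cfg <- sim_config()
  wx <- simulate_weather(cfg, as.Date("2015-11-01"), as.Date("2016-09-30"))
  w <- wx$weather
  expect_equal(as.numeric(diff(w$time)[1], units = "mins"), 5)
  expect_true(all(w$precip_mm >= 0) && all(w$snow_cm >= 0))

  # snow episodes confined to the winter months and crossing the 8 cm boundary
  sd <- wx$snow_daily
  mo <- as.integer(format(sd$date, "%m"))
  expect_true(all(sd$snow_cm[mo %in% 5:9] == 0))
  expect_gt(sum(sd$snow_cm >= 8), 3)
  expect_gt(sum(sd$snow_cm > 0 & sd$snow_cm < 8), 3)

  # rain only in the monsoon window
  rain_dates <- unique(as.Date(format(w$time[w$precip_mm > 0], "%Y-%m-%d")))
  expect_true(all(as.integer(format(rain_dates, "%m")) %in% 6:9))

  # seasonal means: winter colder than summer by roughly the configured swing
  daily <- daily_covariates(w)
  dmo <- as.integer(format(daily$date, "%m"))
  expect_lt(mean(daily$temp_c[dmo == 12]), 5)
  expect_gt(mean(daily$temp_c[dmo == 7]), 12)
})

test_that("suppressed snow nights have low detectability, unlike clear nights", {
  set.seed(106)
  cfg <- sim_config(snow_suppression = 1)
  dates <- seq(as.Date("2015-12-01"), by = "day", length.out = 16)
  snow <- tibble::tibble(date = seq(min(dates) - 1, max(dates) + 1, by = "day"),
                         snow_cm = 12)
  sim <- simulate_trace(cfg, "a1", "female", "winter", dates, snow_daily = snow)
  expect_true(all(sim$truth$suppressed))
  tw <- civil_twilight(flagstaff_site(), seq(min(dates) - 1, max(dates) + 1, by = "day"))
  days <- detect_activity_days(compute_odba(sim$trace), tw)
  full <- days[days$night_date %in% sim$truth$night_date[sim$truth$complete], ]
  snow_rate <- mean(!is.na(full$onset) & !is.na(full$offset))
  expect_lt(snow_rate, 0.5)             # most ultradian nights defeat the detector

  # the same animal on clear consolidated nights is detected reliably
  cfg2 <- sim_config(rules = dplyr::mutate(default_activity_rules(), frag_prob = 0))
  sim2 <- simulate_trace(cfg2, "a1", "female", "winter", dates,
                         snow_daily = NULL, b_time = 0, b_int = 0)
  days2 <- detect_activity_days(compute_odba(sim2$trace), tw)
  full2 <- days2[days2$night_date %in% sim2$truth$night_date[sim2$truth$complete], ]
  clear_rate <- mean(!is.na(full2$onset) & !is.na(full2$offset))
  expect_gt(clear_rate, 0.8)
  expect_lt(snow_rate, clear_rate)
})

test_that("day-record generator matches its declared design", {
  set.seed(107)
  rec <- simulate_day_records(n_animals = 5, n_days = 40)
  expect_equal(nrow(rec), 200)
  expect_equal(length(unique(rec$animal_id)), 5)
  expect_equal(unname(table(rec$stage)[c("winter", "mating", "lactation", "fattening")]),
               rep(50L, 4), ignore_attr = TRUE)
  truth <- attr(rec, "truth")
  expect_equal(truth$stage_effects[["lactation"]], 0.15)
  # stage means reflect the configured effects at generous tolerance
  m <- tapply(rec$mean_daily_odba, rec$stage, mean)
  expect_gt(m[["lactation"]], m[["winter"]] + 0.1)
})
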