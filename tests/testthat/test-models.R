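test_that("the stage/weather co-specification guard and input checks fire", {
  expect_error(model_spec("mean_daily_odba", fixed = c("stage", "temp_c")),
               "cannot co-occur")
  expect_error(model_spec("mean_daily_odba", fixed = c("stage", "snow_cat")),
               "cannot co-occur")
  expect_error(model_spec("mean_daily_odba", fixed = "elevation"), "unknown fixed")
  spec <- model_spec("mean_daily_odba", fixed = "stage")
  expect_s3_class(spec, "model_spec")

  set.seed(91)
  rec <- simulate_day_records(n_animals = 4, n_days = 20)
  one <- rec[rec$animal_id == "skunk01", ]
  expect_error(fit_activity_lmm(one, spec), "at least 2 individuals")
  expect_error(fit_activity_lmm(dplyr::select(rec, -"stage"), spec), "missing column")
})

test_that("balanced designs give lsmeans equal to raw group means, 6 Tukey pairs", {
  set.seed(92)
  rec <- simulate_day_records(n_animals = 6, n_days = 40, sd_day = 0,
                              sd_animal = 0.02, sd_resid = 0.02)
  fit <- fit_activity_lmm(rec, model_spec("mean_daily_odba", fixed = "stage",
                                          random = "individual"))
  ls <- lsmeans_tukey(fit, "stage")
  expect_equal(nrow(ls$contrasts), 6)   # k(k-1)/2 with k = 4
  raw <- tapply(rec$mean_daily_odba, rec$stage, mean)
  expect_equal(ls$lsmeans$lsmean[match(names(raw), ls$lsmeans$level)],
               as.numeric(raw), tolerance = 1e-6)
  expect_error(lsmeans_tukey(fit, "sex"), "not a fixed effect")
})

test_that("well-separated stages are all significant; null stages are not", {
  set.seed(93)
  rec <- simulate_day_records(n_animals = 8, n_days = 40,
                              stage_effects = c(winter = 0, mating = 0.5,
                                                lactation = 1, fattening = 1.5),
                              sd_animal = 0.02, sd_day = 0.01, sd_resid = 0.05)
  fit <- fit_activity_lmm(rec, model_spec("mean_daily_odba", fixed = "stage"))
  ls <- lsmeans_tukey(fit, "stage")
  expect_true(all(ls$contrasts$significant))

  # null simulation: stage estimates near zero, mostly non-significant CIs
  hits <- 0
  for (r in 1:10) {
    rec0 <- simulate_day_records(n_animals = 8, n_days = 40,
                                 stage_effects = c(winter = 0, mating = 0,
                                                   lactation = 0, fattening = 0))
    fit0 <- fit_activity_lmm(rec0, model_spec("mean_daily_odba", fixed = "stage"))
    td <- tidy(fit0)
    stage_rows <- td[grepl("^stage", td$term), ]
    hits <- hits + sum(stage_rows$conf_low <= 0 & stage_rows$conf_high >= 0)
  }
  expect_gte(hits / 30, 0.9)            # 3 stage terms x 10 replicates
})

test_that("fixed effects and variance components are recovered from the generative model", {
  set.seed(94)
  ests <- covered <- NULL
  for (r in 1:8) {
    rec <- simulate_day_records(n_animals = 12, n_days = 60)
    fit <- fit_activity_lmm(rec, model_spec("mean_daily_odba", fixed = "stage"))
    td <- tidy(fit)
    lact <- td[td$term == "stagelactation", ]
    ests <- c(ests, lact$estimate)
    covered <- c(covered, lact$conf_low <= 0.15 & lact$conf_high >= 0.15)
  }
  expect_lt(abs(mean(ests) - 0.15), 0.01)
  expect_gte(sum(covered), 6)
  g <- glance(fit_activity_lmm(rec, model_spec("mean_daily_odba", fixed = "stage")))
  expect_gt(g$sigma2, 0)
  expect_true(all(c("tau00_animal_id", "tau00_day_of_year") %in% names(g)))
  expect_equal(g$nobs, nrow(rec))
})

test_that("residual diagnostics separate normal from heavy-tailed errors", {
  set.seed(95)
  rec <- simulate_day_records(n_animals = 10, n_days = 60)
  fit <- fit_activity_lmm(rec, model_spec("mean_daily_odba", fixed = "stage"))
  d <- residual_diagnostics(fit)
  expect_gt(d$straightness, 0.99)
  expect_false(d$flag)
  expect_equal(nrow(d$qq), nrow(rec))

  heavy <- rec
  heavy$mean_daily_odba <- heavy$mean_daily_odba + 0.05 * stats::rt(nrow(rec), df = 2)
  fith <- fit_activity_lmm(heavy, model_spec("mean_daily_odba", fixed = "stage"))
  dh <- residual_diagnostics(fith)
  expect_lt(dh$straightness, d$straightness)
  expect_true(dh$flag)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("sex models and weather models fit with the documented reference levels", {
  set.seed(96)
  rec <- simulate_day_records(n_animals = 10, n_days = 40)
  rec$mean_daily_odba <- rec$mean_daily_odba + ifelse(rec$sex == "male", 0.03, 0)
  fit <- fit_activity_lmm(rec, model_spec("mean_daily_odba", fixed = "sex"))
  td <- tidy(fit)
  expect_true("sexmale" %in% td$term)   # female is the reference level

  rec$temp_c <- rnorm(nrow(rec), 5, 8)
  rec$wind_ms <- abs(rnorm(nrow(rec), 3, 1))
  rec$temp_x_wind <- wind_chill_interaction(rec$temp_c, rec$wind_ms)
  rec$snow_cat <- factor(ifelse(rec$stage == "winter" &
                                  as.integer(format(rec$date, "%d")) %% 3 == 0,
                                "ge8cm", "lt8cm"), levels = c("lt8cm", "ge8cm"))
  wrec <- rec[rec$stage == "winter", ]
  fitw <- fit_activity_lmm(wrec, model_spec(
    "mean_daily_odba", fixed = c("sex", "temp_c", "wind_ms", "snow_cat", "temp_x_wind")))
  tdw <- tidy(fitw)
  expect_true("snow_catge8cm" %in% tdw$term)  # lt8cm is the reference level
  expect_true(all(tdw$conf_low < tdw$estimate & tdw$estimate < tdw$conf_high))
})
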