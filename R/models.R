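# Linear mixed-effects stage/sex/weather models.
#
# Responses: mean daily ODBA (g), onset relative to civil dusk (min),
# offset relative to civil dawn (min), bout duration (h). Random intercepts
# for individual animal and day of year (crossed). Seasonal stage and
# weather covariates are strongly collinear by design of the deployments,
# so a model may contain stage OR weather terms, never both; the guard is
# enforced in code. Reference levels: winter stage, female sex, snow < 8 cm.
# Degrees of freedom use the Satterthwaite approximation (lmerTest).

STAGE_LEVELS <- c("winter", "mating", "lactation", "fattening")
SEX_LEVELS <- c("female", "male")
WEATHER_TERMS <- c("temp_c", "wind_ms", "precip_sqrt", "snow_cat", "temp_x_wind")

#' Specify an activity mixed model
#'
#' @param response One of `"mean_daily_odba"`, `"onset_rel_dusk_min"`,
#'   `"offset_rel_dawn_min"`, `"duration_h"`.
#' @param fixed Character vector of fixed effects from `stage`, `sex`,
#'   `temp_c`, `wind_ms`, `precip_sqrt`, `snow_cat`, `temp_x_wind`.
#'   `stage` and any weather term cannot co-occur (they are confounded by
#'   the seasonal deployment design); violating this is an error.
#' @param random Random intercepts: subset of `"individual"`,
#'   `"day_of_year"` (crossed).
#' @return A `model_spec` list.
#' @export
model_spec <- function(response = c("mean_daily_odba", "onset_rel_dusk_min",
                                    "offset_rel_dawn_min", "duration_h"),
                       fixed,
                       random = c("individual", "day_of_year")) {
  response <- match.arg(response)
  allowed <- c("stage", "sex", WEATHER_TERMS)
  bad <- setdiff(fixed, allowed)
  if (length(bad)) abort(sprintf("unknown fixed effect(s): %s", paste(bad, collapse = ", ")))
  if ("stage" %in% fixed && any(WEATHER_TERMS %in% fixed)) {
    abort(paste("seasonal stage and weather covariates are confounded and",
                "cannot co-occur in one mixed model; fit separate stage and",
                "weather models"))
  }
  random <- match.arg(random, c("individual", "day_of_year"), several.ok = TRUE)
  structure(list(response = response, fixed = fixed, random = random),
            class = "model_spec")
}

spec_formula <- function(spec) {
  rand <- c(individual = "(1 | animal_id)", day_of_year = "(1 | day_of_year)")
  rhs <- c(spec$fixed, rand[spec$random])
  as.formula(paste(spec$response, "~", paste(rhs, collapse = " + ")))
}

#' Fit an activity linear mixed model (REML)
#'
#' Fits the model described by a [model_spec()] with `lmerTest` (REML,
#' Satterthwaite degrees of freedom). Factor reference levels are winter
#' stage, female sex and `lt8cm` snow. Complete cases on the model variables
#' are used. A singular fit (a variance component estimated at zero) is
#' reported via the `singular` flag, never silently dropped.
#'
#' @param records A day-level tibble with `animal_id`, `date`, the response,
#'   and the fixed-effect columns (`stage`, `sex`, weather covariates as
#'   applicable).
#' @param spec A [model_spec()].
#' @return An `activity_lmm` object (use [tidy()], [glance()],
#'   [lsmeans_tukey()], [residual_diagnostics()]).
#' @export
fit_activity_lmm <- function(records, spec) {
  stopifnot(inherits(spec, "model_spec"))
  df <- tibble::as_tibble(records)
  need <- c("animal_id", "date", spec$response, spec$fixed)
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(sprintf("records are missing column(s): %s",
                                  paste(miss, collapse = ", ")))
  df$animal_id <- factor(df$animal_id)
  df$day_of_year <- factor(as.integer(format(as.Date(df$date), "%j")))
  if ("stage" %in% names(df)) {
    df$stage <- factor(df$stage, levels = intersect(STAGE_LEVELS, unique(as.character(df$stage))))
  }
  if ("sex" %in% names(df)) df$sex <- factor(df$sex, levels = SEX_LEVELS)
  if ("snow_cat" %in% names(df)) {
    df$snow_cat <- factor(as.character(df$snow_cat), levels = c("lt8cm", "ge8cm"))
  }
  df <- df[complete.cases(df[, need]), ]
  if (nlevels(droplevels(df$animal_id)) < 2) {
    abort("need at least 2 individuals to fit random intercepts")
  }
  fit <- lmerTest::lmer(spec_formula(spec), data = df, REML = TRUE)
  structure(list(fit = fit, spec = spec, data = df,
                 singular = lme4::isSingular(fit)),
            class = "activity_lmm")
}

#' @export
print.activity_lmm <- function(x, ...) {
  cat(sprintf("<activity_lmm> %s ~ %s (+ random: %s)%s\n",
              x$spec$response, paste(x$spec$fixed, collapse = " + "),
              paste(x$spec$random, collapse = ", "),
              if (x$singular) " [singular fit]" else ""))
  print(tidy(x))
  invisible(x)
}

#' Tidy fixed-effect estimates
#'
#' One row per fixed-effect term: estimate, standard error, Satterthwaite
#' df, t, p, and 95% Wald confidence bounds.
#'
#' @param x An `activity_lmm`.
#' @param conf_level Confidence level (default 0.95).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy activity_lmm
#' @export
tidy.activity_lmm <- function(x, conf_level = 0.95, ...) {
  sm <- as.data.frame(summary(x$fit)$coefficients)
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[["Estimate"]],
    std_error = sm[["Std. Error"]],
    df = sm[["df"]],
    statistic = sm[["t value"]],
    p_value = sm[["Pr(>|t|)"]],
    conf_low = sm[["Estimate"]] - z * sm[["Std. Error"]],
    conf_high = sm[["Estimate"]] + z * sm[["Std. Error"]]
  )
}

#' Model-level summary: variance components and fit info
#'
#' `sigma2` is the residual variance; `tau00_*` the random-intercept
#' variances (0 with `singular = TRUE` when a component collapses).
#'
#' @param x An `activity_lmm`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance activity_lmm
#' @export
glance.activity_lmm <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  tau <- vc[vc$grp != "Residual", , drop = FALSE]
  out <- tibble::tibble(
    nobs = stats::nobs(x$fit),
    n_individuals = nlevels(droplevels(x$data$animal_id)),
    sigma2 = vc$vcov[vc$grp == "Residual"],
    singular = x$singular,
    reml_criterion = as.numeric(lme4::REMLcrit(x$fit))
  )
  for (i in seq_len(nrow(tau))) {
    out[[paste0("tau00_", tau$grp[i])]] <- tau$vcov[i]
  }
  out
}

#' Least-squares means with Tukey-adjusted pairwise contrasts
#'
#' Model-adjusted group means for a factor in the fixed effects, with all
#' pairwise differences and family-wise Tukey-adjusted p-values;
#' significance at alpha = 0.05.
#'
#' @param fit An `activity_lmm`.
#' @param factor_name `"stage"` or `"sex"` (must be in the fixed effects).
#' @param alpha Significance level (default 0.05, significant when p <= alpha).
#' @return A list with tibbles `lsmeans` (level, lsmean, se, df, CI) and
#'   `contrasts` (pair, estimate, se, df, t, adjusted p, significant).
#' @export
lsmeans_tukey <- function(fit, factor_name, alpha = 0.05) {
  if (!factor_name %in% fit$spec$fixed) {
    abort(sprintf("'%s' is not a fixed effect of this model", factor_name))
  }
  emm <- emmeans::emmeans(fit$fit, specs = factor_name,
                          lmer.df = "satterthwaite")
  prs <- emmeans::contrast(emm, method = "pairwise", adjust = "tukey")
  emm_df <- as.data.frame(emm)
  prs_df <- as.data.frame(prs)
  list(
    lsmeans = tibble::tibble(
      level = as.character(emm_df[[factor_name]]),
      lsmean = emm_df$emmean, se = emm_df$SE, df = emm_df$df,
      conf_low = emm_df$lower.CL, conf_high = emm_df$upper.CL),
    contrasts = tibble::tibble(
      contrast = as.character(prs_df$contrast),
      estimate = prs_df$estimate, se = prs_df$SE, df = prs_df$df,
      statistic = prs_df$t.ratio, p_value = prs_df$p.value,
      significant = prs_df$p.value <= alpha)
  )
}

#' Residual normality diagnostics
#'
#' Ordered residuals against normal quantiles plus a probability-plot
#' correlation ("straightness") statistic; an advisory flag is raised when
#' the correlation falls below `flag_below` (default 0.99). Normal residuals
#' typically score above 0.99; heavy tails pull the statistic down.
#'
#' @param fit An `activity_lmm`.
#' @param flag_below Advisory flag threshold (default 0.99).
#' @return A list: `qq` tibble (`theoretical`, `sample`), `straightness`,
#'   `flag` (TRUE/FALSE/NA), `n`.
#' @export
residual_diagnostics <- function(fit, flag_below = 0.99) {
  r <- resid(fit$fit)
  n <- length(r)
  if (n < 3) {
    return(list(qq = tibble::tibble(theoretical = numeric(), sample = numeric()),
                straightness = NA_real_, flag = NA, n = n))
  }
  qq <- tibble::tibble(theoretical = qnorm(ppoints(n)), sample = sort(r))
  straight <- stats::cor(qq$theoretical, qq$sample)
  list(qq = qq, straightness = straight, flag = straight < flag_below, n = n)
}

#' Quantile-quantile plot of model residuals
#' @param object An `activity_lmm`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot activity_lmm
#' @export
autoplot.activity_lmm <- function(object, ...) {
  d <- residual_diagnostics(object)
  ggplot2::ggplot(d$qq, ggplot2::aes(x = .data$theoretical, y = .data$sample)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_qq_line(ggplot2::aes(sample = .data$sample),
                          inherit.aes = FALSE, linetype = 2) +
    ggplot2::labs(x = "normal quantiles", y = "residuals",
                  subtitle = sprintf("probability-plot correlation %.4f",
                                     d$straightness)) +
    ggplot2::theme_minimal()
}
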