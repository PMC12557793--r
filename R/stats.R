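#' @importFrom lme4 isSingular
NULL

## Shared backend: random-intercept model with Satterthwaite df, Wald-t CIs,
## optional likelihood-ratio test for one factor (models refit by ML).
fit_lmm <- function(formula, data, model_name, lrt_term = NULL,
                    group = "dog_id") {
  if (length(unique(data[[group]])) < 2L)
    stop("mixed model needs at least 2 dogs (grouping levels)")
  resp <- all.vars(formula)[1]
  if (stats::var(data[[resp]]) == 0) {
    ## every observation identical: the mixed model is degenerate, but the
    ## answer is exact -- all contrasts are zero with zero uncertainty
    warning(sprintf("%s: response is constant; returning exact zero contrasts",
                    model_name), call. = FALSE)
    ols <- lm(stats::update(formula, paste(resp, "~ . - (1 |", group, ")")),
              data = data)
    est <- coef(ols)
    fe <- data.frame(term = names(est), estimate = unname(est),
                     ci_low = unname(est), ci_high = unname(est),
                     t_value = NA_real_, df = NA_real_, p_value = NA_real_,
                     stringsAsFactors = FALSE)
    return(structure(list(model_name = model_name, fixed_effects = fe,
                          random_intercept_sd = 0, residual_sd = 0,
                          lrt = NULL, singular = TRUE, n_obs = nrow(data),
                          n_groups = length(unique(data[[group]])),
                          fit = ols),
                     class = "hydro_fit"))
  }
  ## Satterthwaite machinery can fail on fully degenerate (zero-variance)
  ## data; fall back to lme4 with residual df in that case.
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(formula, data = data, REML = TRUE)),
    error = function(e) suppressMessages(
      lme4::lmer(formula, data = data, REML = TRUE)))
  singular <- lme4::isSingular(fit)
  if (singular)
    warning(sprintf("%s: singular random-effect fit (between-dog variance ~0)",
                    model_name), call. = FALSE)
  co <- summary(fit)$coefficients  # Estimate, SE, df, t, p (Satterthwaite)
  if (!"df" %in% colnames(co)) {
    df_res <- nrow(data) - nrow(co)
    co <- cbind(co, df = df_res,
                `Pr(>|t|)` = 2 * stats::pt(abs(co[, "t value"]), df_res,
                                           lower.tail = FALSE))
  }
  tcrit <- qt(0.975, co[, "df"])
  fe <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                   ci_low = co[, "Estimate"] - tcrit * co[, "Std. Error"],
                   ci_high = co[, "Estimate"] + tcrit * co[, "Std. Error"],
                   t_value = co[, "t value"], df = co[, "df"],
                   p_value = co[, "Pr(>|t|)"], row.names = NULL,
                   stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  ri_sd <- vc$sdcor[vc$grp == group & vc$var1 == "(Intercept)"][1]

  lrt <- NULL
  if (!is.null(lrt_term)) {
    full_ml <- lme4::lmer(formula, data = data, REML = FALSE)
    red_form <- stats::update(formula, as.formula(paste(". ~ . -", lrt_term)))
    red_ml <- lme4::lmer(red_form, data = data, REML = FALSE)
    a <- anova(red_ml, full_ml)
    lrt <- list(chi_square = a$Chisq[2], df = a$Df[2],
                p_value = a$`Pr(>Chisq)`[2])
  }
  structure(list(model_name = model_name, fixed_effects = fe,
                 random_intercept_sd = ri_sd,
                 residual_sd = vc$sdcor[vc$grp == "Residual"][1],
                 lrt = lrt, singular = singular,
                 n_obs = nrow(data),
                 n_groups = length(unique(data[[group]])),
                 fit = fit),
            class = "hydro_fit")
}

#' @export
print.hydro_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Random-intercept model '%s' (%d obs, %d dogs%s)\n",
              x$model_name, x$n_obs, x$n_groups,
              if (isTRUE(x$singular)) "; SINGULAR fit" else ""))
  fe <- x$fixed_effects
  cat(sprintf("  %-38s %8s [%8s, %8s] %8s\n", "term", "est", "lo", "hi", "p"))
  for (i in seq_len(nrow(fe)))
    cat(sprintf("  %-38s %8.*f [%8.*f, %8.*f] %8.3g\n", fe$term[i],
                digits, fe$estimate[i], digits, fe$ci_low[i],
                digits, fe$ci_high[i], fe$p_value[i]))
  cat(sprintf("  random intercept SD %.3g, residual SD %.3g\n",
              x$random_intercept_sd, x$residual_sd))
  if (!is.null(x$lrt))
    cat(sprintf("  LRT: chi^2 = %.3g, df = %d, p = %.3g\n",
                x$lrt$chi_square, x$lrt$df, x$lrt$p_value))
  invisible(x)
}

#' @export
summary.hydro_fit <- function(object, ...) {
  print(object, ...)
  invisible(object)
}

#' @export
coef.hydro_fit <- function(object, ...) {
  setNames(object$fixed_effects$estimate, object$fixed_effects$term)
}

#' Scent-preference model for the four-bowl screen
#'
#' Fits `ml_per_kg ~ sleeve + (1 | dog_id)` on daily per-bowl summaries,
#' with the non-scented sleeve as the reference level, and tests the
#' four-level scent factor with a likelihood-ratio chi-square (df = 3;
#' models refit by maximum likelihood). The treatment-coded fixed effects
#' are the post-hoc contrasts of each scent against the non-scented sleeve
#' (no multiplicity correction by default).
#'
#' @param daily A [daily_consumption()] table (needs `dog_id`, `sleeve`,
#'   `ml_per_kg`) with 4 sleeve levels.
#' @param reference Reference sleeve level.
#' @return A `hydro_fit` with an `lrt` component.
#' @export
fit_exp1_scent <- function(daily, reference = "none") {
  stopifnot(reference %in% daily$sleeve)
  daily$sleeve <- stats::relevel(factor(daily$sleeve), ref = reference)
  fit_lmm(ml_per_kg ~ sleeve + (1 | dog_id), daily,
          model_name = "exp1_scent", lrt_term = "sleeve")
}

#' Sleeve-type and diet model for the two-bowl follow-up
#'
#' Fits `ml_per_kg ~ sleeve + diet + (1 | dog_id)` on daily per-bowl
#' summaries: preferred-scented vs non-scented sleeve and dry vs non-dry
#' diet, random intercept per dog, Satterthwaite-t 95% CIs. The diet term
#' is dropped with a warning if diet does not vary across dogs.
#'
#' @param daily Daily summary table with `dog_id`, `sleeve` (levels
#'   `preferred`/`none`), `ml_per_kg` and optionally `diet`.
#' @param diet_coding `"dry_vs_nondry"` codes dry against wet/combination
#'   pooled; `"levels"` keeps the diet factor as-is.
#' @return A `hydro_fit`.
#' @export
fit_exp2_sleeve_diet <- function(daily, diet_coding = c("dry_vs_nondry", "levels")) {
  diet_coding <- match.arg(diet_coding)
  daily$sleeve <- stats::relevel(factor(daily$sleeve), ref = "none")
  has_diet <- !is.null(daily$diet) && length(unique(daily$diet)) > 1L
  if (has_diet && diet_coding == "dry_vs_nondry")
    daily$diet <- factor(ifelse(daily$diet == "dry", "dry", "nondry"),
                         levels = c("dry", "nondry"))
  if (!has_diet && !is.null(daily$diet))
    warning("diet constant across dogs; diet term dropped", call. = FALSE)
  form <- if (has_diet) ml_per_kg ~ sleeve + diet + (1 | dog_id)
          else ml_per_kg ~ sleeve + (1 | dog_id)
  fit_lmm(form, daily, model_name = "exp2_sleeve_diet")
}

#' Time-of-day and activity model on bin-level summaries
#'
#' Fits `ml_per_kg ~ time_of_day + activity + (1 | dog_id)` on one
#' observation per dog, day and six-hour bin, with afternoon and the
#' `<30 min` activity class as reference levels. Bin or activity levels
#' absent from the data are dropped with a warning; the activity term is
#' omitted entirely if constant.
#'
#' @param bin_daily Data.frame with `dog_id`, `time_of_day`, `ml_per_kg`
#'   and optionally `activity`.
#' @return A `hydro_fit`.
#' @export
fit_exp2_time_activity <- function(bin_daily) {
  lv <- c("afternoon", "morning", "evening", "night")
  present <- lv[lv %in% unique(bin_daily$time_of_day)]
  if (length(present) < length(lv))
    warning("time-of-day level(s) missing from data: ",
            paste(setdiff(lv, present), collapse = ", "), call. = FALSE)
  bin_daily$time_of_day <- factor(bin_daily$time_of_day, levels = present)
  has_act <- !is.null(bin_daily$activity) &&
    length(unique(bin_daily$activity)) > 1L
  if (has_act) {
    af <- factor(bin_daily$activity)
    ref <- if ("lt30min" %in% levels(af)) "lt30min" else levels(af)[1]
    bin_daily$activity <- stats::relevel(af, ref = ref)
  }
  form <- if (has_act) ml_per_kg ~ time_of_day + activity + (1 | dog_id)
          else ml_per_kg ~ time_of_day + (1 | dog_id)
  fit_lmm(form, bin_daily, model_name = "exp2_time_activity")
}

#' Univariate age model
#'
#' Fits `ml_per_kg ~ age_years + (1 | dog_id)`; age is evaluated on its
#' own because it is collinear with diet and activity in the cohort.
#'
#' @param daily Data.frame with `dog_id`, `age_years`, `ml_per_kg`.
#' @return A `hydro_fit`.
#' @export
fit_univariate_age <- function(daily) {
  if (length(unique(daily$dog_id)) < 2L)
    stop("mixed model needs at least 2 dogs (grouping levels)")
  if (length(unique(daily$age_years)) < 2L)
    stop("age is constant across dogs; univariate age model is unidentifiable")
  fit_lmm(ml_per_kg ~ age_years + (1 | dog_id), daily,
          model_name = "univariate_age")
}

#' Event-level models: events/day and quantity/event by sleeve type
#'
#' Two random-intercept models on per dog-day-bowl statistics: the number
#' of consumption events per day, and the water quantity consumed per
#' event (mL/kg/event), each predicted by sleeve type. Rows with an
#' undefined quantity/event (zero-event days) are excluded listwise from
#' the second model.
#'
#' @param daily A [daily_consumption()] table with `n_events`, `ml_per_kg`,
#'   `sleeve`, `dog_id`.
#' @return List with components `events_per_day` and `ml_per_kg_per_event`,
#'   both `hydro_fit` objects.
#' @export
fit_event_models <- function(daily) {
  daily$sleeve <- stats::relevel(factor(daily$sleeve), ref = "none")
  d1 <- daily
  d1$ml_per_kg <- d1$n_events
  m1 <- fit_lmm(ml_per_kg ~ sleeve + (1 | dog_id), d1,
                model_name = "events_per_day")
  d2 <- daily[daily$n_events > 0, , drop = FALSE]
  d2$ml_per_kg <- d2$ml_per_kg / d2$n_events
  m2 <- fit_lmm(ml_per_kg ~ sleeve + (1 | dog_id), d2,
                model_name = "ml_per_kg_per_event")
  list(events_per_day = m1, ml_per_kg_per_event = m2)
}

#' Nonparametric bootstrap percentile CI of the mean
#'
#' Resamples the data with replacement and reports the 2.5 and 97.5
#' percentiles of the resampled means, reproducibly under a seed.
#'
#' @param values Numeric vector (n >= 1).
#' @param n_resamples Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return Object of class `bootstrap_ci`: `statistic` (the sample mean),
#'   `ci_low`, `ci_high`, `n_resamples`, `seed`.
#' @export
#' @examples
#' bootstrap_mean_ci(c(10, 12, 9, 14, 11), n_resamples = 2000, seed = 7)
bootstrap_mean_ci <- function(values, n_resamples = 10000L, seed = 1L) {
  if (!length(values)) stop("empty input to bootstrap")
  set.seed(as.integer(seed))
  n <- length(values)
  means <- colMeans(matrix(sample(values, n * n_resamples, replace = TRUE),
                           nrow = n))
  ci <- unname(quantile(means, c(0.025, 0.975)))
  structure(list(statistic = mean(values), ci_low = ci[1], ci_high = ci[2],
                 n_resamples = as.integer(n_resamples),
                 seed = as.integer(seed)),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("mean %.3f, bootstrap 95%% CI [%.3f, %.3f] (%d resamples)\n",
              x$statistic, x$ci_low, x$ci_high, x$n_resamples))
  invisible(x)
}
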