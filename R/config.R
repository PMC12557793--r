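#' Study design for a bowl-scale experiment
#'
#' Encodes the fixed layout of the two experiments: a four-bowl scent screen
#' recorded at 5 s for 4 days (`"exp1"`), and a two-bowl preferred-scent vs
#' non-scented follow-up recorded at 30 s for 14 days (`"exp2"`).
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param duration_days Number of 24 h recording days. Defaults to 4 (exp1)
#'   or 14 (exp2); may be shortened, e.g. for quick checks.
#' @return An object of class `study_design`: a list with `experiment`,
#'   `n_bowls`, `duration_days`, `sampling_interval_s` and `sleeves` (bowl
#'   sleeve labels; for exp2 the label `"preferred"` is resolved per dog to
#'   that dog's preferred scent at simulation time).
#' @export
#' @examples
#' study_design("exp2")
study_design <- function(experiment = c("exp1", "exp2"), duration_days = NULL) {
  experiment <- match.arg(experiment)
  if (experiment == "exp1") {
    d <- list(experiment = "exp1", n_bowls = 4L,
              duration_days = if (is.null(duration_days)) 4L else as.integer(duration_days),
              sampling_interval_s = 5L,
              sleeves = c("chicken", "beef", "peanut_butter", "none"))
  } else {
    d <- list(experiment = "exp2", n_bowls = 2L,
              duration_days = if (is.null(duration_days)) 14L else as.integer(duration_days),
              sampling_interval_s = 30L,
              sleeves = c("preferred", "none"))
  }
  stopifnot(d$duration_days >= 1L)
  structure(d, class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study design '%s': %d bowls (%s), %d day(s), %d s sampling\n",
              x$experiment, x$n_bowls, paste(x$sleeves, collapse = ", "),
              x$duration_days, x$sampling_interval_s))
  invisible(x)
}

#' Simulator configuration
#'
#' Parameters of the synthetic trace generator. Defaults reproduce the
#' magnitudes reported for the household study that motivates the package:
#' roughly 8 drinking events per bowl per day with a mean bout around 41 g
#' (the validation set's 95 events and 3,941 g over 288 h), an
#' evening-peaked diurnal profile, a preferred-sleeve increment of
#' 5.26 mL/kg, a dry-diet increment of 10.75 mL/kg, and 1 g weight
#' quantization.
#'
#' @param seed Integer seed used when a simulation call does not supply its
#'   own.
#' @param base_ml_per_kg Expected daily intake per bowl (mL/kg) before any
#'   sleeve, diet or dog effect.
#' @param scent_effects_ml_per_kg Named additive sleeve effects (mL/kg)
#'   applied by sleeve label, e.g. `c(chicken = 2.89)`. Unnamed sleeves get 0.
#' @param preference_effect_ml_per_kg Additive effect (mL/kg) on the bowl
#'   whose sleeve matches the dog's preferred scent.
#' @param diet_effect_ml_per_kg Additive effect (mL/kg) for dry-fed dogs.
#' @param dog_sd_ml_per_kg Between-dog random-intercept SD (mL/kg).
#' @param day_sd_ml_per_kg Day-to-day residual SD of the per-bowl daily
#'   total (mL/kg).
#' @param events_per_day_rate Poisson mean of drinking events per bowl-day.
#' @param event_mass_shape Gamma shape of event masses (right-skewed bouts).
#' @param event_duration_range_s Range (s) of event durations, uniform.
#' @param min_event_gap_s Minimum spacing (s) between scheduled events on
#'   one bowl: separate drinking bouts are at least five minutes apart, a
#'   brief return to the bowl within that window being part of the same
#'   bout.
#' @param diurnal_weights Probabilities of an event falling in the morning,
#'   afternoon, evening and night bins; must sum to 1. Defaults follow the
#'   observed evening-peaked profile (8.06/9.02/17.8/3.17 mL/kg bin means).
#' @param nudge_rate_per_day Poisson mean of transient scale nudges per day.
#' @param nudge_magnitude_range_g Magnitude range (g) of a press-type nudge.
#' @param nudge_negative_prob Probability a nudge is instead a small
#'   negative wobble (3-4.9 g), below the stability tolerance so that only
#'   the transient rule can exclude it.
#' @param refill_policy List: `mode` one of `"daily+demand"` (owner refill
#'   at a fixed hour plus whenever content falls below `demand_frac` of
#'   full), `"none"` (never refill) or `"error"` (stop if the bowl would
#'   run dry); `hour` local refill hour; `demand_frac` low-content fraction.
#' @param full_weight_g Weight (g) of a freshly filled bowl.
#' @param quantization_g Recording resolution of the scale (g); 0 disables
#'   quantization.
#' @param evaporation_g_per_day Optional linear drift (g/day), default 0.
#' @param midnight_offset_s Offset (s) added to epoch timestamps before
#'   computing local days and time-of-day bins.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       base_ml_per_kg = 6.08,
                       scent_effects_ml_per_kg = c(chicken = 0, beef = 0,
                                                   peanut_butter = 0, none = 0),
                       preference_effect_ml_per_kg = 5.26,
                       diet_effect_ml_per_kg = 10.75,
                       dog_sd_ml_per_kg = 7,
                       day_sd_ml_per_kg = 6,
                       events_per_day_rate = 8,
                       event_mass_shape = 4,
                       event_duration_range_s = c(15, 45),
                       min_event_gap_s = 300,
                       diurnal_weights = c(morning = 8.06, afternoon = 9.02,
                                           evening = 17.8, night = 3.17) / 38.05,
                       nudge_rate_per_day = 5,
                       nudge_magnitude_range_g = c(20, 200),
                       nudge_negative_prob = 0.2,
                       refill_policy = list(mode = "daily+demand", hour = 8,
                                            demand_frac = 0.10),
                       full_weight_g = 1500,
                       quantization_g = 1,
                       evaporation_g_per_day = 0,
                       midnight_offset_s = 0) {
  cfg <- list(seed = as.integer(seed), base_ml_per_kg = base_ml_per_kg,
              scent_effects_ml_per_kg = scent_effects_ml_per_kg,
              preference_effect_ml_per_kg = preference_effect_ml_per_kg,
              diet_effect_ml_per_kg = diet_effect_ml_per_kg,
              dog_sd_ml_per_kg = dog_sd_ml_per_kg,
              day_sd_ml_per_kg = day_sd_ml_per_kg,
              events_per_day_rate = events_per_day_rate,
              event_mass_shape = event_mass_shape,
              event_duration_range_s = event_duration_range_s,
              min_event_gap_s = min_event_gap_s,
              diurnal_weights = diurnal_weights,
              nudge_rate_per_day = nudge_rate_per_day,
              nudge_magnitude_range_g = nudge_magnitude_range_g,
              nudge_negative_prob = nudge_negative_prob,
              refill_policy = refill_policy,
              full_weight_g = full_weight_g,
              quantization_g = quantization_g,
              evaporation_g_per_day = evaporation_g_per_day,
              midnight_offset_s = midnight_offset_s)
  stopifnot(length(cfg$diurnal_weights) == 4L,
            all(cfg$diurnal_weights >= 0),
            abs(sum(cfg$diurnal_weights) - 1) < 1e-9,
            cfg$base_ml_per_kg >= 0, cfg$events_per_day_rate >= 0,
            cfg$nudge_rate_per_day >= 0, cfg$full_weight_g > 0,
            cfg$quantization_g >= 0,
            cfg$refill_policy$mode %in% c("daily+demand", "none", "error"))
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulator configuration\n")
  cat(sprintf("  base intake        : %.2f mL/kg/day per bowl\n", x$base_ml_per_kg))
  cat(sprintf("  preference effect  : %+.2f mL/kg (preferred sleeve)\n",
              x$preference_effect_ml_per_kg))
  cat(sprintf("  diet effect        : %+.2f mL/kg (dry-fed)\n", x$diet_effect_ml_per_kg))
  cat(sprintf("  events/day         : %.1f (gamma bouts, shape %.1f)\n",
              x$events_per_day_rate, x$event_mass_shape))
  cat(sprintf("  nudges/day         : %.1f; refill: %s; quantization: %g g\n",
              x$nudge_rate_per_day, x$refill_policy$mode, x$quantization_g))
  invisible(x)
}

#' Detector configuration
#'
#' Thresholds of the consumption-event detection algorithm. The defaults are
#' the values used on the real recordings: a 5-point centred moving average,
#' a 5 g stability tolerance, a 2 g serial-loss threshold (strict
#' inequalities throughout) and a 10 s transient-fluctuation window. The
#' same gram and second thresholds are reused unchanged in the 30 s
#' sampling mode.
#'
#' @param ma_window Odd moving-average window length (samples).
#' @param stability_tolerance_g Maximum absolute deviation (g) from the
#'   moving average for a raw sample to count as stable.
#' @param min_loss_g Serial weight loss (g) that must be exceeded for a
#'   step to seed a consumption event.
#' @param transient_window_s Window (s) within which an excursion must
#'   return to its prior stable weight to be classed a transient.
#' @param merge_gap_samples Maximum number of intervening stable samples
#'   between loss steps merged into a single event.
#' @param refill_threshold_g Sustained gain (g) between successive stable
#'   samples treated as a refill, segmenting the trace.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(ma_window = 5L,
                            stability_tolerance_g = 5,
                            min_loss_g = 2,
                            transient_window_s = 10,
                            merge_gap_samples = 2L,
                            refill_threshold_g = 50) {
  cfg <- list(ma_window = as.integer(ma_window),
              stability_tolerance_g = stability_tolerance_g,
              min_loss_g = min_loss_g,
              transient_window_s = transient_window_s,
              merge_gap_samples = as.integer(merge_gap_samples),
              refill_threshold_g = refill_threshold_g)
  stopifnot(cfg$ma_window >= 1L, cfg$ma_window %% 2L == 1L,
            cfg$stability_tolerance_g > 0, cfg$min_loss_g > 0,
            cfg$transient_window_s > 0, cfg$merge_gap_samples >= 0L,
            cfg$refill_threshold_g > 0)
  structure(cfg, class = "detector_config")
}

#' @export
print.detector_config <- function(x, ...) {
  cat(sprintf(paste0("Detector: %d-point moving average, stability +/-%g g, ",
                     "loss > %g g, transient window %g s, merge gap %d, ",
                     "refill >= %g g\n"),
              x$ma_window, x$stability_tolerance_g, x$min_loss_g,
              x$transient_window_s, x$merge_gap_samples, x$refill_threshold_g))
  invisible(x)
}

#' Generate a cohort of dog profiles
#'
#' Draws dog metadata resembling the study population: adult dogs (1-14
#' years), body masses spanning small to large breeds, dry or combination
#' diets, three activity classes, and scent preferences dominated by chicken
#' and beef.
#'
#' @param n Number of dogs.
#' @param seed Integer seed.
#' @param scent_probs Named probabilities of each preferred scent.
#' @return A data.frame with columns `dog_id`, `body_mass_kg`, `diet`,
#'   `activity`, `age_years`, `preferred_scent`.
#' @export
dog_profiles <- function(n, seed = 1L,
                         scent_probs = c(chicken = 0.45, beef = 0.35,
                                         peanut_butter = 0.10, none = 0.10)) {
  stopifnot(n >= 1, abs(sum(scent_probs) - 1) < 1e-9)
  set.seed(as.integer(seed))
  data.frame(
    dog_id = sprintf("dog%02d", seq_len(n)),
    body_mass_kg = round(exp(rnorm(n, log(15), 0.55)), 1),
    diet = sample(c("dry", "combination"), n, replace = TRUE),
    activity = sample(c("lt30min", "30to60min", "gt1h"), n, replace = TRUE),
    age_years = round(runif(n, 1, 14), 1),
    preferred_scent = sample(names(scent_probs), n, replace = TRUE,
                             prob = scent_probs),
    stringsAsFactors = FALSE
  )
}

#' Hours of observation implied by a cohort layout
#'
#' Dog-hours of continuous 24 h recording: `n_dogs * duration_days * 24`.
#' The four-bowl screen with 20 dogs over 4 days yields 1,920 h.
#'
#' @param design A [study_design()].
#' @param n_dogs Number of dogs recorded.
#' @return Hours of observation (numeric).
#' @export
observation_hours <- function(design, n_dogs) {
  stopifnot(inherits(design, "study_design"), n_dogs >= 1)
  n_dogs * design$duration_days * 24
}

## seed arithmetic kept below .Machine$integer.max
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}
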