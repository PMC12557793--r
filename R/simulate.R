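#' Simulate one bowl-weight trace with ground truth
#'
#' Generates a timestamped, quantized weight trace for a single bowl on a
#' load-cell scale, together with the ground-truth drinking events and
#' nuisance events (owner refills, transient nudges) that produced it.
#' Drinking events appear as stepwise losses spread linearly over the bout
#' duration; refills restore the bowl to full; nudges are brief excursions
#' that return exactly to the prior stable weight. All recorded weights are
#' quantized to the scale resolution.
#'
#' Ground-truth event masses are reported two ways: `mass_sched_g`, the
#' continuous scheduled bout mass, and `mass_g`, the mass as realized on the
#' quantized recording (stable recorded weight before the bout minus stable
#' recorded weight after). Detector validation uses `mass_g`, since a manual
#' reader of the raw files can only ever see the quantized weights.
#'
#' @param design A [study_design()].
#' @param dog One-row data.frame as from [dog_profiles()].
#' @param bowl_id Identifier of the bowl/scale.
#' @param sleeve Sleeve label on this bowl; `"preferred"` resolves to the
#'   dog's preferred scent.
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @param dog_offset_ml_per_kg Per-dog random-intercept value (mL/kg),
#'   supplied by [simulate_cohort()] so all of a dog's bowls share it.
#' @return A list with `trace` (data.frame `timestamp`, `weight_g`,
#'   `scale_id`, with attribute `sampling_interval_s`), `events` (ground
#'   truth drinking events) and `nuisance` (refills and nudges).
#' @export
#' @examples
#' d <- study_design("exp2", duration_days = 1)
#' dog <- dog_profiles(1, seed = 7)
#' sim <- simulate_trace(d, dog, "b1", sleeve = "none",
#'                       config = sim_config(nudge_rate_per_day = 0))
#' nrow(sim$trace)  # 86400 / 30 samples
simulate_trace <- function(design, dog, bowl_id, sleeve,
                           config = sim_config(), seed = config$seed,
                           dog_offset_ml_per_kg = 0) {
  stopifnot(inherits(design, "study_design"), inherits(config, "sim_config"),
            nrow(dog) == 1L, dog$body_mass_kg > 0)
  set.seed(as.integer(seed))
  interval <- design$sampling_interval_s
  total_s <- design$duration_days * 86400
  n <- total_s %/% interval
  stopifnot(n * interval == total_s)
  t <- (seq_len(n) - 1) * interval

  is_pref <- identical(sleeve, "preferred") ||
    (!identical(sleeve, "none") && identical(sleeve, dog$preferred_scent))
  scent_eff <- config$scent_effects_ml_per_kg
  eff <- if (sleeve %in% names(scent_eff)) scent_eff[[sleeve]] else 0
  target_base <- config$base_ml_per_kg + eff +
    if (is_pref) config$preference_effect_ml_per_kg else 0
  if (identical(dog$diet, "dry")) target_base <- target_base + config$diet_effect_ml_per_kg
  target_base <- target_base + dog_offset_ml_per_kg

  refill_mode <- config$refill_policy$mode
  refill_hour <- if (is.null(config$refill_policy$hour)) 8 else config$refill_policy$hour
  refill_ticks <- integer(0)
  if (refill_mode == "daily+demand") {
    rt <- (seq_len(design$duration_days) - 1) * 86400 + refill_hour * 3600
    refill_ticks <- findInterval(rt, t)
  }
  refill_guard_s <- 60  # events/nudges are kept clear of the refill tick

  ## ---- schedule drinking events day by day --------------------------------
  ev <- list()
  bins <- c("morning", "afternoon", "evening", "night")
  bin_start <- c(morning = 6, afternoon = 12, evening = 18, night = 0) * 3600
  for (d in seq_len(design$duration_days)) {
    day0 <- (d - 1) * 86400
    target <- max(0, target_base + rnorm(1, 0, config$day_sd_ml_per_kg))
    grams <- target * dog$body_mass_kg
    n_ev <- rpois(1, config$events_per_day_rate)
    if (n_ev == 0 || grams <= 0) next
    m <- rgamma(n_ev, shape = config$event_mass_shape)
    m <- m / sum(m) * grams
    b <- sample(bins, n_ev, replace = TRUE, prob = config$diurnal_weights)
    start <- day0 + bin_start[b] + runif(n_ev, 0, 6 * 3600 - 120)
    dur <- runif(n_ev, config$event_duration_range_s[1], config$event_duration_range_s[2])
    o <- order(start)
    start <- start[o]; dur <- dur[o]; m <- m[o]; b <- b[o]
    keep <- rep(TRUE, n_ev)
    last_end <- -Inf
    for (k in seq_len(n_ev)) {
      s <- max(start[k], last_end + config$min_event_gap_s)
      if (refill_mode == "daily+demand") {
        rtime <- day0 + refill_hour * 3600
        if (s < rtime + refill_guard_s && s + dur[k] > rtime - refill_guard_s)
          s <- rtime + refill_guard_s
      }
      if (s + dur[k] > day0 + 86400 - interval) { keep[k] <- FALSE; next }
      start[k] <- s
      last_end <- s + dur[k]
    }
    if (!any(keep)) next
    ev[[d]] <- data.frame(start_time = start[keep], duration_s = dur[keep],
                          mass_sched_g = m[keep], bin = unname(b[keep]),
                          stringsAsFactors = FALSE)
  }
  ev <- if (length(ev)) do.call(rbind, ev) else
    data.frame(start_time = numeric(0), duration_s = numeric(0),
               mass_sched_g = numeric(0), bin = character(0))

  ## ---- per-tick consumption decrements ------------------------------------
  dec <- numeric(n)
  if (nrow(ev)) {
    for (k in seq_len(nrow(ev))) {
      s <- ev$start_time[k]; e <- s + ev$duration_s[k]
      i0 <- findInterval(s, t)                 # last tick at or before start
      i1 <- min(n, findInterval(e - 1e-9, t) + 1L)  # first tick at/after end
      rng <- (i0 + 1L):i1
      frac <- pmin(1, pmax(0, (t[rng] - s) / ev$duration_s[k]))
      dec[rng] <- dec[rng] + ev$mass_sched_g[k] * diff(c(0, frac))
    }
  }
  if (config$evaporation_g_per_day > 0)
    dec <- dec + config$evaporation_g_per_day * interval / 86400

  ## ---- refill schedule -----------------------------------------------------
  ## Demand refills are decided at the bout level: the owner refills shortly
  ## before a bout that would leave the bowl below the low-content threshold,
  ## never in the middle of a bout (which would corrupt both the recording
  ## and the ground truth).
  full <- config$full_weight_g
  demand_frac <- if (is.null(config$refill_policy$demand_frac)) 0.1 else
    config$refill_policy$demand_frac
  demand_ticks <- integer(0)
  if (nrow(ev)) {
    items <- rbind(data.frame(time = ev$start_time, mass = ev$mass_sched_g),
                   if (length(refill_ticks))
                     data.frame(time = t[refill_ticks], mass = NA_real_))
    items <- items[order(items$time), , drop = FALSE]
    cont <- full
    for (k in seq_len(nrow(items))) {
      if (is.na(items$mass[k])) { cont <- full; next }
      if (refill_mode == "daily+demand" &&
          cont - items$mass[k] < demand_frac * full) {
        demand_ticks <- c(demand_ticks, findInterval(items$time[k] - 60, t))
        cont <- full
      }
      if (cont - items$mass[k] < 0) {
        if (refill_mode == "error")
          stop("bowl would run dry at t=", items$time[k],
               " under refill_policy 'error'")
        if (refill_mode == "daily+demand")
          stop("single bout larger than a full bowl; increase full_weight_g")
      }
      cont <- cont - items$mass[k]
    }
  }

  ## ---- content path ---------------------------------------------------------
  content <- numeric(n)
  refills <- list()
  all_refill <- sort(unique(c(refill_ticks, demand_ticks)))
  all_refill <- all_refill[all_refill > 1L]
  seg_starts <- unique(c(1L, all_refill))
  seg_ends <- c(seg_starts[-1] - 1L, n)
  for (si in seq_along(seg_starts)) {
    i <- seg_starts[si]
    seg <- i:seg_ends[si]
    if (i %in% all_refill) {
      prev <- content[i - 1L]
      if (full - prev > 0)
        refills[[length(refills) + 1L]] <-
          data.frame(time = t[i], magnitude_g = full - prev)
    }
    content[seg] <- full - cumsum(dec[seg])
  }

  ## ---- nudges in quiet periods --------------------------------------------
  n_nudge <- rpois(1, config$nudge_rate_per_day * design$duration_days)
  nudges <- NULL
  nudge_add <- numeric(n)
  if (n_nudge > 0) {
    busy_s <- ev$start_time; busy_e <- ev$start_time + ev$duration_s
    tries <- 0L
    rows <- list()
    while (length(rows) < n_nudge && tries < 50L * n_nudge) {
      tries <- tries + 1L
      t0 <- runif(1, interval, total_s - 3 * interval)
      dur <- runif(1, 2, config$transient_window_s %||% 10)
      clash <- any(t0 < busy_e + 15 & t0 + dur > busy_s - 15)
      near_refill <- length(all_refill) &&
        any(abs(t0 - t[all_refill]) < refill_guard_s)
      if (clash || near_refill) next
      mag <- if (runif(1) < config$nudge_negative_prob)
        -runif(1, 3, 4.9) else runif(1, config$nudge_magnitude_range_g[1],
                                     config$nudge_magnitude_range_g[2])
      idx <- which(t >= t0 & t < t0 + dur)
      if (!length(idx)) { dur_eff <- 0 } else {
        nudge_add[idx] <- nudge_add[idx] + mag
        dur_eff <- dur
      }
      rows[[length(rows) + 1L]] <- data.frame(kind = "nudge", time = t0,
                                              magnitude_g = mag,
                                              return_within_s = dur_eff)
    }
    nudges <- if (length(rows)) do.call(rbind, rows) else NULL
  }

  ## ---- quantize and assemble ----------------------------------------------
  q <- config$quantization_g
  quant <- function(x) if (q > 0) round(x / q) * q else x
  weight <- quant(content + nudge_add)
  qcontent <- quant(content)

  if (nrow(ev)) {
    i_before <- findInterval(ev$start_time, t)
    i_after <- pmin(n, findInterval(ev$start_time + ev$duration_s - 1e-9, t) + 1L)
    ev$mass_g <- qcontent[i_before] - qcontent[i_after]
    ev$end_time <- ev$start_time + ev$duration_s
    ev <- data.frame(dog_id = dog$dog_id, bowl_id = bowl_id,
                     start_time = ev$start_time, end_time = ev$end_time,
                     duration_s = ev$duration_s, mass_g = ev$mass_g,
                     mass_sched_g = ev$mass_sched_g, bin = ev$bin,
                     stringsAsFactors = FALSE)
  } else {
    ev <- data.frame(dog_id = character(0), bowl_id = character(0),
                     start_time = numeric(0), end_time = numeric(0),
                     duration_s = numeric(0), mass_g = numeric(0),
                     mass_sched_g = numeric(0), bin = character(0))
  }

  nuis <- rbind(
    if (length(refills)) {
      r <- do.call(rbind, refills)
      data.frame(kind = "refill", time = r$time, magnitude_g = r$magnitude_g,
                 return_within_s = NA_real_)
    },
    if (!is.null(nudges)) nudges
  )
  if (is.null(nuis))
    nuis <- data.frame(kind = character(0), time = numeric(0),
                       magnitude_g = numeric(0), return_within_s = numeric(0))
  nuis <- cbind(bowl_id = rep(bowl_id, nrow(nuis)), nuis)

  trace <- data.frame(timestamp = t, weight_g = weight,
                      scale_id = rep(bowl_id, n), stringsAsFactors = FALSE)
  attr(trace, "sampling_interval_s") <- interval
  list(trace = trace, events = ev, nuisance = nuis)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full cohort of traces
#'
#' Generates one trace per dog and bowl under a study design, sharing a
#' per-dog random intercept across that dog's bowls so that repeated
#' measures are correlated as in the mixed models fitted downstream.
#'
#' @param design A [study_design()].
#' @param dogs Data.frame of dog profiles ([dog_profiles()]); `dog_id` must
#'   be unique.
#' @param config A [sim_config()].
#' @param seed Integer master seed; per-trace seeds are derived from it.
#' @return An object of class `hydro_cohort`: list with `design`, `config`,
#'   `dogs`, `bowls` (dog/bowl/sleeve map), `traces` (named list of trace
#'   data.frames), `truth` (all ground-truth events) and `nuisance`.
#' @export
simulate_cohort <- function(design, dogs, config = sim_config(),
                            seed = config$seed) {
  stopifnot(inherits(design, "study_design"), nrow(dogs) >= 1)
  if (anyDuplicated(dogs$dog_id))
    stop("duplicate dog_id in dog metadata")
  set.seed(derive_seed(seed, 0L))
  offsets <- rnorm(nrow(dogs), 0, config$dog_sd_ml_per_kg)

  bowls <- do.call(rbind, lapply(seq_len(nrow(dogs)), function(i) {
    data.frame(dog_id = dogs$dog_id[i],
               bowl_id = sprintf("%s_b%d", dogs$dog_id[i], seq_len(design$n_bowls)),
               sleeve = design$sleeves, stringsAsFactors = FALSE)
  }))

  traces <- vector("list", nrow(bowls))
  names(traces) <- bowls$bowl_id
  truth <- vector("list", nrow(bowls))
  nuis <- vector("list", nrow(bowls))
  for (k in seq_len(nrow(bowls))) {
    i <- match(bowls$dog_id[k], dogs$dog_id)
    sim <- simulate_trace(design, dogs[i, , drop = FALSE], bowls$bowl_id[k],
                          sleeve = bowls$sleeve[k], config = config,
                          seed = derive_seed(seed, k),
                          dog_offset_ml_per_kg = offsets[i])
    traces[[k]] <- sim$trace
    truth[[k]] <- sim$events
    nuis[[k]] <- sim$nuisance
  }
  structure(list(design = design, config = config, dogs = dogs, bowls = bowls,
                 traces = traces,
                 truth = do.call(rbind, truth),
                 nuisance = do.call(rbind, nuis)),
            class = "hydro_cohort")
}

#' @export
print.hydro_cohort <- function(x, ...) {
  cat(sprintf("Cohort (%s): %d dogs, %d traces, %d true events, %.0f h observation\n",
              x$design$experiment, nrow(x$dogs), length(x$traces),
              nrow(x$truth), observation_hours(x$design, nrow(x$dogs))))
  invisible(x)
}

#' Simulate daily per-bowl consumption from the mixed-model data-generating
#' process
#'
#' Draws daily mL/kg observations directly at the level the mixed models are
#' fitted at: `value = base + covariate effects + dog intercept + residual`,
#' with the dog intercept shared across all of a dog's rows. Used for
#' parameter-recovery and coverage studies of the model-fitting layer
#' without the expense of full trace simulation.
#'
#' @param n_dogs,n_days Cohort layout.
#' @param sleeve_effect Additive effect (mL/kg) of the preferred-scent bowl
#'   over the non-scented bowl.
#' @param base_ml_per_kg Mean daily intake (mL/kg) from the non-scented bowl.
#' @param diet_effect Additive effect (mL/kg) for dry-fed dogs; when
#'   non-zero, half the dogs are dry-fed and half combination-fed.
#' @param age_slope Additive effect per year of age (mL/kg/yr).
#' @param dog_sd,resid_sd Random-intercept and residual SDs (mL/kg).
#' @param seed Integer seed.
#' @return Data.frame with `dog_id`, `day`, `sleeve` (preferred/none),
#'   `diet`, `activity`, `age_years`, `ml_per_kg`, `n_events`.
#' @export
simulate_exp2_daily <- function(n_dogs = 10, n_days = 14, sleeve_effect = 5.26,
                                base_ml_per_kg = 16.4, diet_effect = 0,
                                age_slope = 0, dog_sd = 7, resid_sd = 6,
                                seed = 1L) {
  set.seed(as.integer(seed))
  dogs <- data.frame(
    dog_id = sprintf("dog%02d", seq_len(n_dogs)),
    diet = if (diet_effect != 0)
      rep(c("dry", "combination"), length.out = n_dogs) else "dry",
    activity = sample(c("lt30min", "30to60min", "gt1h"), n_dogs, replace = TRUE),
    age_years = runif(n_dogs, 1, 14),
    offset = rnorm(n_dogs, 0, dog_sd), stringsAsFactors = FALSE)
  g <- expand.grid(day = seq_len(n_days), sleeve = c("preferred", "none"),
                   dog = seq_len(n_dogs), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  mu <- base_ml_per_kg + sleeve_effect * (g$sleeve == "preferred") +
    diet_effect * (dogs$diet[g$dog] == "dry") +
    age_slope * dogs$age_years[g$dog] + dogs$offset[g$dog]
  val <- mu + rnorm(nrow(g), 0, resid_sd)
  data.frame(dog_id = dogs$dog_id[g$dog], day = g$day, sleeve = g$sleeve,
             diet = dogs$diet[g$dog], activity = dogs$activity[g$dog],
             age_years = dogs$age_years[g$dog],
             ml_per_kg = val, n_events = NA_integer_, stringsAsFactors = FALSE)
}

#' Simulate daily per-bowl consumption for the four-sleeve screen
#'
#' Daily-level analogue of [simulate_exp2_daily()] for the four-bowl
#' layout: one mL/kg observation per dog, day and sleeve with additive
#' sleeve effects, a shared per-dog intercept and residual noise. With all
#' sleeve effects zero it draws from the null of the scent factor.
#'
#' @param n_dogs,n_days Cohort layout.
#' @param sleeve_effects Named additive effects (mL/kg) vs the non-scented
#'   bowl.
#' @param base_ml_per_kg Non-scented bowl mean (mL/kg).
#' @param dog_sd,resid_sd Random-intercept and residual SDs (mL/kg).
#' @param seed Integer seed.
#' @return Data.frame with `dog_id`, `day`, `sleeve`, `ml_per_kg`.
#' @export
simulate_exp1_daily <- function(n_dogs = 20, n_days = 4,
                                sleeve_effects = c(chicken = 0, beef = 0,
                                                   peanut_butter = 0),
                                base_ml_per_kg = 6.08, dog_sd = 7,
                                resid_sd = 6, seed = 1L) {
  set.seed(as.integer(seed))
  sleeves <- c("chicken", "beef", "peanut_butter", "none")
  eff <- setNames(rep(0, 4), sleeves)
  eff[names(sleeve_effects)] <- sleeve_effects
  offset <- rnorm(n_dogs, 0, dog_sd)
  g <- expand.grid(day = seq_len(n_days), sleeve = sleeves,
                   dog = seq_len(n_dogs), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  data.frame(dog_id = sprintf("dog%02d", g$dog), day = g$day,
             sleeve = g$sleeve,
             ml_per_kg = base_ml_per_kg + eff[g$sleeve] + offset[g$dog] +
               rnorm(nrow(g), 0, resid_sd),
             stringsAsFactors = FALSE)
}

#' Simulate daily time-of-day bin consumption
#'
#' Bin-level analogue of [simulate_exp2_daily()]: one mL/kg observation per
#' dog, day and time-of-day bin, with additive bin contrasts relative to the
#' afternoon reference.
#'
#' @param n_dogs,n_days Cohort layout.
#' @param bin_effects Named contrasts (mL/kg) vs the afternoon bin.
#' @param base_ml_per_kg Afternoon-bin mean (mL/kg).
#' @param activity_effects Named contrasts vs the `lt30min` activity class.
#' @param dog_sd,resid_sd Random-intercept and residual SDs (mL/kg).
#' @param seed Integer seed.
#' @return Data.frame with `dog_id`, `day`, `time_of_day`, `activity`,
#'   `ml_per_kg`.
#' @export
simulate_bin_daily <- function(n_dogs = 10, n_days = 14,
                               bin_effects = c(morning = -0.96, evening = 8.75,
                                               night = -6.03),
                               base_ml_per_kg = 9.02,
                               activity_effects = c(`30to60min` = 0, gt1h = 0),
                               dog_sd = 5, resid_sd = 6, seed = 1L) {
  set.seed(as.integer(seed))
  bins <- c("morning", "afternoon", "evening", "night")
  eff <- setNames(rep(0, 4), bins)
  eff[names(bin_effects)] <- bin_effects
  act_lv <- c("lt30min", "30to60min", "gt1h")
  act_eff <- setNames(rep(0, 3), act_lv)
  act_eff[names(activity_effects)] <- activity_effects
  activity <- sample(act_lv, n_dogs, replace = TRUE)
  offset <- rnorm(n_dogs, 0, dog_sd)
  g <- expand.grid(bin = bins, day = seq_len(n_days), dog = seq_len(n_dogs),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- base_ml_per_kg + eff[g$bin] + act_eff[activity[g$dog]] + offset[g$dog]
  data.frame(dog_id = sprintf("dog%02d", g$dog), day = g$day,
             time_of_day = g$bin, activity = activity[g$dog],
             ml_per_kg = mu + rnorm(nrow(g), 0, resid_sd),
             stringsAsFactors = FALSE)
}
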