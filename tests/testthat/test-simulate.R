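cfg_quiet <- function(...) {
  sim_config(events_per_day_rate = 0, nudge_rate_per_day = 0,
             refill_policy = list(mode = "none"), ...)
}

test_that("trace layout is forced by the design arithmetic", {
  d2 <- study_design("exp2")
  expect_equal(d2$duration_days * 86400 / d2$sampling_interval_s, 40320)
  dog <- dog_profiles(1, seed = 3)
  sim <- simulate_trace(d2, dog, "b1", sleeve = "none", config = cfg_quiet(),
                        seed = 42)
  expect_equal(nrow(sim$trace), 40320)
  expect_equal(diff(sim$trace$timestamp[1:2]), 30)

  d1 <- study_design("exp1")
  expect_equal(d1$sampling_interval_s, 5)
  expect_equal(observation_hours(d1, 20), 1920)
})

test_that("no scheduled events yields a constant trace and empty truth", {
  d <- study_design("exp1", duration_days = 1)
  dog <- dog_profiles(1, seed = 3)
  sim <- simulate_trace(d, dog, "b1", sleeve = "none", config = cfg_quiet())
  expect_equal(nrow(sim$events), 0)
  expect_equal(length(unique(sim$trace$weight_g)), 1)
  expect_equal(sim$trace$weight_g[1], 1500)
})

test_that("mass is conserved between refills when quantization is off", {
  d <- study_design("exp1", duration_days = 2)
  dog <- dog_profiles(1, seed = 3)
  cfg <- sim_config(quantization_g = 0, nudge_rate_per_day = 0,
                    refill_policy = list(mode = "none"),
                    full_weight_g = 5000, base_ml_per_kg = 20,
                    dog_sd_ml_per_kg = 0)
  sim <- simulate_trace(d, dog, "b1", sleeve = "none", config = cfg, seed = 9)
  expect_gt(nrow(sim$events), 0)
  tr <- sim$trace
  expect_equal(tr$weight_g[1] - tr$weight_g[nrow(tr)],
               sum(sim$events$mass_sched_g), tolerance = 1e-9)
  # realized mass equals scheduled mass without quantization
  expect_equal(sim$events$mass_g, sim$events$mass_sched_g, tolerance = 1e-9)
  # with 1 g quantization, realized masses stay within a sample-rounding
  # step of the schedule
  cfg2 <- sim_config(quantization_g = 1, nudge_rate_per_day = 0,
                     refill_policy = list(mode = "none"),
                     full_weight_g = 5000, base_ml_per_kg = 20,
                     dog_sd_ml_per_kg = 0)
  sim2 <- simulate_trace(d, dog, "b1", sleeve = "none", config = cfg2, seed = 9)
  expect_true(all(abs(sim2$events$mass_g - sim2$events$mass_sched_g) <= 1))
})

test_that("identical seed and config reproduce the trace bit for bit", {
  d <- study_design("exp1", duration_days = 1)
  dog <- dog_profiles(1, seed = 3)
  cfg <- sim_config()
  a <- simulate_trace(d, dog, "b1", sleeve = "chicken", config = cfg, seed = 5)
  b <- simulate_trace(d, dog, "b1", sleeve = "chicken", config = cfg, seed = 5)
  expect_identical(a$trace, b$trace)
  expect_identical(a$events, b$events)
  c <- simulate_trace(d, dog, "b1", sleeve = "chicken", config = cfg, seed = 6)
  expect_false(identical(a$trace$weight_g, c$trace$weight_g))
})

test_that("nudges never change the net stable weight", {
  d <- study_design("exp1", duration_days = 1)
  dog <- dog_profiles(1, seed = 3)
  base <- simulate_trace(d, dog, "b1", sleeve = "none",
                         config = cfg_quiet(quantization_g = 0), seed = 4)
  nud <- simulate_trace(d, dog, "b1", sleeve = "none",
                        config = sim_config(events_per_day_rate = 0,
                                            nudge_rate_per_day = 10,
                                            refill_policy = list(mode = "none"),
                                            quantization_g = 0), seed = 4)
  expect_gt(nrow(nud$nuisance[nud$nuisance$kind == "nudge", ]), 0)
  expect_equal(nud$trace$weight_g[1], nud$trace$weight_g[nrow(nud$trace)])
})

test_that("cohort layout, shared intercepts and duplicate guard", {
  d <- study_design("exp1", duration_days = 1)
  dogs <- dog_profiles(5, seed = 2)
  cfg <- sim_config(events_per_day_rate = 2)
  co <- simulate_cohort(d, dogs, cfg, seed = 3)
  expect_equal(length(co$traces), 5 * 4)
  expect_equal(nrow(co$bowls), 20)
  expect_equal(sort(unique(co$bowls$sleeve)), sort(d$sleeves))
  expect_identical(simulate_cohort(d, dogs, cfg, seed = 3)$truth, co$truth)

  dogs2 <- rbind(dogs, dogs[1, ])
  expect_error(simulate_cohort(d, dogs2, cfg, seed = 3), "duplicate")
})

test_that("null preference effect gives equal expected consumption across bowls", {
  d <- study_design("exp2", duration_days = 4)
  dogs <- dog_profiles(6, seed = 8)
  cfg <- sim_config(base_ml_per_kg = 20, preference_effect_ml_per_kg = 0,
                    diet_effect_ml_per_kg = 0, dog_sd_ml_per_kg = 0,
                    day_sd_ml_per_kg = 0, quantization_g = 0,
                    nudge_rate_per_day = 0,
                    refill_policy = list(mode = "none"),
                    full_weight_g = 5000)
  co <- simulate_cohort(d, dogs, cfg, seed = 2)
  tot <- tapply(co$truth$mass_sched_g, co$truth$bowl_id, sum)
  per_dog <- split(co$bowls$bowl_id, co$bowls$dog_id)
  for (ids in per_dog) {
    mass <- dogs$body_mass_kg[match(co$bowls$dog_id[match(ids[1], co$bowls$bowl_id)],
                                    dogs$dog_id)]
    # each bowl's total equals days * base * mass exactly (no noise terms)
    expect_equal(as.vector(tot[ids]), rep(4 * 20 * mass, 2), tolerance = 1e-9)
  }
})

test_that("event times follow the diurnal weights (chi-square GOF, >= 10k events)", {
  d <- study_design("exp2", duration_days = 14)
  dog <- dog_profiles(1, seed = 1)
  cfg <- sim_config(events_per_day_rate = 100, base_ml_per_kg = 200,
                    full_weight_g = 100000, dog_sd_ml_per_kg = 0,
                    nudge_rate_per_day = 0,
                    refill_policy = list(mode = "none"), quantization_g = 0,
                    min_event_gap_s = 30, event_duration_range_s = c(10, 20))
  ev <- do.call(rbind, lapply(1:8, function(k)
    simulate_trace(d, dog, paste0("b", k), sleeve = "none", config = cfg,
                   seed = 100 + k)$events))
  expect_gt(nrow(ev), 10000)
  bins <- factor(bin_time_of_day(ev$start_time),
                 levels = c("morning", "afternoon", "evening", "night"))
  p <- suppressWarnings(stats::chisq.test(table(bins),
                                          p = cfg$diurnal_weights))$p.value
  expect_gt(p, 0.01)
})

test_that("refill policies: demand refills trigger, 'error' mode raises", {
  d <- study_design("exp1", duration_days = 2)
  dog <- dog_profiles(1, seed = 3)
  # small bowl, heavy drinking: must refill on demand
  cfg <- sim_config(full_weight_g = 300, base_ml_per_kg = 30,
                    dog_sd_ml_per_kg = 0, nudge_rate_per_day = 0)
  sim <- simulate_trace(d, dog, "b1", sleeve = "none", config = cfg, seed = 1)
  expect_gt(sum(sim$nuisance$kind == "refill"), 0)
  expect_true(all(sim$trace$weight_g > 0))

  cfg_err <- sim_config(full_weight_g = 150, base_ml_per_kg = 40,
                        dog_sd_ml_per_kg = 0, nudge_rate_per_day = 0,
                        refill_policy = list(mode = "error"))
  expect_error(simulate_trace(d, dog, "b1", sleeve = "none",
                              config = cfg_err, seed = 1), "run dry")
})
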