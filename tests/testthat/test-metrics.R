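mk_dog <- function(id = "d1", mass = 10) {
  data.frame(dog_id = id, body_mass_kg = mass, diet = "dry",
             activity = "lt30min", age_years = 4, preferred_scent = "chicken",
             stringsAsFactors = FALSE)
}
mk_bowls <- function(id = "d1", sleeves = c("chicken", "none")) {
  data.frame(dog_id = id, bowl_id = paste0(id, "_b", seq_along(sleeves)),
             sleeve = sleeves, stringsAsFactors = FALSE)
}
mk_events <- function(bowl_id, start_time, mass_g, dog_id = "d1") {
  data.frame(dog_id = dog_id, bowl_id = bowl_id, start_time = start_time,
             end_time = start_time + 30, mass_g = mass_g,
             stringsAsFactors = FALSE)
}

test_that("time-of-day bins are half-open six-hour clock intervals", {
  expect_equal(bin_time_of_day(18.5 * 3600), "evening")
  expect_equal(bin_time_of_day(12 * 3600), "afternoon")   # lower bound inclusive
  expect_equal(bin_time_of_day(6 * 3600 - 1), "night")    # 05:59:59
  expect_equal(bin_time_of_day(0), "night")
  expect_equal(bin_time_of_day(6 * 3600), "morning")
  # every second of the day maps to exactly one bin
  h <- bin_time_of_day(seq(0, 86399, by = 97))
  expect_true(all(h %in% c("morning", "afternoon", "evening", "night")))
  # midnight offset shifts the clock
  expect_equal(bin_time_of_day(0, midnight_offset_s = 7 * 3600), "morning")
})

test_that("daily consumption normalises to mL/kg and keeps zero days", {
  ev <- mk_events("d1_b1", c(10 * 3600, 14 * 3600), c(150, 150))
  ds <- daily_consumption(ev, mk_dog(), mk_bowls(), n_days = 2)
  expect_equal(nrow(ds), 4)  # 2 bowls x 2 days, zero rows kept
  r <- ds[ds$bowl_id == "d1_b1" & ds$day == 1, ]
  expect_equal(r$ml_per_kg, 30)           # (150+150)/10 kg
  expect_equal(r$n_events, 2)
  expect_equal(r$morning + r$afternoon + r$evening + r$night, r$ml_per_kg)
  expect_equal(r$morning, 15)
  expect_equal(r$afternoon, 15)
  # untouched bowl and day are explicit zeros
  expect_equal(ds$ml_per_kg[ds$bowl_id == "d1_b2"], c(0, 0))
  expect_equal(ds$ml_per_kg[ds$day == 2], c(0, 0))

  # event outside the study window errors
  ev_bad <- mk_events("d1_b1", 3 * 86400, 10)
  expect_error(daily_consumption(ev_bad, mk_dog(), mk_bowls(), n_days = 2),
               "outside the study window")
})

test_that("bin totals partition the daily total and scale with body mass", {
  set.seed(21)
  ev <- mk_events("d1_b1", sort(runif(40, 0, 2 * 86400 - 1)),
                  round(runif(40, 5, 80)))
  for (mass in c(5, 10, 20)) {
    ds <- daily_consumption(ev, mk_dog(mass = mass), mk_bowls(), n_days = 2)
    expect_equal(ds$morning + ds$afternoon + ds$evening + ds$night,
                 ds$ml_per_kg, tolerance = 1e-12)
  }
  d10 <- daily_consumption(ev, mk_dog(mass = 10), mk_bowls(), n_days = 2)
  d20 <- daily_consumption(ev, mk_dog(mass = 20), mk_bowls(), n_days = 2)
  expect_equal(d10$ml_per_kg, 2 * d20$ml_per_kg)   # doubling mass halves mL/kg
})

test_that("per-event statistics handle zero-event periods", {
  ev <- mk_events("d1_b1", seq_len(28) * 3600, rep(20, 28))
  s <- per_event_stats(ev, mk_dog(), n_days = 14)
  expect_equal(s$events_per_day, 2)

  s0 <- per_event_stats(ev[0, ], mk_dog(), n_days = 14)
  expect_equal(s0$events_per_day, 0)
  expect_true(is.na(s0$ml_per_kg_per_event))

  # 3 events of 10, 20, 30 g on a 6 kg dog: 60/6/3 = 10/3 mL/kg/event
  ev3 <- mk_events("d1_b1", c(1, 2, 3) * 3600, c(10, 20, 30))
  s3 <- per_event_stats(ev3, mk_dog(mass = 6), n_days = 1)
  expect_equal(s3$ml_per_kg_per_event, 10 / 3)
})

test_that("preference assignment is the argmax with deterministic tie-break", {
  mk_sum <- function(totals, firsts = NULL) {
    ds <- data.frame(dog_id = "d1", day = 1, bowl_id = paste0("b", seq_along(totals)),
                     sleeve = names(totals), ml_per_kg = unname(totals),
                     n_events = 1L, morning = 0, afternoon = 0, evening = 0,
                     night = 0,
                     first_event = if (is.null(firsts)) NA_real_ else unname(firsts),
                     stringsAsFactors = FALSE)
    ds
  }
  a <- assign_preference(mk_sum(c(chicken = 9, beef = 7, peanut_butter = 6.5,
                                  none = 6)))
  expect_equal(a$preferred_scent, "chicken")
  expect_false(a$no_preference)

  # one bowl only ever used
  b <- assign_preference(mk_sum(c(chicken = 0, beef = 4, peanut_butter = 0,
                                  none = 0)))
  expect_equal(b$preferred_scent, "beef")

  # exact tie: earliest first drink wins
  d <- assign_preference(mk_sum(c(chicken = 5, beef = 5),
                                firsts = c(chicken = 7200, beef = 3600)))
  expect_equal(d$preferred_scent, "beef")

  # nothing consumed at all: flagged, no preference
  z <- assign_preference(mk_sum(c(chicken = 0, beef = 0)))
  expect_true(z$no_preference)
  expect_true(is.na(z$preferred_scent))

  # increasing a scent's total never switches preference away from it
  base <- c(chicken = 9, beef = 7, peanut_butter = 6.5, none = 6)
  for (extra in c(0.5, 2, 10)) {
    up <- base
    up["chicken"] <- up["chicken"] + extra
    expect_equal(assign_preference(mk_sum(up))$preferred_scent, "chicken")
  }
})

test_that("stratified sampling is exact, seeded and guarded", {
  asg <- data.frame(dog_id = sprintf("d%02d", 1:16),
                    preferred_scent = rep(c("chicken", "beef"), c(9, 7)),
                    stringsAsFactors = FALSE)
  sel <- stratified_sample(asg, 5, seed = 11)
  expect_equal(length(sel), 10)
  expect_equal(sum(asg$preferred_scent[match(sel, asg$dog_id)] == "chicken"), 5)
  expect_equal(sum(asg$preferred_scent[match(sel, asg$dog_id)] == "beef"), 5)
  expect_identical(stratified_sample(asg, 5, seed = 11), sel)
  expect_false(identical(stratified_sample(asg, 5, seed = 12), sel))
  # n equal to the stratum size returns the whole stratum
  expect_setequal(stratified_sample(asg, 7, strata = "beef", seed = 1),
                  asg$dog_id[asg$preferred_scent == "beef"])
  expect_error(stratified_sample(asg, 8, strata = "beef", seed = 1),
               "stratum")
})
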