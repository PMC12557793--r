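test_that("moving average matches direct windowed means, incl. truncated edges", {
  x <- c(100, 100, 100, 200, 100, 100, 100)
  ma <- moving_average(x, 5)
  # centre index 4: (100+100+200+100+100)/5
  expect_equal(ma[4], 120)
  # truncated edges: window shrinks to available samples
  expect_equal(ma[1], mean(x[1:3]))
  expect_equal(ma[2], mean(x[1:4]))
  expect_equal(ma[7], mean(x[5:7]))
  expect_equal(moving_average(rep(100, 10), 5), rep(100, 10))
  expect_equal(moving_average(x, 1), x)
  expect_error(moving_average(numeric(0), 5), "empty")
  expect_error(moving_average(x, 4))   # even window
})

test_that("stability filter drops spikes and keeps exact-tolerance deviations", {
  tr <- make_trace(c(100, 100, 100, 200, 100, 100, 100))
  st <- stability_filter(tr, detector_config())
  expect_false(200 %in% st$weight_g)          # |200 - 120| = 80 > 5
  expect_true(all(st$weight_g == 100))
  # every sample whose window contains the spike deviates > 5: dropped
  expect_equal(nrow(st), 2)

  # a deviation of exactly 5 g is retained (strict ">"): +6.25 g on a
  # 100 g baseline deviates from its 5-point mean by 6.25 * 4/5 = 5
  tr5 <- make_trace(c(rep(100, 5), 106.25, rep(100, 5)))
  st5 <- stability_filter(tr5, detector_config())
  expect_true(106.25 %in% st5$weight_g)
  expect_equal(nrow(st5), 11)

  # sub-tolerance deviations are retained
  tr4 <- make_trace(c(rep(100, 2), 105, rep(100, 2)))
  ma4 <- moving_average(tr4$weight_g, 5)
  expect_equal(abs(tr4$weight_g[3] - ma4[3]), 4)  # 105 vs 101
  st4 <- stability_filter(make_trace(rep(c(100, 105), 5)),
                          detector_config(stability_tolerance_g = 5))
  expect_equal(nrow(st4), 10)                 # all deviations <= 5: retained

  expect_error(stability_filter(make_trace(c(0, 1000, 0, 1000, 0, 1000)),
                                detector_config(stability_tolerance_g = 0.5)),
               "unusable")
})

test_that("serial-loss detection finds events above the strict 2 g threshold", {
  cfg <- detector_config()
  st <- make_step_trace(c(1000, 990))
  st$segment <- 1L
  ev <- detect_consumption(st, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$mass_g, 10)
  expect_equal(ev$start_time, 45)  # last stable sample before the loss
  expect_equal(ev$end_time, 50)

  # loss of exactly 2 g seeds nothing
  ev2 <- detect_consumption(make_step_trace(c(1000, 998)), cfg)
  expect_equal(nrow(ev2), 0)

  # constant trace
  expect_equal(nrow(detect_consumption(make_step_trace(1000, 20), cfg)), 0)

  # two well-separated losses stay distinct; nearby ones merge
  ev3 <- detect_consumption(make_step_trace(c(1000, 990, 990, 980)), cfg)
  expect_equal(nrow(ev3), 2)
  expect_equal(ev3$mass_g, c(10, 10))
  st4 <- make_trace(c(rep(1000, 5), 990, 980, rep(970, 5)))
  ev4 <- detect_consumption(st4, cfg)
  expect_equal(nrow(ev4), 1)
  expect_equal(ev4$mass_g, 30)
})

test_that("transient fluctuations are flagged and produce no events", {
  # +50 g for one 5 s sample, then back: flagged, zero events
  tr <- make_trace(c(rep(100, 10), 150, rep(100, 10)))
  spans <- classify_transients(tr, detector_config())
  expect_equal(nrow(spans), 1)
  expect_equal(spans$baseline_g, 100)
  expect_equal(nrow(detect_events(tr)), 0)

  # -4 g dip for one sample: survives the stability filter but is flagged,
  # so no spurious 4 g event is emitted
  tr2 <- make_trace(c(rep(100, 10), 96, rep(100, 10)))
  st2 <- stability_filter(tr2, detector_config())
  expect_true(96 %in% st2$weight_g)            # deviation 3.2 <= 5
  expect_equal(nrow(classify_transients(tr2, detector_config())), 1)
  expect_equal(nrow(detect_events(tr2)), 0)

  # +50 g sustained for 60 s (a refill-like gain) exceeds the window: not flagged
  tr3 <- make_trace(c(rep(100, 10), rep(150, 12), rep(150, 10)))
  expect_equal(nrow(classify_transients(tr3, detector_config())), 0)

  # sub-threshold gain that reverts within the window is flagged too
  tr4 <- make_trace(c(rep(100, 10), 130, 130, rep(100, 10)))
  expect_equal(nrow(classify_transients(tr4, detector_config())), 1)
})

test_that("refill segmentation keeps consumption within segments", {
  cfg <- detector_config()
  # 1000 -> 900 (drink) -> 1500 (refill) -> 1400 (drink)
  tr <- make_step_trace(c(1000, 900, 1500, 1400))
  ev <- detect_events(tr, cfg)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$mass_g, c(100, 100))
  expect_equal(sum(ev$mass_g), 200)

  # refill only: zero events
  expect_equal(nrow(detect_events(make_step_trace(c(1000, 1500)), cfg)), 0)

  # segment labels increase at the refill
  st <- stability_filter(make_step_trace(c(1000, 900, 1500, 1400)), cfg)
  st <- handle_refills(st, cfg)
  expect_equal(length(unique(st$segment)), 2)
})

test_that("inserting a refill does not alter events detected before it", {
  cfg <- detector_config()
  ev_plain <- detect_events(make_step_trace(c(1000, 950, 900)), cfg)
  ev_refill <- detect_events(make_step_trace(c(1000, 950, 900, 1400, 1350)), cfg)
  expect_equal(nrow(ev_plain), 2)
  expect_equal(ev_refill[seq_len(nrow(ev_plain)), ], ev_plain)
  expect_equal(nrow(ev_refill), 3)
})

test_that("raising min_loss_g never increases total detected mass", {
  set.seed(11)
  for (rep in 1:5) {
    w <- 2000 - cumsum(sample(c(0, 0, 0, 1, 3, 8, 25), 200, replace = TRUE))
    tr <- make_trace(w)
    masses <- vapply(c(1, 2, 5, 10, 30), function(ml) {
      sum(detect_events(tr, detector_config(min_loss_g = ml))$mass_g)
    }, 0)
    expect_true(all(diff(masses) <= 1e-9))
  }
})

test_that("calibration recovers linear maps and rejects out-of-tolerance fits", {
  f1 <- calibrate_scale(c(0, 500, 2000), c(0, 500, 2000))
  expect_equal(f1$slope, 1)
  expect_equal(f1$intercept, 0, tolerance = 1e-12)
  expect_equal(f1$max_residual_g, 0, tolerance = 1e-9)
  expect_true(f1$accepted)

  # raw = 2*g + 10 with references 0 and 2000 g -> slope 0.5, intercept -5
  f2 <- calibrate_scale(c(10, 4010), c(0, 2000))
  expect_equal(f2$slope, 0.5)
  expect_equal(f2$intercept, -5)
  expect_equal(apply_calibration(f2, 1010), 500)

  # worst residual above 1 g: rejected
  f3 <- calibrate_scale(c(0, 1000, 2000), c(0, 1003, 2000))
  expect_gt(f3$max_residual_g, 1)
  expect_false(f3$accepted)

  expect_error(calibrate_scale(c(1, 2), c(5, 5)), "distinct")
})
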