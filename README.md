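# hydrotrace

Measuring daily water consumption of dogs from load-cell bowl scales.

Domestic dogs on dry diets often drink less than recommended, and simple
enrichment — such as scent-infused silicone sleeves fitted to the water
bowl — has been proposed to nudge intake upward. Testing that idea in
households requires an unobtrusive way to measure *how much* a dog drinks,
*when*, and *from which bowl*. `hydrotrace` implements the full analysis
chain for such studies, for behavioural and veterinary researchers working
with timestamped bowl-weight recordings:

1. **Simulation** of realistic scale traces with full ground truth —
   drinking bouts as stepwise losses, owner refills, transient "nudge"
   fluctuations, 1 g weight quantization, evening-peaked diurnal structure,
   per-dog preference and diet effects (`simulate_trace()`,
   `simulate_cohort()`).
2. **Detection** of consumption events from raw traces: a 5-point centred
   moving average; removal of raw samples deviating from it by more than
   5 g; serial losses of more than 2 g between successive stable samples
   retained as drinking events; excursions returning to the prior stable
   weight within 10 s excluded as transients; sustained gains segmented as
   refills (`detect_events()`). Scale calibration against reference masses
   is included (`calibrate_scale()`).
3. **Metrics**: daily consumption per bowl normalised by body mass
   (1 g water = 1 mL, so mL/kg), six-hour time-of-day bins, events/day,
   quantity/event, per-dog scent preference and stratified sampling
   (`daily_consumption()`, `assign_preference()`, `stratified_sample()`).
4. **Validation** of the detector against ground truth by greedy
   nearest-timestamp matching; the headline metric is the *mass error
   rate*, `100 × miscalculated detected mass / total detected mass`
   (`validate_detection()`, `run_validation()`).
5. **Statistics**: random-intercept linear mixed models
   `y_ij = Xβ + b_i + ε_ij`, `b_i ~ N(0, σ_dog²)`, fitted by REML with
   Satterthwaite degrees of freedom (lme4/lmerTest), a likelihood-ratio
   χ² test for the four-level scent factor, and nonparametric bootstrap
   percentile CIs for descriptive means (`fit_exp1_scent()`,
   `fit_exp2_sleeve_diet()`, `fit_exp2_time_activity()`,
   `fit_univariate_age()`, `fit_event_models()`, `bootstrap_mean_ci()`).
6. A reproducible end-to-end **pipeline**: simulate → detect → summarize →
   validate → fit, with every intermediate written to CSV/JSON and a
   markdown report (`run_pipeline()`).

Two study layouts are built in: a four-bowl scent screen sampled every 5 s
over 4 days (`study_design("exp1")`) and a two-bowl preferred-vs-non-scented
follow-up sampled every 30 s over 14 days (`study_design("exp2")`).

## Worked example

Simulate a 14-day two-bowl cohort of 10 dogs with a true preferred-sleeve
effect of 5.26 mL/kg, detect events, validate, and fit the sleeve model:

```r
library(hydrotrace)

design <- study_design("exp2", duration_days = 14)
dogs   <- dog_profiles(10, seed = 42)
cohort <- simulate_cohort(design, dogs,
                          sim_config(base_ml_per_kg = 16.4,
                                     scent_effects_ml_per_kg = c(none = 0),
                                     preference_effect_ml_per_kg = 5.26,
                                     diet_effect_ml_per_kg = 0,
                                     events_per_day_rate = 6),
                          seed = 42)
cohort
#> Cohort (exp2): 10 dogs, 20 traces, 1603 true events, 3360 h observation

events <- do.call(rbind, lapply(names(cohort$traces), function(id) {
  e <- detect_events(cohort$traces[[id]])
  e$dog_id <- cohort$bowls$dog_id[match(id, cohort$bowls$bowl_id)]
  e
}))

validate_detection(events, cohort$truth, time_tolerance_s = 90)
#> Validation: 366.00 g miscalculated of 98158.00 g detected -> 0.37% error rate
#>   events: 1620 detected, 1603 true, 60 miscalculated, 42 missed

daily <- daily_consumption(events, cohort$dogs, cohort$bowls, n_days = 14)
fit_exp2_sleeve_diet(merge(daily, dogs[, c("dog_id", "diet")], by = "dog_id"))
#> Random-intercept model 'exp2_sleeve_diet' (280 obs, 10 dogs)
#>   term                 est [      lo,       hi]        p
#>   (Intercept)       12.625 [   6.760,   18.491]  0.00103
#>   sleevepreferred    4.607 [   3.232,    5.983] 2.25e-10
#>   dietnondry         0.606 [ -17.889,   19.100]    0.942
#>   random intercept SD 7.53, residual SD 5.85
```

Reading the output: the detector recovered 98.2 kg of the simulated water
with a 0.37% mass error rate; the mixed model attributes 4.6 mL/kg extra
daily intake to the preferred-scented bowl (true value 5.26, inside the
95% CI), with a between-dog SD of 7.5 mL/kg. The 42 missed events are
small bouts whose per-sample losses never exceed the 2 g threshold — a
genuine limitation of the thresholded algorithm, not of the simulation.

`run_pipeline(pipeline_config("exp2", n_dogs = 10, seed = 1), out_dir = "out")`
performs the same steps end to end and writes the traces, events, daily
summaries, validation report, model fits and a markdown report to `out/`.

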