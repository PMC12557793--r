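---
title: "Measuring canine water intake from bowl-scale traces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring canine water intake from bowl-scale traces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrotrace)
```

# The measurement problem

A load-cell scale under a water bowl records a quantized weight (1 g
resolution) every 5 or 30 seconds. Three kinds of signal are superimposed
on that trace: stepwise *losses* when the dog drinks, large sustained
*gains* when the owner refills, and short-lived *excursions* when the dog
nudges or leans on the scale. The analysis task is to recover the drinking
episodes — their times and masses — and turn them into per-dog daily
intake normalised by body mass (1 g of water ≡ 1 mL, so g/kg = mL/kg),
then model that intake.

# The detection algorithm

`detect_events()` applies four steps, in order:

1. **Transient classification** (`classify_transients()`). A span of
   samples that departs from the current stable weight and returns to
   *exactly* that weight within the transient window (default 10 s) is
   flagged and excluded. This is what prevents a brief −4 g wobble from
   being counted as a 4 g drink. A departure that never returns — a drink
   step or a refill — instead updates the running stable weight.
2. **Stability filtering** (`stability_filter()`). A centred moving
   average (default 5 points, truncated at the trace edges) is computed on
   the raw weights; samples deviating from it by strictly more than the
   stability tolerance (default 5 g) are dropped, not interpolated. A
   deviation of exactly 5 g is retained: all thresholds in the algorithm
   are strict inequalities, following the "more than" reading of the
   original procedure. The centred window avoids phase lag, so the
   deviation test is symmetric around steps.
3. **Refill segmentation** (`handle_refills()`). A gain of at least
   `refill_threshold_g` (default 50 g) between successive stable samples
   splits the trace; losses are never computed across a refill, so a
   refill can neither hide nor create consumption.
4. **Serial-loss extraction** (`detect_consumption()`). Within each
   segment, losses between successive stable samples are computed. A loss
   strictly greater than `min_loss_g` (default 2 g) *seeds* an event;
   contiguous loss steps separated by at most `merge_gap_samples`
   (default 2) stable samples are merged into one event whose mass is the
   sum of all losses in the merged span. Including the sub-threshold edge
   losses adjoining a qualifying step makes the event mass equal to the
   drop in stable weight across the span, which is what gives exact mass
   recovery on clean traces. Gains never contribute negative mass.

Two properties follow by construction and are asserted in the test suite:
on noiseless traces without nudges or refills, total detected mass equals
total true mass exactly and the event count matches; and raising
`min_loss_g` can only remove whole events, so total detected mass is
monotone non-increasing in the threshold.

## Steep losses and the filter

A large bout concentrated in one or two samples (e.g. 50 g between
consecutive 30 s samples) drags the moving average enough that the two or
three samples around the step exceed the 5 g tolerance and are dropped.
The surviving stable samples then bracket the whole drop, which the
serial-loss step recovers as a single event. The practical consequences
are (a) detected start times can precede the true bout start by up to
`(ma_window - 1)/2 + 1` sampling intervals, which is why validation
matching uses a tolerance of three sampling intervals by default in the
pipeline, and (b) two bouts closer together than roughly six sampling
intervals can merge into one detection — at 30 s sampling the algorithm's
intrinsic bout-separation resolution is therefore about three minutes.

## Thresholds in the 30 s mode

The gram and second thresholds are deliberately reused unchanged at 30 s
sampling. One consequence is that the 10 s transient window can never span
two samples 30 s apart, so the transient rule is inert in that mode; a
sub-tolerance wobble that happens to cover a sample tick (for example a
brief −4 g lean) can then pass as a small spurious event. This is a known
limitation of the thresholded design, visible in the validation reports as
a residual error well under 1%.

# The simulator

`simulate_trace()` generates the conditions the detector is meant to face,
with full ground truth:

* **Bouts.** The number of drinking events per bowl-day is Poisson
  (default mean 8); bout masses are gamma-distributed (shape 4 — positive
  and right-skewed, like real intake bouts) and rescaled so the day's
  total matches the target intake; each bout is spread as a linear
  decrement over a 15–45 s duration. The within-bout shape is a modelling
  choice — nothing downstream depends on it beyond the per-sample losses
  it induces. Distinct bouts are scheduled at least five minutes apart:
  a dog returning to the bowl within a few minutes is treated as one bout.
* **Intake targets.** Expected daily intake per bowl is
  `base + scent effect + preference effect + diet effect + dog intercept`,
  in mL/kg, plus day-to-day noise. Defaults follow the magnitudes observed
  in the motivating household study: a non-scented-bowl base of
  16.4 mL/kg in the two-bowl layout, a preferred-sleeve increment of
  5.26 mL/kg, a dry-diet increment of 10.75 mL/kg, a between-dog SD of
  7 mL/kg and a residual SD of 6 mL/kg; the validation workload uses
  ~8 bouts and ~330 g per bowl-day, matching the arithmetic of the
  original 12-file manual validation (95 events, 3,941 g over 288 h).
* **Diurnal structure.** Bout times are drawn from the four six-hour
  clock bins with weights proportional to the observed bin means
  (morning 8.06, afternoon 9.02, evening 17.8, night 3.17 mL/kg), i.e.
  an evening peak. A chi-square goodness-of-fit test over >10,000
  simulated events checks the allocation.
* **Nuisance events.** Nudges are brief (2–10 s) excursions — mostly
  presses of +20–200 g, a minority small −3 to −4.9 g wobbles below the
  stability tolerance, so that only the transient rule can exclude them.
  They are placed in quiet periods (not overlapping bouts or refills) so
  each returns to a constant baseline, matching the definition of a
  transient. Owner refills restore the bowl to full at a fixed hour daily,
  plus on demand shortly *before* a bout that would leave the bowl below
  10% of full — never mid-bout, which no real owner does and which would
  make the ground truth ill-defined.
* **Quantization.** Recorded weights are rounded to 1 g. Ground-truth
  masses are reported both as scheduled (`mass_sched_g`, continuous) and
  as *realized* on the quantized recording (`mass_g`, the drop in
  quantized stable weight across the bout). Validation compares against
  the realized mass: a human reader of the raw files could only ever see
  the quantized weights, so that is the reference the detector should be
  held to.
* **Not emulated:** evaporation (exposed as an optional linear drift,
  default 0), multi-dog interference, scale drift or electronics
  artefacts, bouts that overlap nuisance events, and any within-bout
  microstructure (lap rates). Passing tests therefore show that the
  algorithm is correct *for this signal model*; they do not certify
  performance on pathologies the model excludes.

Determinism: every simulation function takes a seed, cohort functions
derive per-trace seeds from a master seed (kept under 2³¹), and identical
seeds reproduce traces bit for bit.

# Metrics

Days are local calendar days (midnight to midnight, with a configurable
clock offset), because the time-of-day bins are clock-defined: morning
[06,12), afternoon [12,18), evening [18,24), night [00,06), half-open so
every timestamp falls in exactly one bin. Bin totals sum exactly to the
daily total. Bowl-days with no events are kept as explicit zero rows —
they are observations, and dropping them would bias the models. Quantity
per event is undefined on zero-event days and reported as missing, not
zero; events/day counts zero days in its denominator.

A dog's preferred scent is the sleeve with the largest summed mL/kg over
the screening days. Exact ties (possible with quantized masses) are broken
deterministically in favour of the sleeve drunk from earliest; a dog that
never drank is flagged as having no preference rather than being assigned
one arbitrarily.

# Validation

Detections are matched to ground truth greedily by nearest start time
within a tolerance, each truth event matching at most one detection; when
both tables carry bowl identifiers, matching is per bowl. The error rate
is `100 × miscalculated mass / total detected mass`, where miscalculated
mass is the full mass of unmatched detections plus the absolute mass
difference of matched pairs. Extending the metric to matched-pair
differences makes it total (a detection can be wrong in mass, not only in
existence). Truth events with no detection are reported separately as
missed but excluded from the rate, whose numerator and denominator are
both detected mass.

# Statistical models

All models are random-intercept linear mixed models fitted by REML with
lme4, with Satterthwaite degrees of freedom and Wald-t 95% intervals via
lmerTest — the standard small-sample practice for repeated-measures animal
data. The four-level scent factor in the screening experiment is tested
with a likelihood-ratio χ² (df = 3) between nested fits refit by maximum
likelihood, since REML likelihoods are not comparable across fixed-effect
structures. Treatment coding with the non-scented sleeve as reference
makes the fixed effects directly the post-hoc contrasts of interest; no
multiplicity correction is applied by default. Diet is coded dry vs
non-dry (wet and combination pooled), exposed as an option. Age is
modelled univariately because it is collinear with diet and activity in
small cohorts. Singular fits (between-dog variance estimated at zero) are
reported with a warning flag rather than silently; a fully degenerate
response (all observations identical) returns exact zero contrasts.
Bootstrap CIs for descriptive means are percentile intervals over 10,000
resamples by default.

Calibration of this machinery is checked by simulation at the study's own
scale (10 dogs × 14 days × 2 bowls, intercept SD 7, residual SD 6): the
type-I error of the scent LRT over 500 null replicates must lie in
[0.03, 0.07] at α = 0.05, and the 95% CI coverage of the sleeve effect
over 500 recovery replicates in [93%, 97%]. Parameter recovery of the
sleeve effect and the evening-vs-afternoon contrast is averaged over 200
simulated cohorts. These problem sizes keep the whole suite comfortably
fast while leaving Monte-Carlo error well inside the asserted bands.

# Degenerate inputs and numerical conventions

* Empty traces, traces whose samples are all filtered away, calibration
  with fewer than two distinct reference masses, zero total detected mass,
  an empty bootstrap input, single-dog mixed models and constant-age
  models all raise informative errors rather than returning quiet
  nonsense.
* Weight quantization uses `round()` (banker's rounding at .5, matching
  R); mass-conservation assertions allow for half-step rounding when
  quantization is on and are exact when it is off.
* The moving average at trace edges truncates the window to the available
  samples, keeping the output aligned 1:1 with the input.
* All seeds are integer and all derived seeds stay below 2³¹ − 1.

# Known limitations

* Sub-threshold drinking (every per-sample loss ≤ 2 g) is invisible by
  design; slow lappers at 5 s sampling and small bouts generally are
  under-counted. The validation report exposes this as missed events.
* At 30 s sampling the transient rule cannot fire and bout separation
  below ~3 min is unresolvable (see above).
* The refill threshold (50 g) assumes refills are much larger than single
  bout losses; topping up a nearly full bowl by a few grams would be
  misread as noise or, if it reverts, a transient.
* The error-rate denominator is detected mass, so a detector that misses
  heavily but is accurate on what it finds scores well on the rate alone;
  the per-event counts in the report are the complementary check.
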