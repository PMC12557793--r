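Package: hydrotrace
Title: Drinking-Event Detection and Intake Analysis from Load-Cell Water-Bowl Scales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring daily water consumption of dogs from
    timestamped bowl-weight traces recorded by load-cell scales. Provides a
    synthetic trace simulator with full ground truth (drinking events, owner
    refills, transient nudges, 1 g quantization, diurnal structure), a
    consumption-event detection algorithm (moving-average stability filter,
    serial-loss thresholding, transient-fluctuation exclusion, refill
    segmentation), scale calibration, daily intake metrics normalised to
    mL/kg with time-of-day bins, an algorithm-validation error-rate
    procedure, random-intercept linear mixed models of intake, and
    nonparametric bootstrap confidence intervals, tied together by a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
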