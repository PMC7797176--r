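Package: adprogress
Title: Forecasting Alzheimer's Disease Progression from Longitudinal Clinical Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for monthly-grid longitudinal modelling of Alzheimer's disease
    progression. Implements a minimal gated recurrent network and a linear
    state-space baseline trained with a masked multi-task loss (cross-entropy on
    the clinical diagnosis, mean absolute error on 22 continuous markers), three
    missing-data strategies (forward filling, linear filling, and integrative
    model filling in which the network's own one-step-ahead predictions stand in
    for missing inputs), recursive any-horizon forecasting, constant-prediction
    and support-vector baselines on a horizon grid, and a TADPOLE-style
    evaluation suite (multiclass AUC, balanced class accuracy, mean absolute
    error, subject-group and yearly-horizon breakdowns, corrected resampled
    t-tests across repeated splits). A seeded synthetic-cohort generator
    emulating ADNI-like visit schedules, marker distributions and missingness
    makes the whole pipeline exercisable without access-controlled data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
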