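Package: hrvstress
Title: Stress Reactivity and Recovery Dynamics from Ambulatory Heart Rate Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying vagally-mediated heart rate variability (vmHRV)
    around naturalistic stressful events recorded with wearable ECG and
    accelerometer devices. Screens RR-interval series for artifacts, aggregates
    them to 60-second resolution, computes RMSSD on 5-minute segments, identifies
    self-marked and device-detected (MET-based) stressful events, derives
    resting/reactivity difference scores and sliding-window recovery times with
    pile-up and timeout censoring, codes time-windowed and person-level
    covariates, and fits the corresponding multilevel models (linear mixed model
    for reactivity; Poisson generalized linear mixed model for recovery minutes,
    reported as incidence rate ratios). Includes a synthetic-cohort generator
    with known ground truth so every stage can be validated by parameter
    recovery without access to raw participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
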