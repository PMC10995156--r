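Package: hipacc
Title: Quality Control and Physical Activity Metrics for Raw Hip-Worn
    Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing pipeline for raw triaxial hip-worn accelerometer
    recordings in large epidemiological cohorts: sphere-fit auto-calibration
    from non-movement periods with a calibration-error exclusion gate,
    per-epoch ENMO and MAD signal features, posture angles and empirical
    identification of the longitudinal axis, non-wear and clipping detection
    on 15-minute segments, within-person imputation of invalid segments,
    valid-day and participant inclusion rules, four-level aggregation of
    activity metrics, intensity-bin and MVPA estimators, stratified
    winsorization and subgroup reporting, and an intraclass-correlation
    simulation quantifying the reliability of k-day averages. Includes a
    synthetic-cohort generator with ground-truth labels (circadian posture
    rhythm, activity bursts, non-wear episodes, calibration distortions,
    12-bit quantization) so every stage is testable without restricted
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
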