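Package: ppfi
Title: Performance Fatigability from Wrist Accelerometry During a 400-m Walk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for accelerometry-based
    performance fatigability in older adults. Generates synthetic wrist
    accelerometer recordings from a usual-paced 400-m walk with known cadence
    ground truth, extracts cadence-versus-time trajectories by short-time
    spectral analysis, smooths them with penalized regression splines, and
    computes the Pittsburgh Performance Fatigability Index (PPFI): the percent
    shortfall of the observed cadence trajectory's area relative to the area
    under sustained maximal cadence. Also generates cohort tables with a
    known left-censored data-generating process calibrated to published
    summary statistics, and estimates associations between skeletal-muscle
    energetics and PPFI via left-censored (tobit) maximum likelihood and
    proportional-odds ordinal regression with the Brant-Wald proportionality
    test, including trend tests, Spearman correlations, progressive covariate
    tiers, and interaction and physical-function-stratified analyses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    survival,
    jsonlite
Config/testthat/edition: 3
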