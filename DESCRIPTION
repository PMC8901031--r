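Package: cgmetrics
Title: Glucose and Glycemic Variability Metrics from Continuous Glucose
    Monitor Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for systematic, reproducible analysis of continuous
    glucose monitor (CGM) time series. Imports Dexcom and Abbott
    FreeStyle Libre CSV exports into a canonical tidy glucose series,
    computes 28 clinically validated metrics of glucose and glycemic
    variability (including MAGE, MODD, CONGA, LBGI/HBGI, ADRR, GMI and
    estimated A1c) through 25 metric functions, renders longitudinal
    visualizations (mean +/- SD band, hypo-/hyperglycemia thresholds,
    LOWESS smoothing, by-day overlays), and ships a seeded synthetic CGM
    simulator with circadian structure, meal excursions, autocorrelated
    sensor noise and missing-data gaps so every analysis path can be
    exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
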