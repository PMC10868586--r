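Package: thermotol
Title: Thermal Death Time Modelling of Ectotherm Heat Tolerance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing critical thermal limits of aquatic
    ectotherms with the thermal death time (TDT) framework. Fits
    injury-accumulation models to dynamic CTmax ramping assays, converts
    between static and dynamic thermal limits, predicts knockdown
    temperatures under slow habitat heating rates and tolerable exposure
    durations for ecologically relevant temperature bands, summarises
    temperature-logger time series (daily extremes, sunrise-to-peak heating
    rates, time-in-band exposure, heat-spike events), computes thermal
    safety margins and tolerance breadths, and provides a trial-blocked
    permutation test for species-by-oxygen interactions. Includes synthetic
    generators for assay records and diel logger series so the full
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
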