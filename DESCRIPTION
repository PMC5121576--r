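Package: altiop
Title: Altitude-Driven Intraocular Pressure Change in Gas-Tamponade Eyes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how intraocular pressure (IOP) responds to
    altitude in vitrectomized eyes carrying a gas tamponade, built around
    Friedenwald's log-pressure/volume model of scleral rigidity. The package
    estimates ocular rigidity from paired Schiotz indentation readings at two
    plunger weights, fits per-eye linear regressions of IOP on altitude with
    confidence-interval slope comparison, extrapolates measured rabbit
    pressure series to human-equivalent series under published human rigidity
    coefficients, and provides a travel-advisory calculator for predicted IOP
    after an altitude change. A seeded synthetic road-trip generator supports
    parameter-recovery and coverage checks of the regression stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
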