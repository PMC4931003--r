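Package: thermoreg
Title: Thermoregulation Effectiveness Analysis for Alpine Lizards
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the behavioural-thermoregulation analysis of alpine
    ectotherms: estimation of the preferred (set-point) temperature range from
    laboratory gradient selections, the Hertz accuracy (d_b), habitat thermal
    quality (d_e) and effectiveness (E = 1 - mean d_b / mean d_e) indices with
    bootstrap pseudo-distributions, operative-temperature microhabitat
    profiling with hourly thermal-suitability assessment, a two-era warming
    comparison (location tests, temperature-type by era interaction, ANCOVA
    slope homogeneity) and thermal safety margins against the physiological
    optimum. A calibrated synthetic-data generator reproduces the statistical
    structure of field capture records, gradient selections and copper-model
    operative-temperature logger series, so that the whole pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
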