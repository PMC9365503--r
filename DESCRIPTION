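Package: oarrisk
Title: Radiobiological Risk Modelling for Organs at Risk in Breast Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models late normal-tissue effects of breast radiotherapy across
    whole-breast irradiation and boost techniques. Provides biologically
    effective dose (BED) and EQD2 plan summation under the linear-quadratic
    model, dose-volume histogram construction and metrics, equivalent uniform
    dose and Lyman-Kutcher-Burman normal-tissue complication probability,
    Schneider-type secondary-cancer excess absolute risk (linear no-threshold
    out-of-field and full mechanistic in-field models), the linear excess
    relative risk model for major coronary events, thermoluminescent dosimeter
    (TLD) out-of-field dose aggregation, a seeded synthetic-cohort generator
    for four treatment scenarios, and cohort-level scenario comparison with
    normality-gated two-sample testing and report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
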