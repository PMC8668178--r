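Package: penflux
Title: Gas Emissions, Growth and Dose-Response Analysis for Enclosed
    Cattle Feeding Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for beta-adrenergic modulator
    dose-titration trials run in mechanically ventilated cattle pen
    enclosures. Converts rotating-analyzer gas concentration readings
    (NH3, CH4, CO2, H2S, N2O) to emission fluxes with an ideal-gas
    conversion and a fan-decay airflow model, applies data-validity rules
    (door-event exclusion windows, minimum-valid-minutes thresholds,
    neighbour-day substitution), aggregates to daily, per-animal,
    cumulative and weight-standardized emissions, computes growth and
    carcass metrics (DMI, ADG, G:F, dressing percent, USDA yield and
    quality grades, THI, shear force), fits the randomized-complete-block
    dose-by-sex ANOVA with planned control contrasts, selects among five
    competing linear/linear-plateau dose-response models to determine
    minimum and maximum effective doses, and ships a synthetic trial
    generator so the whole pipeline is testable without access to raw
    trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
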