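Package: wearversion
Title: Effects of Wearable Software and Hardware Upgrades on Daily Activity Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating the effect of smartwatch software and
    hardware version upgrades on daily activity summaries (exercise minutes,
    active calories). Implements wear-time estimation from heart-rate sampling
    gaps, day-level version assignment from raw version metadata, detection of
    per-participant upgrade transition dates, construction of 14-day
    treatment and control comparison windows with eligibility and completeness
    rules, person-day exclusion filters, descriptive pre/post change
    summaries, and negative binomial mixed-model rate-ratio estimation with a
    participant random intercept integrated by adaptive Gauss-Hermite
    quadrature. Includes a synthetic HealthKit-like cohort generator with a
    ground-truth ledger for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmmTMB,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
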