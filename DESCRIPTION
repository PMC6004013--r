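Package: urometab
Title: QC-Anchored Batch Correction and PLS-DA Surveillance for Urinary
    LC-MS Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for untargeted urinary LC-MS
    metabolomics in bladder-cancer recurrence surveillance. Provides
    quality-control (QC) anchored batch-effect correction of peak tables
    (per-feature support-vector-regression drift models fitted to pooled-QC
    injections, between-batch median equalization, blank-based background
    removal, RSD reliability filtering), multiplicative scatter correction
    and Pareto scaling, PLS-DA classification with leave-one-patient-out
    cross-validation and VIP feature screening, diagnostic figures of merit
    with exact binomial and log-method likelihood-ratio confidence
    intervals plus prevalence-adjusted predictive values, and per-patient
    longitudinal trajectories of the discriminant score. Ships a synthetic
    cohort generator emulating the acquisition design (two batches,
    periodic QCs, smooth intensity drift, heteroscedastic multiplicative
    noise, class effects, relapse trajectories) so the whole pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    mixOmics,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
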