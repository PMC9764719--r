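Package: occmsm
Title: Marginal Structural Models for Time-Varying Hospital Capacity
    Utilization and 14-Day In-Hospital Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the causal effect of time-varying high hospital bed
    occupancy (capacity utilization) on 14-day in-hospital mortality from
    patient-level administrative records. Derives per-hospital daily census,
    capacity-utilization and patient-turnover series, hospital-specific
    percentile exposure thresholds, and a censored person-day analysis table;
    estimates stabilized inverse-probability-of-treatment weights and fits
    weighted pooled logistic marginal structural models with cluster-robust
    variance; provides a directed-acyclic-graph toolkit (d-separation,
    backdoor adjustment, treatment-confounder-feedback detection) and a
    multi-hospital synthetic cohort simulator with occupancy feedback, an
    unmeasured staffing process and a randomized-exposure oracle for
    validating the estimators against a known causal truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    sandwich,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
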