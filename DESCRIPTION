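Package: pedctrisk
Title: Hematological Malignancy Risk from Pediatric CT Radiation Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of cohorts of children, adolescents and
    young adults exposed to computed-tomography (CT) radiation, for estimating
    the excess relative risk (ERR) and excess absolute risk (EAR) of
    hematological malignancies per unit cumulative active-bone-marrow dose.
    Provides a seeded synthetic-cohort generator with two-component
    (shared/unshared) lognormal dose uncertainty and piecewise-exponential
    event simulation under a linear relative-risk model; follow-up derivation
    and inclusion/exclusion bookkeeping; lagged cumulative-dose metrics, dose
    categories and exposure-window decompositions; a stratified
    partial-likelihood engine for the linear ERR model with
    profile-likelihood confidence intervals, categorical relative risks,
    trend and heterogeneity tests; an additive-excess Poisson model on
    person-year tables; and sensitivity-analysis machinery (alternative lags,
    percentile truncation, exclusion windows, leave-one-country-out,
    exam-count exposure metric).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite
Config/testthat/edition: 3
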