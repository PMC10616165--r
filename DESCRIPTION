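Package: neuroburden
Title: Prognostic Models and Disease Burden for Neurocritical Care Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cohorts of intensive-care patients with
    acute neurological disorders: classification of potential secondary
    brain injuries ("Hs") from admission physiology, modified Rankin
    Scale outcome coding, univariate 2x2 odds ratios and multivariable
    logistic prognostic models with Wald inference and ROC AUC, and a
    disability-adjusted life-year (DALY) engine combining life-table
    years of life lost with prevalence-weighted, comorbidity-corrected
    years lived with disability. Includes a synthetic cohort generator
    emulating the marginal structure of a multicentre Brazilian
    neurocritical-care study, so every stage of the pipeline is testable
    without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
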