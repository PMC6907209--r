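Package: ddikit
Title: Normative Brain-Age Modelling and the Developmental Deviation Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for normative modelling of brain development from regional
    anatomical (cortical volume, surface area, thickness) and diffusion (FA,
    ADC) metrics. Trains a linear age-prediction ("brain age") model on a
    typically developing cohort with repeated k-fold cross-validation,
    computes a bias-corrected, z-normalised Developmental Deviation Index
    (DDI) for a clinical cohort, stratifies the cohort into Advanced,
    Balanced and Delayed developmental subgroups, and quantifies the
    DDI-symptom-severity relationship with nonparametric effect sizes,
    Fisher r-to-z confidence intervals and proportional-odds ordinal
    regression. Includes a seeded synthetic-cohort generator with known
    ground-truth developmental deviations so the whole pipeline is testable
    without clinical data.
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
    glmnet,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
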