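Package: incns
Title: INCNS Neurocritical-Illness Prognostic Score and Validation Toolkit
Version: 0.1.0
Authors@R:
    person("N-ICU", "Scoring Toolkit Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the 19-item, 44-point INCNS prognostic score for
    neurocritically ill patients (inflammation, nutrition, consciousness,
    neurologic function, systemic condition), together with the comparator
    severity scores it is benchmarked against (Glasgow Coma Scale, FOUR,
    APACHE II, SAPS II), worst-value abstraction of longitudinal observations
    over 24 h and 72 h windows, and a validation battery: empirical ROC and
    AUC with DeLong confidence intervals and paired AUC comparison, Youden
    cutoff selection with full confusion metrics, paired McNemar tests,
    Wald-type comparison of positive and negative predictive values, and a
    logistic score-to-probability map. A seeded synthetic-cohort generator
    produces longitudinal observation series with a controllable latent
    severity link, and a command-line interface binds scoring, validation and
    simulation to CSV/JSON files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    graphics,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
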