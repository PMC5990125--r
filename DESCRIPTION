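Package: mshybrid
Title: Human-Machine Hybrid Prognosis of Multiple Sclerosis Disease Course
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to combine crowd forecasts and machine-learning ensemble
    predictions of the relapsing-remitting to secondary-progressive transition
    in multiple sclerosis. Implements a patient-level modified leave-one-out
    ensemble protocol (one randomly chosen visit per training patient),
    aggregation of discrete human ratings into Singles, Pairs and Group
    forecasts, a concordance-ranked hybrid combiner that weights each agent by
    the agreement of its unitary predictions, and tie-aware ROC/AUC evaluation
    with percentile-bootstrap confidence intervals and paired AUC-difference
    tests. A synthetic cohort generator with a log-linear hazard on a latent
    risk reproduces the statistical structure the analysis assumes, so the
    full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cli,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
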