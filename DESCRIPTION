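Package: bayesaccrual
Title: Bayesian Accrual Prediction for Clinical Trials with Seasonal Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting participant accrual in clinical trials with a
    conjugate gamma-Poisson model and a seasonal extension in which each
    meteorological quarter (summer, fall, winter, spring) carries its own
    accrual rate. Provides prior elicitation from planned enrollment, exact
    conjugate posterior updates, posterior predictive simulation of total
    accrual to a horizon, pairwise and extreme-season posterior comparison
    probabilities, DIC model comparison, a rolling internal-prediction
    evaluation of forecast accuracy (RMSE, bias, SD), a synthetic accrual
    generator for validation, and readers/writers for delimited accrual
    tables plus an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    withr
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
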