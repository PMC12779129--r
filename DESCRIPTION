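Package: echodml
Title: Double Machine Learning for Echocardiogram Appointment Urgency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the effect of administrative, comorbidity
    and referral-diagnosis variables on the urgency of echocardiogram
    appointments using cross-fitted double machine learning for the
    partially linear model. Includes a synthetic electronic-health-record
    cohort generator with a known confounded causal structure, a uniform
    adapter over seven classification learner families for the nuisance
    models, Neyman-orthogonal residual-on-residual estimation with
    asymptotic inference, a repeated cross-validation prediction benchmark,
    and significance-ranked effect reporting with forest plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
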