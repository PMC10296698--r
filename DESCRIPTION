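Package: cogfrail
Title: Cognitive Aging Trajectories and Deficit-Accumulation Frailty in
    Survivorship Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal neuropsychological cohort
    studies that contrast cancer survivors with non-cancer controls.
    Provides control-referenced domain scoring with Box-Cox normalization,
    the deficit-accumulation frailty index (DAFI) with its missing-item and
    validity rules, a Bayesian varying-intercepts/varying-slopes growth
    model (quadratic age cohort trends, age-quartile practice-effect
    slopes, correlated person-level intercepts and slopes) fitted with
    JAGS, and post-hoc survivor-control gap curves over age with
    null-crossing detection. A synthetic cohort generator with known
    ground-truth parameters makes every stage testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
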