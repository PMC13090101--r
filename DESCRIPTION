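Package: nestfate
Title: Known-Fate Nest Survival with Time-Varying Weather Covariates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Interval-censored known-fate models of daily nest survival
    (Mayfield/Dinsmore-type) with time-varying weather covariates, fitted by
    maximum likelihood on the logit scale. Includes constrained AICc model
    selection over all hierarchical submodels of a global model with balance
    and uninformative-parameter screening, a bootstrap estimator of
    cumulative incubation-period survival with mean re-centering,
    fate-contingency statistics (Fisher exact tests and conditional
    maximum-likelihood odds ratios with Holm-Bonferroni adjustment), and a
    synthetic-data generator (AR(1) weather, nest observation process) for
    validation without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
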