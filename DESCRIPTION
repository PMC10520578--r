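Package: msmmed
Title: Marginal Structural Models for Income-Mediated Effects of
    Unemployment on Mental Health
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Causal mediation analysis of the short-term effect of
    unemployment on common mental disorder with household income as the
    mediator, for long-format longitudinal panels. Implements
    double-robust marginal structural models with stabilised inverse
    probability of treatment weights for the total effect, additional
    mediator (income-density) weights for the controlled direct effect,
    weighted pooled logistic outcome models with marginal
    standardisation to odds ratios and risk differences, population
    attributable fractions, percentage mediation with cluster bootstrap
    confidence intervals, multiple imputation by chained equations,
    transition (job loss/gain) and stratified analyses, and a seeded
    synthetic panel generator with brute-force oracle effects for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    nnet
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
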