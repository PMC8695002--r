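Package: difnet
Title: Differential Item Functioning Detection with Elastic Net Regularized
    Ordinal Logistic Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects uniform and nonuniform differential item functioning (DIF)
    in ordinal questionnaire items by comparing nested proportional-odds
    (cumulative logit) regression models, fitted either by maximum likelihood
    or by elastic net penalized likelihood with BIC-selected regularization
    strength along an automatically generated lambda path. Includes a graded
    response model simulator with controllable uniform DIF between a reference
    and a focal group, and a Monte Carlo engine estimating power and type I
    error of the tests over condition grids in small samples.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    parallel
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
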