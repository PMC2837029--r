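Package: offsetboost
Title: Permutation Test for the Additional Predictive Value of
    High-Dimensional Molecular Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tests whether a high-dimensional molecular block (p >> n)
    carries predictive value for a binary outcome beyond a small set of
    clinical covariates. A logistic regression model for the clinical
    covariates is fitted first and its linear predictor enters, as a
    fixed offset, a componentwise linear least squares boosting model
    for the molecular block. The average negative binomial
    log-likelihood of the combined fit is compared against its null
    distribution obtained by jointly permuting the rows of the
    molecular matrix while clinical covariates and outcome stay fixed.
    Includes AIC-based selection of the number of boosting iterations,
    a synthetic-data generator for power and type-I error studies, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    parallel,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
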