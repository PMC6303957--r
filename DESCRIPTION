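Package: priorconf
Title: Bayesian Adjustment for Unmeasured Confounding via Informative
    Priors on Confounder-Outcome Relations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sensitivity analysis of unmeasured confounding in
    linear exposure-outcome models. Implements closed-form omitted-variable
    bias expressions for the exposure-outcome and confounder-outcome
    estimators, a structural-equation synthetic data generator, a conjugate
    Gibbs sampler for Bayesian linear regression with an informative normal
    prior on the measured confounder-outcome coefficient, and a Monte-Carlo
    harness comparing frequentist and Bayesian estimators by bias, empirical
    standard deviation and mean squared error over a factorial scenario grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
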