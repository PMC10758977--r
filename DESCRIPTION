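Package: cmclogit
Title: Copula-Based Markov Chain Logistic Regression for Binomial Time Series
Version: 0.1.0
Authors@R: person("cmclogit", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits a first-order Markov model for binomial count time series
    in which the joint law of adjacent observations is built from a bivariate
    Archimedean copula (Clayton, Gumbel or Frank) over binomial-logistic
    margins. Regression coefficients and the copula dependence parameter are
    estimated simultaneously by maximum likelihood using discrete-margin
    rectangle probabilities. Includes a forward simulator driven by the
    inverse conditional copula, Kendall's tau calibration, one-step-ahead
    prediction with MSE/MAPE fit metrics, and a Monte-Carlo harness for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    optparse,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
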