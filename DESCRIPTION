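Package: halcausal
Title: Highly Adaptive Lasso Estimation and Causal Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Nonparametric regression with the highly adaptive lasso (HAL):
    empirical risk minimization over cadlag functions of bounded sectional
    variation norm, realized as an L1-penalized regression on tensor products
    of zero- or first-order spline basis functions with data-dependent knots.
    On top of the regression layer the package provides causal-effect
    estimation for a binary point treatment: targeted maximum likelihood
    estimation (TMLE) of the average treatment effect with efficient-
    influence-curve Wald inference, undersmoothed plug-in and inverse
    probability weighted estimators, nonparametric bootstrap confidence
    intervals with plateau penalty selection, and delta-method inference on
    the data-adaptive working model for conditional average treatment effect
    and dose-response curves. Synthetic data generators with known truth
    support simulation studies and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    Matrix,
    jsonlite,
    methods,
    sandwich,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
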