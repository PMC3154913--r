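Package: veloseg
Title: Velocity-Based Movement Modelling with Behavioural Change Points
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links irregular, noisy animal telemetry to gridded environmental
    covariates through a velocity-based regression with an unknown number of
    behavioural change points. A continuous-time correlated random walk
    (integrated Ornstein-Uhlenbeck velocity) is fitted by Kalman filtering and
    used to impute multiple regular-interval path realizations; velocity
    vectors are regressed on local covariate gradients (potential drivers of
    movement) with piecewise-constant coefficients, the partition being
    sampled by birth-death MCMC; covariate subsets are compared with a
    data-augmented deviance information criterion and fixed-K BIC; and
    population-level movement regimes are obtained by Gaussian-mixture
    clustering of pooled time-varying coefficients with classification-tree
    tests for subgroup differences. Includes a synthetic-data generator for
    gradient-driven tracks with Argos-like telemetry degradation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mclust,
    rpart,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
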