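Package: hybridcast
Title: Hybrid Mechanistic and Delay-Coordinate Modeling of Dynamical Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Joint state and parameter estimation for nonlinear dynamical
    systems with an unscented Kalman filter in which any subset of a
    mechanistic model's equations can be replaced by Takens delay-coordinate
    nonparametric advancement. Provides the fully parametric and fully
    nonparametric (k-nearest-neighbor direct prediction) baselines,
    Kalman-Takens denoising of training data, built-in simulators for the
    Lorenz-63 system, networks of Hindmarsh-Rose neurons and the discrete
    larvae-pupae-adult flour beetle map, and a Monte-Carlo experiment
    harness that scores forecasts by normalized root-mean-square error.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
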