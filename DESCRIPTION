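Package: hhnoise
Title: Stochastic Hodgkin-Huxley Simulators with Exact and Approximate
    Channel Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Side-by-side simulators for channel noise in Hodgkin-Huxley
    type membranes: exact Markov-chain channel-state kinetics via a
    Gillespie-type algorithm, and four stochastic differential equation
    approximations (white current noise, subunit noise with state-dependent
    covariance, voltage-clamp Ornstein-Uhlenbeck conductance noise, and the
    Fox-Lu system-size conductance noise model with matrix square-root
    diffusion).  Includes the closed-form time-resolved binomial moments of
    open-channel fractions along a fixed voltage path, replayed-trajectory
    ensemble statistics, spike detection, and interspike-interval statistics
    used to benchmark the approximations against the exact model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
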