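Package: tempocode
Title: Temporal-Coding Analysis of Interval-Timing Recurrent Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates and trains excitatory/inhibitory firing-rate recurrent
    neural networks (Dale's law, Softplus rates, backpropagation through time
    with Adam) on two-interval timing tasks in which the target interval is
    cued either by an analog context level or by distinct transient stimuli.
    Provides the population- and single-unit-level indices that distinguish
    temporal-scaling, absolute, and stimulus-specific timing codes
    (SSI_pop, SSI_unit, ASI), analytic prototype dynamics for validating the
    indices, behavioral scoring with generalization and noise-robustness
    sweeps, unit- and synapse-group-deletion experiments, and principal
    component state-space geometry with input/output subspace angles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
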