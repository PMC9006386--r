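Package: bimeta
Title: Bayesian Inference Modelling of Metamemory Confidence
Version: 0.1.0
Authors@R:
    person("bimeta", "maintainers", email = "maintainers@bimeta.dev", role = c("aut", "cre"))
Description: Tools for modelling metamemory monitoring as Bayesian inference.
    Confidence ratings in recall and recognition tasks are modelled as the
    posterior probability of success obtained by integrating trial-wise
    processing experience with prior beliefs about memory ability. The
    package simulates trial-level confidence/performance data on continuous
    or discrete rating scales, fits the model by maximum likelihood, and
    provides the reference models and metrics it is usually compared
    against: a restricted stochastic detection and retrieval model (SDRM),
    its criterion-rescaled two-condition variant, the meta-d' model with
    padding, Goodman-Kruskal gamma, and the trapezoidal type II AUROC.
    Experiment harnesses reproduce parameter-recovery and model
    cross-correlation simulation studies, leave-one-out cross-validated
    log-likelihoods, and blockwise refitting for detecting belief updating.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
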