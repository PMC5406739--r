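Package: mtmdecode
Title: Mixture-of-Trajectory-Models Decoding of Delayed Obstacle-Avoidance Reaches
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for decoding 2D hand trajectories from premotor cortex
    spike counts in a delayed obstacle-avoidance reaching task. Implements a
    mixture of trajectory models (MTM): one linear-Gaussian state-space model
    per movement regime (a target-direction by obstacle-opening pair),
    combined by recursive Bayesian estimation with probabilistic regime
    weights. Target direction and intended movement selection are decoded
    from delay-period activity with per-unit Gaussian naive Bayes and
    injected into the mixture as prior knowledge. Includes a synthetic
    session generator emulating the task geometry and the statistical
    assumptions of the decoder, population-vector and PCA analyses of
    planning activity, and evaluation utilities (trajectory correlation,
    mean squared error, task success rate, paired comparisons of decoders
    run with no prior, target-only prior, or combined prior).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
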