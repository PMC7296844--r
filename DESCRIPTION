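Package: rewardConn
Title: Reinforcement Learning and Effective Connectivity Modelling of a
    Probabilistic Reward Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end modelling pipeline for a 66-trial choice/no-choice
    probabilistic reward learning task and its fMRI correlates. Provides five
    Rescorla-Wagner reinforcement-learning models with maximum a posteriori
    fitting under empirical-Bayes group priors and integrated-BIC model
    comparison; behavioural statistics including a default Bayes factor for
    correlations; event-related GLM design construction with canonical HRF
    convolution and Monte-Carlo cluster-extent thresholds; a bilinear
    three-region dynamic causal model (visual cortex, ventral striatum, medial
    prefrontal cortex) with balloon-Windkessel haemodynamics inverted by
    variational Laplace; parametric-empirical-Bayes group inference with
    Bayesian model reduction, greedy pruning and Bayesian model averaging; and
    split-sample replication. A synthetic-cohort generator emulates the task
    design and plants parameter-symptom and connectivity-symptom effects so the
    whole pipeline can be exercised and validated without access-controlled
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
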