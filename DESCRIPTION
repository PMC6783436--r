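Package: loopbelief
Title: Simulation and Computational Modelling of Self-Related Belief Updating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how people update beliefs about their own
    (and others') abilities from trial-by-trial performance feedback.
    Generates feedback schedules and synthetic cohorts for the "learning of
    own performance" paradigm, defines a space of Rescorla-Wagner delta-rule
    learning models with condition-, valence- and agent-specific learning
    rates, fits them per subject by adaptive Markov chain Monte Carlo with
    convergence diagnostics, compares models with Pareto-smoothed
    importance-sampling leave-one-out cross-validation (PSIS-LOO) and
    random-effects Bayesian model selection (protected exceedance
    probabilities, Bayesian omnibus risk), and computes downstream
    group statistics: valence bias scores, repeated-measures ANOVAs,
    partial correlations with trait questionnaires, Fisher-z comparison of
    correlations, and posterior predictive checks.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
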