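Package: dualcontrol
Title: Simulation and Cross-Validation of Goal-Directed and Habitual Action Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the balance between goal-directed (model-based)
    and habitual (model-free) instrumental control. Provides a simulator for
    the two-step Markov sequential decision task with drifting Gaussian
    random-walk reward probabilities, a hybrid SARSA(lambda) model-based/
    model-free reinforcement-learning agent with a compiled choice likelihood,
    hierarchical empirical-Bayes parameter estimation (per-subject MAP under a
    group Gaussian prior, updated by Expectation-Maximization with Laplace
    uncertainties), schedule generation and scoring for a three-phase
    instrumental learning task with outcome devaluation (including the
    devaluation sensitivity index), the nonparametric behavioral statistics
    used with these tasks, cross-task Spearman correlations with one-tailed
    Bonferroni-corrected p-values, simple mediation with bias-corrected
    bootstrap confidence intervals, the Sobel test and the kappa-squared
    effect size, and a synthetic-cohort generator with a latent
    goal-directedness trait so the whole pipeline can be exercised end-to-end
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
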