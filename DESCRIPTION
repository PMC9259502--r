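Package: beadmodels
Title: Computational Models of Belief Updating in Beads Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative models and likelihood-based inversion for two beads-task
    paradigms: a costed Bayesian optimal-stopping model of the draws-to-decision
    task (Bayes-optimal belief updating, backward-induction action values under
    a per-draw sampling cost, softmax decision noise) and a retrospective-
    inference hidden Markov model of the 30-bead probability-estimation task
    (subjective reversal probability, tempered likelihood updating, online
    re-estimation of the reversal probability under a Beta prior over a trailing
    window, Beta-distributed slider responses). Also provides the standard
    behavioral indices (average draws to decision, jumping-to-conclusions bias,
    contrary updating), a simulate-then-refit parameter-recovery harness, a
    synthetic cohort simulator with planted exposure-mediator-outcome structure,
    and the epidemiological stage: exposure-outcome regressions (logistic,
    ordinal, multinomial, linear, with optional quadratic terms) and a
    counterfactual mediation estimator returning natural direct and indirect
    effect odds ratios and percent mediated.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
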