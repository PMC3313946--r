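Package: probetask
Title: Task-Set Creation, Monitoring and Selection Models of Executive Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and fitting toolkit for models of human executive
    control over behavioral strategies ("task sets"). Implements the PROBE
    model, in which a bounded monitoring buffer tracks the Bayesian
    reliability of a few candidate task sets against a null "no set matches"
    hypothesis, creates probe task sets by recombining strategies stored in
    long-term memory, and confirms or discards them by hypothesis testing.
    Also implements the rival MAX, FORGET and flat reinforcement-learning
    models behind the same agent interface, generators for the stochastic
    episode protocols used to study task-set switching (open, recurrent and
    color-cued sessions with 90/10 probabilistic feedback), one-step-ahead
    likelihood and least-squares fitting with BIC comparison, response
    classification, episode-aligned performance curves, the mutual-dependence
    (mutual information) statistic for successive correct decisions, and
    performance optimization over model parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
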