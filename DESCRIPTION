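Package: moltevol
Title: Phylogenetic Comparative Analysis of First-Year Flight-Feather Molt Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the evolutionary history of discrete
    life-history strategies on time-calibrated phylogenies, built around the
    analysis of wing flight-feather molt during the first year of life in
    birds. Provides maximum-likelihood fitting of k-state Mk (continuous-time
    Markov) models with equal-rates, symmetric and all-rates-different
    parameterizations and AICc model selection; exact marginal
    (empirical-Bayes) ancestral state reconstruction; Brownian-motion
    ancestral reconstruction of continuous traits via linear-time message
    passing; phylogenetic logistic regression of a binary strategy on
    continuous covariates under a two-state Markov switching model; a
    family-level dual-topology robustness analysis; and seeded simulators for
    birth-death trees and all trait models so every stage can be validated
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phytools,
    optparse
Config/testthat/edition: 3
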