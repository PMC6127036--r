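Package: priorlearn
Title: Learning a Concealed Base Rate from Unsupervised Perceptual Decisions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and maximum-likelihood fitting of a hierarchical
    Bayesian account of how observers learn a concealed base rate from their
    own perceptual decisions, without trial-by-trial feedback. Includes a
    bounded drift-diffusion model of choice and confidence with Fokker-Planck
    first-passage likelihoods, a counterfactual-confidence belief updater over
    discrete base rates together with rival update rules (choice-only,
    choice-confidence, empirical, mixture), a task generator for blocked
    random-dot-motion experiments, multi-start maximum-likelihood fitting with
    rank-preserving confidence transformation, belief-trajectory prediction,
    and the regression and lag diagnostics used to evaluate the fitted models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
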