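Package: cblearn
Title: Choice-Based Learning Models for Preference Judgment Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, maximum-likelihood fitting and comparison of
    choice-based learning (CBL) models of choice-induced preference change
    in internally guided decision making. Implements a family of
    Rescorla-Wagner-style value-update models for two-alternative
    preference judgments (chosen-only, rejected-only, shared and separate
    learning rates, experience-dependent inverse temperature, and value
    forgetting), a frequency-ratio control model without free parameters,
    trial-schedule construction for round-robin pairwise designs,
    synthetic choice-data generation, multi-start bounded likelihood
    optimization with AIC and normalized-likelihood model comparison,
    parameter- and model-recovery experiments, and reaction-time conflict
    and rating-consistency analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
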