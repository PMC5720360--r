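Package: nmari
Title: Network Meta-Analysis with Random Inconsistency Effects
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits contrast-based network meta-analysis models under the
    design-by-treatment interaction model with random inconsistency
    effects.  Provides three classical estimators of the between-study
    heterogeneity variance and the inconsistency variance: iterative
    Paule-Mandel type estimators built on monotone Q pivots, a
    DerSimonian-Laird method of moments, and (restricted) maximum
    likelihood.  Treatment effects are then estimated by generalized
    least squares with the variance components plugged in, for all
    pairwise comparisons.  Also included are Q-profile and
    profile-likelihood confidence intervals for the variance components,
    readers for arm-level and contrast-level data, and a Monte-Carlo
    simulation harness for studying estimator behaviour on synthetic
    networks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
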