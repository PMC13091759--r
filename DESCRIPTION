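Package: cuecomb
Title: Simulation and Analysis of Cue-Combination Psychophysics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A complete pipeline for two-interval forced-choice (2IFC)
    cue-combination experiments: generative ideal-observer simulation of
    depth discrimination from binocular disparity, relative size and an
    audio pitch cue; two-stage Bayesian psychometric-function fitting with
    a session-wise shared lapse rate; derived sensory-noise, weight and
    combination/re-weighting/incongruence indices with their
    maximum-likelihood optimal-integration predictions; group-level
    nonparametric hypothesis tests with principled exclusion rules;
    mixed-model repeatability (intraclass correlation) with parametric
    bootstrap, likelihood-ratio and permutation inference; and
    simulation-based power analysis for detecting group-level combination
    benefits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
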