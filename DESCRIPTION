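Package: circinf
Title: Circular Inference Models of Probabilistic Cue Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative Bayesian observer models for two-cue probabilistic
    decision tasks (the "fisher task"): Simple Bayes, Weighted Bayes, and the
    two circular-inference variants in which prior and/or sensory signals are
    reverberated with or without interference. Provides balanced trial-set
    construction, synthetic cohort simulation with trait questionnaires
    (AQ, PDI), per-participant least-squares fitting in logit space scored by
    BIC, fixed-effects and random-effects (variational Dirichlet) group model
    selection with exceedance probabilities, parameter- and model-recovery
    validation, and a trait-association statistical battery (linear
    mixed-effects variants, Kendall rank correlations, Mann-Whitney tests
    with common-language effect sizes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
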