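Package: metaspe
Title: Modelling Global Self-Performance Estimates from Local Confidence and Feedback
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative modelling and analysis of how observers form global
    self-performance estimates (SPEs) over short learning blocks of a
    two-alternative perceptual task. Provides a signal-detection perceptual
    module producing choices, confidence and response times; a Bayesian
    learning module that tracks a posterior belief over each task's accuracy,
    updated from external feedback or from local decision confidence as soft
    evidence; experiment design builders for three block-structured dot
    discrimination designs; type-2 signal-detection metrics including
    maximum-likelihood meta-d' and metacognitive efficiency (meta-d'/d') and
    AUROC2; a synthetic-cohort simulator with a trial/block CSV schema; and
    the accompanying statistical pipeline (subject exclusions, RT trimming,
    repeated-measures ANOVA with arcsine transform, JZS Bayes-factor paired
    t-tests, fixed-effect logistic regressions with BIC comparison and
    regressor orthogonalisation, block splits, recency regression and
    between-subject correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
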