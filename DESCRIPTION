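Package: trajmix
Title: Latent Class Trajectory Models with Structured Random-Effect Covariances
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maximum-likelihood estimation of latent class trajectory models
    (growth mixture models) for long-format repeated measures, under a ladder
    of seven within-class covariance structures ranging from fixed-effects-only
    homoscedastic to class-specific unrestricted random-quadratic covariance.
    Provides EM fitting with multiple starts, BIC class enumeration, posterior
    classification diagnostics (average posterior probability of assignment,
    odds of correct classification, mismatch, relative entropy), discrimination
    tools (Mahalanobis degrees of separation, posterior-weighted residual
    envelopes), weighted-kappa concordance, an eight-step model construction
    workflow, and a generative simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
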