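Package: bifdyn
Title: Bifurcation Dynamics of Single-Trial Neural Responses Around
    Perceptual Threshold
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Model-based analysis of trial-to-trial neural activity evoked by
    near-threshold stimuli. Fits competing generative models of single-trial
    activity as a function of stimulus strength (null, unimodal linear,
    unimodal non-linear, and a two-state bifurcation mixture) by maximum
    likelihood with block-respecting cross-validation, compares them at the
    group level with random-effects Bayesian model selection (protected
    exceedance probabilities), characterizes mean and across-trial
    variability response profiles, predicts conscious reports from the fitted
    mixture via trial-wise Bayes factors, and provides multivariate decoding
    (projected activity, temporal generalization) plus a synthetic-experiment
    generator emulating a near-threshold auditory detection design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
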