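Package: loalfuse
Title: Outcome-Adaptive LASSO Selection and Fused Smoothing of Longitudinal Treatment Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step dimension reduction of pooled treatment (propensity
    score) models for marginal structural models with time-varying binary
    treatments. Step one selects confounders into time-specific treatment
    models with a longitudinal outcome-adaptive LASSO whose per-coefficient
    penalties are driven by working structural-model coefficients estimated
    through sequential g-computation; the regularisation parameter is tuned
    by a longitudinal weighted-absolute-mean-difference covariate balance
    metric. Step two smooths the selected model over time with an adaptive
    fused LASSO on a user-defined coefficient graph, tuned by BIC. Also
    provides inverse-probability-of-treatment weighting with stabilised
    weights and robust sandwich variances, sequential g-computation of
    marginal structural model parameters, an m-out-of-n bootstrap hook,
    synthetic longitudinal data-generating processes, and a replicated
    simulation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
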