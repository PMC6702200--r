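Package: pvtvuln
Title: Classifying Attentional Vulnerability to Sleep Deprivation from
    Baseline Psychomotor Vigilance Test Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting an individual's relative attentional
    vulnerability to total sleep deprivation from a single baseline 10-minute
    Psychomotor Vigilance Test (PVT). Provides a trial-level synthetic cohort
    generator with trait-like individual differences in lapse propensity and
    homeostatic sleep-pressure response, session validity screening, a
    parameterized catalog of per-session reaction-time summary measures,
    intraclass-correlation feature screening via linear mixed models, a
    cost-sensitive three-class linear discriminant classifier, wrapper-based
    best-first feature-subset search under repeated stratified k-fold
    cross-validation, and the associated performance metrics (accuracy,
    Cohen's kappa, sensitivity, specificity, predictive values, modal group
    assignment, and group lapse time courses).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    yaml,
    knitr
VignetteBuilder: knitr
Config/testthat/edition: 3
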