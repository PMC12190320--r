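Package: dmprog
Title: Obesity-Diabetes Progression Models with Nonlinear Mixed-Effects
    Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A family of composable glucose-insulin-beta-cell ordinary
    differential equation models of long-term type 2 diabetes progression,
    driven by time-varying adiposity (percent body fat) and age.  Provides a
    recalibrated three-variable base model and nine mechanistic ingredients
    (adiposity- and age-dependent insulin sensitivity, insulin-induced insulin
    resistance, dynamic hepatic glucose production, saturating insulin
    clearance, calcium-mediated dynamic beta-cell secretory capacity with
    glucotoxicity, and lipotoxic or biphasic lipid effects on beta-cell mass
    and function), together with stochastic-approximation EM (SAEM) population
    fitting, importance-sampling marginal likelihood and BIC, greedy
    generational model selection, k-fold cross-validation for population
    models, extended FAST variance-based sensitivity analysis, and a synthetic
    longitudinal cohort generator emulating a biennial-visit progression study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
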