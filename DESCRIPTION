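Package: summarymr
Title: Two-Sample Mendelian Randomization with Summarized Genetic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Causal-effect estimation from genome-wide association study
    summary statistics using genetic variants as instrumental variables.
    Implements the inverse-variance weighted (IVW), MR-Egger, simple and
    weighted median, and robust (Tukey bisquare) estimators with fixed and
    multiplicative random-effects variance models, variant orientation with
    respect to the risk-factor-increasing allele, regression diagnostics
    (instrument-strength I-squared, heterogeneity Q, Cook's distance,
    studentized residuals, leave-one-out analysis), a generalized
    least-squares extension for correlated variants, and a scenario
    simulator for studying directional pleiotropy and violations of the
    InSIDE assumption.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    metafor,
    optparse
Config/testthat/edition: 3
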