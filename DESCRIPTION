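Package: rsmval
Title: Box-Behnken Response Surfaces and 2002/657/EC Validation for
    Multi-Residue LC-MS/MS Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and validating targeted multi-residue
    LC-MS/MS quantification methods. Generates three-factor Box-Behnken
    designs with coded/actual unit mapping, fits second-order response
    surfaces by ordinary least squares with a Type-III ANOVA including the
    lack-of-fit versus pure-error split and adequacy diagnostics (R-squared,
    adjusted and predicted R-squared via PRESS, adequate precision), locates
    and classifies stationary points, and maximizes the fitted surface
    exactly over the coded experimental cube. Implements the European
    Commission Decision 2002/657/EC validation statistics used for veterinary
    drug residues: decision limit CCalpha, detection capability CCbeta,
    matrix-effect classification from calibration slope ratios, limit of
    quantification from signal-to-noise, compliant-analyte counts, and
    intra-/inter-day precision summaries. A seeded synthetic-data generator
    emulates spiked-recovery experiments across the design so every pipeline
    stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
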