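Package: mrmediate
Title: Two-Sample Mendelian Randomization and Two-Step Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics and for two-step mediation MR of the form
    exposure -> mediator -> outcome. Implements instrument selection with
    greedy LD clumping, allele harmonization, the inverse-variance weighted
    estimator with Cochran's Q-driven fixed/multiplicative-random-effects
    choice, MR-Egger regression with its intercept test for directional
    pleiotropy, the weighted-median estimator with a parametric bootstrap,
    an MR-PRESSO-style global/outlier/distortion test, Benjamini-Hochberg
    false-discovery-rate control over screen families, and
    product-of-coefficients mediation effects with proportions mediated.
    Ships a synthetic three-trait GWAS summary-statistics generator with
    known causal structure for calibration and parameter-recovery studies,
    plus packaged reference tables from a published BMI -> blood metabolite
    -> cholelithiasis screen for arithmetic verification.
License: MIT
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
    metafor,
    withr
Config/testthat/edition: 3
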