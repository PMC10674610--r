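Package: mrsuite
Title: Two-Sample Mendelian Randomization with Mediation and Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: allele harmonization and instrument selection,
    univariable estimators (Wald ratio, inverse-variance weighted, MR-Egger,
    weighted median, weighted mode, MR-PRESSO) with heterogeneity, instrument
    strength and Steiger directionality diagnostics; multivariable MR
    (MV-IVW, MVMR-Egger, MVMR-median, MVMR-Lasso) with conditional F
    statistics; two-step MR mediation with delta-method confidence intervals
    for mediation proportions; fixed/random-effect meta-analysis across
    outcome cohorts; a configuration-driven analysis pipeline with
    sensitivity-gated causal calls; and a generative simulator of two-sample
    GWAS summary statistics with known causal structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
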