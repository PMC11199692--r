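Package: mrmediate
Title: Two-Sample Mendelian Randomization with Two-Step Mediation Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) on GWAS
    summary statistics: instrument selection (genome-wide significance,
    greedy LD clumping, F-statistic screening, confounder exclusion),
    allele harmonization with palindromic-SNP handling, five causal-effect
    estimators (inverse-variance weighted, MR-Egger, weighted median,
    weighted and simple mode), heterogeneity and horizontal-pleiotropy
    diagnostics (Cochran's Q, Egger intercept, leave-one-out), a
    bidirectional exposure-screening cascade, and two-step MR mediation
    that decomposes a total causal effect into direct and mediated parts
    with the mediated proportion. Includes a summary-level GWAS simulator
    with known causal truth for calibration and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
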