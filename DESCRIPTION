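Package: mrmediate
Title: Two-Step Two-Sample Mendelian Randomization with Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) screens and
    two-step mediation analysis from GWAS summary statistics. Provides
    instrument selection (p-value threshold, greedy LD clumping, F-statistic
    filter), allele harmonization with palindromic/ambiguous SNP handling, a
    suite of causal estimators (Wald ratio, fixed- and multiplicative-random-
    effects IVW, MR-Egger, weighted median, simple and weighted mode, and a
    Bayesian weighted estimator robust to horizontal pleiotropy), sensitivity
    diagnostics (Cochran's Q, Egger intercept test, MR-PRESSO global, outlier
    and distortion tests, leave-one-out), reverse-MR screening, and
    product-method mediation decomposition with delta-method confidence
    intervals. A synthetic three-trait GWAS generator with known causal
    structure supports validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
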