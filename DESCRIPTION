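Package: mrpipe
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization with published GWAS
    summary statistics: reading and harmonizing summary-association tables onto
    a common effect-allele orientation, instrument selection (genome-wide
    significance filtering, greedy linkage-disequilibrium pruning, imputation
    quality filtering), Wald-ratio, inverse-variance-weighted and weighted-median
    causal estimation with Cochran's Q / I-squared heterogeneity diagnostics, an
    MR-PRESSO style residual-sum-of-squares global, per-variant outlier and
    distortion test, a synthetic summary-statistics generator with known causal
    truth and configurable pleiotropy, and a pipeline orchestrating the full
    analysis across outcome strata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
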