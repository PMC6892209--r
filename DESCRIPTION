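Package: mrcausal
Title: Two-Sample Mendelian Randomization with GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: reading, validating and harmonizing summary-statistic
    tables onto a common effect allele; instrument selection with distance
    pruning and pleiotropy filters; instrument-strength diagnostics (variance
    explained and F statistics); inverse-variance-weighted, MR-Egger and
    weighted-median causal estimators; heterogeneity, leave-one-out,
    MR-PRESSO outlier resampling and funnel diagnostics; random-effects
    meta-analysis of published odds ratios; analytic power calculation for a
    binary outcome; and a synthetic two-sample summary-statistics generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
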