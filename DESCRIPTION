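Package: mrscreen
Title: Two-Sample Mendelian Randomization Screening of GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) with GWAS
    summary statistics: instrument selection (p-value filtering, greedy LD
    clumping, F-statistic instrument strength), allele harmonization with
    palindrome removal and strand-flip rescue, causal estimators (Wald ratio,
    fixed/random-effects inverse-variance weighted, MR-Egger, weighted median
    with parametric-bootstrap standard errors, maximum likelihood), and
    sensitivity diagnostics (Cochran's Q, Egger intercept pleiotropy test,
    MR-PRESSO global/outlier/distortion tests, scatter and funnel plot data).
    Includes a synthetic summary-statistics generator with known ground truth
    calibrated to a microbiome-abundance exposure cohort and a binary-disease
    outcome cohort, and a pipeline for screening many exposures against one
    outcome.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    yaml,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
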