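Package: vitdmr
Title: Two-Sample Mendelian Randomization for Genetically Lowered
    Vitamin D and Multiple Sclerosis Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the effect of genetically lowered
    25-hydroxyvitamin D (25OHD) on the odds of multiple sclerosis from
    summary-statistic instruments: per-SNP Wald ratios,
    inverse-variance-weighted fixed-effects pooling,
    DerSimonian-Laird random effects, Cochran's Q and I-squared
    heterogeneity with test-based confidence intervals, sensitivity and
    pathway-stratified reruns, instrument-strength validation on
    individual-level cohorts (allele scores, F-statistics, rank trend
    tests, pairwise linkage disequilibrium, Hardy-Weinberg and ancestry
    checks), clinical-threshold back-transformation, and a seeded
    generator of genotype-biomarker-disease cohorts for parameter
    recovery and calibration studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite
Config/testthat/edition: 3
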