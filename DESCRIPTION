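Package: organoidCIN
Title: Chromosomal Instability Analysis for Tumour Organoid Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative characterization of chromosomal instability in
    patient-derived tumour organoid cohorts profiled by shallow whole-genome
    and single-cell DNA sequencing. Provides compositional-geometry analysis
    of copy-number signature activities (zero imputation, CLR/ILR transforms,
    Aitchison-distance clustering, a log-ratio Wald test for differential
    signature abundance), an excess-variance chi-squared statistic for
    single-cell copy-number subclonal heterogeneity with clade detection and
    Holm-adjusted per-bin clade comparisons, gene-level copy-number/expression
    concordance metrics with median-of-ratios normalization, and a robust
    dose-response pipeline (control-median standardization, MM-type polynomial
    outlier exclusion, five-parameter log-logistic fitting, normalized
    log-dose AUC). Synthetic-data generators emulate each input type with
    known ground truth so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    minpack.lm,
    mclust,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
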