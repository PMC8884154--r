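Package: scpv
Title: Downstream Analysis of True Single-Cell Proteomes and Their Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the downstream quantitative analysis
    used for drug-perturbed single-cell proteome cohorts measured one cell per
    LC-MS run: quality-control filtering of cells and protein groups,
    median-ratio per-cell normalization, missing-not-at-random imputation from a
    downshifted normal distribution, gene-set cell-cycle phase scoring with ROC
    evaluation, SAM-statistic differential expression with permutation-based
    false discovery rate control, coefficient-of-variation and core-proteome
    analysis, Poisson shot-noise dropout modelling, and harmonized comparison of
    proteome intensity matrices with single-cell RNA count matrices. A synthetic
    data generator emulates the statistical structure of such cohorts (log-normal
    abundances over four decades, stage-dependent cell size factors,
    multiplicative measurement noise, abundance-dependent detection, and
    shot-noise dominated RNA counts) and retains the ground truth needed for
    parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
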