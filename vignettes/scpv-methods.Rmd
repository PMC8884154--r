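---
title: "Models and methods behind scpv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scpv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scpv)
```

`scpv` analyses cell × protein-group intensity matrices from true
single-cell proteomics — one FACS-sorted cell measured per LC–MS run — and
compares them with single-cell RNA count matrices. This vignette explains
the statistical models the package implements, the defaults and why they
are what they are, what the synthetic generator does and does not emulate,
and the numerical choices a maintainer should know about.

## The data model

An `intensity_matrix` holds strictly positive linear-scale intensities with
`NA` for "not quantified". This asymmetry with RNA counts is fundamental:
a DIA search engine either quantifies a protein group in a cell or reports
nothing, and nothing is *not* zero — low-abundance proteins drop out
preferentially (missing not at random, MNAR). RNA count matrices are the
opposite: a zero is an observed outcome of molecule sampling. Every
function in the package is explicit about which convention it uses, and
readers treat zeros in proteomics tables as missing by default because
search output never contains true zero intensities.

## The synthetic cohort generator

`generate_proteome_cohort()` draws

\[ I_{cp} = B_p \cdot s_c \cdot 2^{e_{p,\mathrm{stage}(c)}} \cdot \eta_{cp},
   \qquad \log_{10} B_p \sim N(4, 1), \]

with \(s_c\) the stage size factor (defaults G1 = 1, G1/S = 1.4, G2 = G2/M
= 1.8 — arrested G2 cells hold roughly 1.8-fold more protein than G1
cells), \(e\) the marker log2 effects, and \(\eta\) multiplicative
log-normal noise with `noise_cv = 0.3`, the median per-protein CV such
cohorts exhibit (`sdlog = sqrt(log(1 + cv²))`, unit mean). An entry is then
*detected* with probability

\[ p_{\mathrm{det}} = \mathrm{logit}^{-1}\big(k\,(\log_{10} I - m)\big), \]

the simplest monotone MNAR curve. The default midpoint `m = 4.15` sits at
the population mean log10 intensity, so average completeness is ~0.5
(about half of the protein space is quantified per cell, matching the
working regime of these experiments); the slope `k = 1.5` per decade
produces the characteristic bimodality of completeness at low abundance
while keeping detection near-certain in the top decade. The missingness
curve of real data is not parametrically characterized; the logistic form
is a stand-in and is labelled as such wherever it matters.

Choices worth spelling out:

* **Cell sizes carry no extra jitter.** Every cell receives exactly its
  stage's size factor, so the within-stage per-protein CV is governed by
  `noise_cv` alone and the generator calibration (median CV 0.3 within the
  baseline stage) is directly checkable. Between-stage spread then comes
  from the size factors, as in the arrested populations themselves.
* **Marker abundances live in the upper half of the dynamic range.** Marker
  panels are, by the way they are selected (top differentially expressed
  proteins *filtered for quantification in at least 70 % of cells*), never
  drawn from the poorly detected tail. The generator reflects marker base
  abundances above the population mean (half-normal) to honour that.
* **Marker effects default to +2.5 log2** (~5.7-fold) in the marked stage.
  This is the order of change reported for the most differentially
  expressed cell-cycle proteins under thymidine/nocodazole arrest, and it
  is the calibration under which the end-to-end recovery property — the
  G2/M score separates arrested transitions with AUC ≥ 0.9 despite
  zero-filled dropout — holds. With ~50 % completeness, a zero-filled
  missing marker swings a per-cell set mean by ~9 natural-log units, so
  modest (two-fold) effects are genuinely not recoverable at panel size 12;
  the default reflects markers as they are in practice: abundant and
  strongly regulated.
* **Default cohort size** is 120 cells per stage × 4 stages × 2 000
  proteins — the order of the real cohorts (several hundred cells, ~2 000–
  2 500 protein groups) while keeping every test and the acceptance script
  in seconds on one CPU.
* All randomness flows from one seed through fixed sub-streams (abundances,
  noise, detection), so cohorts are bit-reproducible and extending one
  dimension does not reshuffle another's draws.

`generate_rna_counts()` emulates two protocols. Under `umi`, counts are
Poisson with per-gene means drawn log-normally (`10^N(-0.3, 1)`: ~60 % of
genes below one copy per cell — the shot-noise regime, where detection
follows `1 − exp(−mean)` exactly). Under `full_length`, Gamma–Poisson
overdispersion (amplification) is followed by the saturating transform
`round(K·x/(x+K))`, which reproduces the saturation-sequencing signature
without modelling PCR explicitly. `protein_rna_coupling` correlates gene
log-means with protein log-abundances so cross-modal analyses have shared
structure to find.

**What the generator does not emulate:** peptide/spectrum-level effects,
retention time, batch structure beyond an optional per-batch scalar offset,
biological co-regulation between proteins, and cell-to-cell size variation
within a stage. Passing tests therefore demonstrate correctness of the
estimators under the stated generative model, not performance on any
particular real dataset.

## QC, normalization, imputation

The funnel is applied in a fixed order — cells (≥ 600 quantified proteins,
inclusive), then protein completeness (≥ 15 % of the *remaining* cells),
then protein CV (< 0.75, strict, on linear intensities) — and is idempotent
on its own output. CVs are computed on the linear scale (sample SD/mean
over non-missing entries); proteins with fewer than two observations have
no defined CV and are dropped by the CV filter.

Per-cell normalization uses one factor per cell against a per-protein
median pseudo-reference. The factor is computed as
`exp(median(log(I_cp / ref_p)))` — the median *log* fold-change — rather
than the median of linear ratios: the two differ whenever a cell shares an
even number of proteins with the reference, and only the log-scale median
guarantees the postcondition that every cell's median log-ratio to the
reference is exactly zero afterwards. This median-ratio scheme is the
package's stand-in for search-engine-internal normalization, which is not
re-implementable from its description; the substitution is deliberate and
affects only the estimated per-cell scale. Normalization never creates or
destroys missingness. The cell-size estimate (`total_signal_per_cell`)
sums *raw* intensities by default, since normalization is designed to
cancel exactly the size signal; a flag allows post-normalization sums.

Imputation draws each missing entry of the log-transformed matrix from
`N(μ − 1.8 σ, (0.3 σ)²)` with moments computed per cell (each sample
imputed from its own observed distribution, the column-wise convention of
the Perseus ecosystem) or globally. Cells with fewer than two observed
values fall back to global moments with a log message. Width 0.3 and
downshift 1.8 are the standard parameters of this MNAR model; imputation
is seeded and reproducible.

## Cell-cycle scoring

Scoring follows the score_genes approach: all genes are placed into 25
equal-frequency bins by mean expression; for each marker, 50 reference
genes are sampled (seeded, without replacement) from the marker's bin,
excluding markers; the per-cell score is mean(marker expression) −
mean(reference expression). Bin count and controls-per-gene are not
specified by the upstream method description, so the defaults (25/50, the
conventional values) are exposed and the sampling is seeded to make any
choice auditable. Equal-frequency (rank-based) binning is used because the
abundance distribution is heavily skewed; ties are broken deterministically
by first occurrence. Input must be complete: in this workflow cells are
filtered, log(1+x)-transformed and missing values are **replaced by
zeros** — not imputed — before scoring, and the scoring matrix is the
completeness-filtered one *before* the CV filter, because the CV cut would
remove exactly the strongly regulated marker proteins. Phase calls are the
argmax of the three scores with ties broken in fixed order (G1, S, G2M).
ROC curves sweep the score threshold; the AUC is the Mann–Whitney
`U/(n₊·n₋)` with ties counting one half, which equals the trapezoidal area
under the tie-aware curve.

## Differential expression

The SAM statistic is `d = (mean_a − mean_b)/(s + s₀)` with `s` the
classical pooled two-sample standard error, so `s₀ = 0` recovers the
pooled-variance Student t exactly. The default `s₀ = 0.3` follows the
stated analysis parameters; a value of 0.2 also appears in the figure
annotations of the same analysis, and the parameter is exposed rather than
resolved. Proteins enter testing when quantified in ≥ 50 % of the cells of
*at least one* group; proteins with fewer than two observations in either
group are untested (never given p = 0 from zero variance). Q-values are
Benjamini–Hochberg over tested proteins.

Permutation FDR shuffles group labels (default 250 shuffles; all distinct
assignments are enumerated exactly when fewer than that): for candidate
threshold τ on |d|, `FDR(τ)` is the mean permutation count of |d*| ≥ τ over
the observed count, and the smallest τ with FDR ≤ 0.05 is selected. With no
admissible τ nothing is flagged. Pooled variance is the default (classical
SAM); Welch is available by flag.

Fragment-level profiles re-estimate one median-ratio factor per cell on the
cells × fragments matrix, log2-transform, and summarize per (protein,
fragment, group) as median, quartiles and 1.5×IQR whiskers clipped to the
data — the boxplot convention of the corresponding figures.

## Variability and dropout

The core proteome is the k = 200 lowest-CV proteins among those quantified
in ≥ 70 % of all retained cells — including perturbed populations, since
stability under perturbation is the point of the statistic. Ties are broken
by protein identifier; if fewer than k are eligible all are returned with a
warning. Whether CVs should be computed on raw or normalized intensities is
not specified upstream; the default is normalized (the pipeline wires the
normalized matrix in), with the function usable on either.

Completeness profiles report, per feature, the observed detection fraction
and the Poisson expectation `1 − exp(−mean)`. For RNA this is exact under
the UMI model and the package's UMI simulation matches it gene-by-gene
within binomial error. For proteomics the curve is emitted on a
pseudo-count scale for plotting parity only — intensities are not molecule
counts, and the profile documents this rather than pretending otherwise.

RNA CVs are computed with zeros included (single-cell RNA-seq treated as
not zero-inflated), proteomics CVs with missing values excluded; this
asymmetry mirrors the two technologies' noise models and is what makes the
cross-modal CV comparison meaningful: genes below one copy per cell are
shot-noise dominated (CV ≥ 1/√mean) while protein CVs stay near the
measurement floor across the dynamic range.

## Cross-modal comparison

Gene harmonization is by uppercased, trimmed symbol, intersected across
technologies and sorted alphabetically; all downstream matrices are aligned
to that order. Cell–cell Pearson correlations use pairwise-complete
observations for proteomics (pairs with < 3 shared observations are
skipped and counted) and zeros-as-values for RNA. Two distinct scaling
recipes are kept deliberately separate, matching the two analysis paths:
scaling each RNA cell to the dataset's mean total ("mean cell size") before
correlation analyses, and scaling to 10⁶ before PCA. PCA is a mean-centred
SVD with components ordered by explained variance and the sign of each
component fixed so its largest-magnitude loading is positive — a pure
convention that makes embeddings platform-reproducible.

## Pipeline, sizes and determinism

`run_pipeline()` executes simulate → QC → normalize → impute → score → DE →
variability → cross-modal with one seed, per-stage sub-seeds, a JSON run
report carrying every filter count, and TSV outputs consumable by any
plotting tool. Unknown configuration keys are rejected so typos cannot
silently fall back to defaults. Identical configuration and seed give
byte-identical outputs.

Problem sizes used in the shipped tests (a deliberate choice of the
package, to keep the full suite under a minute while leaving Monte-Carlo
margins comfortable): cohorts of 100–480 cells × 300–2 000 proteins,
permutation counts of 40–250, and 10–20 replicate null simulations for the
FDR-control property. The acceptance script uses the full default cohort
(480 × 2 000).

## Known limitations

* The logistic detection model and the saturating full-length transform are
  stand-ins for mechanisms the underlying study does not characterize
  parametrically.
* The permutation-FDR "smallest admissible τ" rule can flag MNAR-induced
  distributional differences between groups (detection bias shifts observed
  means even without a true abundance effect); this is a property of the
  method, visible in the synthetic cohorts precisely because their ground
  truth is known.
* No batch-effect correction beyond per-cell factors, no peptide-level
  inference, no spectra: the package starts where search-engine output
  ends.
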