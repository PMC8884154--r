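# scpv — downstream analysis of true single-cell proteomes

`scpv` re-implements, as a tested and reusable R pipeline, the downstream
quantitative analysis used for *true single-cell proteomics* cohorts: one
cell sorted, prepared and injected per LC–MS run, quantified by a DIA search
engine into a cell × protein-group intensity matrix in which an absent entry
means "not quantified" — never zero. It is written for computational
proteomics researchers who want the complete analysis chain — QC,
normalization, imputation, cell-cycle scoring, differential expression,
variability and cross-omics comparison — as composable, unit-tested
functions rather than a notebook.

## What it computes

Given a cohort of drug-arrested single cells (G1, G1/S, G2, G2/M enriched):

* **QC funnel** — cells with ≥ 600 quantified proteins, proteins quantified
  in ≥ 15 % of cells, then proteins with linear-scale CV < 0.75.
* **Cell size** — total summed raw intensity per cell; G2-arrested cells
  carry ≈ 1.8× the protein signal of G1 cells.
* **Normalization** — one factor per cell,
  `f_c = exp( median_p log( I_cp / ref_p ) )` against a per-protein median
  pseudo-reference (fold-change-based normalization).
* **Imputation** — missing values drawn from
  `N( μ_obs − 1.8 σ_obs, (0.3 σ_obs)² )`, the downshifted-normal model of
  missing-not-at-random dropout.
* **Cell-cycle scoring** — per-cell gene-set score
  `s = mean(set) − mean(reference)` with the reference sampled from
  expression-matched bins (25 bins, 50 controls/gene), argmax phase call,
  and ROC/AUC evaluation where `AUC = U / (n₊ n₋)` (Mann–Whitney, ties ½).
* **Differential expression** — two-sided unpaired t-tests with
  Benjamini–Hochberg q-values, the SAM statistic
  `d = Δmean / (s_pooled + s₀)` with `s₀ = 0.3`, and a permutation-based
  FDR threshold on |d|.
* **Variability** — per-protein CV = SD/mean on linear intensities; the
  *core proteome* = the 200 lowest-CV proteins among those quantified in
  ≥ 70 % of cells; completeness profiles against the Poisson shot-noise
  expectation `1 − exp(−x)`.
* **Cross-modal comparison** — case-insensitive gene intersection with
  single-cell RNA count matrices (UMI and full-length protocols), pairwise
  cell–cell Pearson correlations (missing excluded for protein, zeros kept
  for RNA), CV–CV correlation, and mean-centred SVD embeddings.

A first-class synthetic-data module generates cohorts with the statistical
structure these analyses assume — log-normal abundances over ~4 decades,
stage size factors (G2 = 1.8 × G1), multiplicative noise with median CV 0.3,
logistic abundance-dependent dropout at ~50 % average completeness, marker
fold-changes, and shot-noise RNA counts — and retains the ground truth so
every estimator can be tested against known parameters.

## Worked example

```r
library(scpv)

cfg <- pipeline_config(seed = 7)
cfg$simulate$n_cells_per_stage <- c(G1 = 60, G1S = 60, G2 = 60, G2M = 60)
cfg$simulate$n_proteins <- 1200
cfg$diffexp$n_permutations <- 100
report <- run_pipeline(cfg, outdir = "scpv_demo")
str(report$stages$qc)
#> $ cells   : Named int [1:2] 240 147        # before / after >=600-protein filter
#> $ proteins: Named int [1:3] 1200 1068 1056 # before / >=15% complete / CV < 0.75
report$stages$cellcycle$auc_g2m
#> [1] 0.974
report$stages$variability[c("core_size", "median_cv")]
#> $core_size: 200      $median_cv: 0.297
```

The run directory contains the raw and normalized matrices, the per-cell
size table, phase scores with ROC curve, the volcano table with permutation
FDR flags, `core_proteome.tsv`, completeness and CV–mean profiles, the
shared-gene RNA comparison, and `run_report.json` with every filter count
and seed. The numbers above read as: of 240 simulated cells, 147 clear the
600-protein bar at ~50 % completeness; the G2/M marker score separates
arrested transitions with AUC 0.97; the 200-member core proteome sits at a
median CV of ~0.3.

Module functions are equally usable on real exported tables:
`read_intensity_table()` (wide or long DIA-NN-style protein-group reports),
`read_mtx_counts()` (Matrix Market + features/barcodes), then the same QC /
DE / variability calls.

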