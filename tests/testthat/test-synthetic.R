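test_that("empty configurations produce empty but valid output", {
  co <- generate_proteome_cohort(proteome_sim_config(
    n_cells_per_stage = c(G1 = 0, G2 = 0), n_proteins = 50, seed = 1))
  expect_equal(nrow(co$intensities), 0)
  expect_equal(ncol(co$intensities), 50)
  expect_equal(nrow(co$cells), 0)
})

test_that("a saturating detection curve yields 100% completeness", {
  co <- generate_proteome_cohort(proteome_sim_config(
    n_cells_per_stage = c(G1 = 20), n_proteins = 100,
    detection_midpoint = -20, detection_slope = 1e6, seed = 3))
  expect_equal(completeness(co$intensities), 1)
})

test_that("default noise calibration gives median per-protein CV near 0.3", {
  co <- generate_proteome_cohort(proteome_sim_config(
    n_cells_per_stage = c(G1 = 100), n_proteins = 2000, seed = 5))
  cvs <- brute_force_cv(co$intensities)
  expect_lt(abs(median(cvs, na.rm = TRUE) - 0.3), 0.05)
})

test_that("identical seed and config give bit-identical cohorts", {
  cfg <- proteome_sim_config(n_cells_per_stage = c(G1 = 15, G2 = 15),
                             n_proteins = 120, seed = 99)
  a <- generate_proteome_cohort(cfg)
  b <- generate_proteome_cohort(cfg)
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$truth$base_abundance_log10, b$truth$base_abundance_log10)
})

test_that("detection completeness increases with true intensity", {
  co <- generate_proteome_cohort(proteome_sim_config(
    n_cells_per_stage = c(G1 = 80), n_proteins = 1500, seed = 7))
  true_log <- co$truth$base_abundance_log10
  comp <- colMeans(!is.na(co$intensities))
  bins <- cut(true_log, breaks = quantile(true_log, seq(0, 1, 0.1)),
              include.lowest = TRUE)
  binned <- tapply(comp, bins, mean)
  expect_gt(binned[[10]], binned[[1]])
  expect_gt(cor(as.numeric(binned), seq_along(binned), method = "spearman"), 0.9)
})

test_that("summed per-cell intensity recovers the configured size-factor ratio", {
  co <- small_cohort(seed = 11, cells = 50, proteins = 800)
  ts <- total_signal_per_cell(co$intensities)
  ratio <- median(ts[co$cells$stage == "G2"]) / median(ts[co$cells$stage == "G1"])
  expect_lt(abs(ratio / 1.8 - 1), 0.10)
})

test_that("marker effects shift marker proteins in their stage", {
  co <- small_cohort(seed = 13, cells = 40, proteins = 100)
  m <- co$intensities
  g2m_gene <- "TOP2A"
  eff <- default_marker_effects()
  target <- eff$log2fc[eff$gene == g2m_gene & eff$stage == "G2"]
  j <- which(toupper(genes(m)) == g2m_gene)
  in_g2 <- co$cells$stage == "G2"
  lfc <- log2(mean(m[in_g2, j], na.rm = TRUE) / mean(m[!in_g2, j], na.rm = TRUE))
  # expected: configured marker effect plus the size-factor log2(1.8)
  expect_lt(abs(lfc - (target + log2(1.8))), 0.5)
})

test_that("fragment report with one peptide, one fragment, no noise is the protein matrix", {
  co <- small_cohort(seed = 17, cells = 10, proteins = 30)
  rep1 <- generate_fragment_report(co$intensities, 1, 1, noise_cv = 0)
  m <- co$intensities
  obs <- which(!is.na(unclass(m)), arr.ind = TRUE)
  expect_equal(nrow(rep1), nrow(obs))
  expect_equal(rep1$intensity,
               unclass(m)[cbind(match(rep1$cell_id, rownames(m)),
                                match(rep1$protein_group, colnames(m)))])
})

test_that("fragment log-ratios are constant across cells when noise is zero", {
  co <- small_cohort(seed = 19, cells = 12, proteins = 10)
  rep0 <- generate_fragment_report(co$intensities, 2, 3, noise_cv = 0)
  one_pep <- rep0[rep0$peptide == rep0$peptide[1], ]
  wide <- reshape(one_pep[c("cell_id", "fragment", "intensity")],
                  idvar = "cell_id", timevar = "fragment", direction = "wide")
  ratios <- log2(wide[[2]] / wide[[3]])
  expect_lt(diff(range(ratios)), 1e-9)
})

test_that("fragment variance decomposes into protein and fragment noise", {
  co <- generate_proteome_cohort(proteome_sim_config(
    n_cells_per_stage = c(G1 = 150), n_proteins = 60,
    detection_midpoint = -20, detection_slope = 1e6, seed = 23))
  frag_cv <- 0.2
  repn <- generate_fragment_report(co$intensities, 1, 1, noise_cv = frag_cv,
                                   seed = 31)
  # brute-force variance decomposition on the log scale, protein by protein
  expected_extra <- log1p(frag_cv^2)  # var of log fragment noise
  extras <- vapply(unique(repn$protein_group)[1:30], function(pg) {
    sub <- repn[repn$protein_group == pg, ]
    prot <- unclass(co$intensities)[, pg]
    var(log(sub$intensity)) - var(log(prot[sub$cell_id]))
  }, numeric(1))
  expect_lt(abs(mean(extras) - expected_extra), 0.02)
})

test_that("zero gene means give an all-zero RNA matrix and negatives are rejected", {
  r <- generate_rna_counts(rna_sim_config(
    n_cells = 10, n_genes = 5, gene_mean_expression = rep(0, 5), seed = 1))
  expect_true(all(r$counts == 0))
  expect_error(rna_sim_config(n_cells = 10, n_genes = 2,
                              gene_mean_expression = c(1, -1)),
               ">= 0")
})

test_that("UMI detection fraction matches the Poisson law 1 - exp(-mean)", {
  means <- c(0.1, 0.3, 1, 2, 5)
  n_cells <- 800
  r <- generate_rna_counts(rna_sim_config(
    protocol = "umi", n_cells = n_cells, n_genes = length(means),
    gene_mean_expression = means,
    gene_symbols = paste0("g", seq_along(means)), seed = 29))
  observed <- colMeans(r$counts > 0)
  expected <- 1 - exp(-means)
  se <- sqrt(expected * (1 - expected) / n_cells)
  expect_true(all(abs(observed - expected) <= 3 * se))
})

test_that("default RNA configuration puts most genes below one copy per cell", {
  r <- generate_rna_counts(rna_sim_config(n_cells = 300, n_genes = 1500, seed = 37))
  expect_gt(mean(colMeans(r$counts) < 1), 0.5)
})

test_that("full-length protocol saturates counts and stays deterministic", {
  cfg <- rna_sim_config(protocol = "full_length", n_cells = 50, n_genes = 100,
                        saturation_scale = 20, seed = 41)
  a <- generate_rna_counts(cfg)
  b <- generate_rna_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_lte(max(a$counts), 20)
})
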