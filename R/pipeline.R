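#' Default end-to-end pipeline configuration
#'
#' Nested configuration covering every stage with the standard defaults
#' written out explicitly so any deviation is visible in a diff. Unknown
#' keys are rejected at run time.
#'
#' @param seed global seed; every stage derives its own sub-seed from it.
#' @return nested list of stage parameter lists plus `stages` toggles.
#' @export
pipeline_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, qc = TRUE, normalize = TRUE,
                  impute = TRUE, cellcycle = TRUE, diffexp = TRUE,
                  variability = TRUE, crossmodal = TRUE),
    simulate = list(n_cells_per_stage = c(G1 = 120, G1S = 120,
                                          G2 = 120, G2M = 120),
                    n_proteins = 2000,
                    rna_n_cells = 300, rna_n_genes = 2000,
                    rna_coupling = 0.7),
    qc = list(min_proteins = 600, min_completeness = 0.15, max_cv = 0.75),
    impute = list(width = 0.3, downshift = 1.8, scope = "per_cell"),
    cellcycle = list(n_bins = 25, ctrl_per_gene = 50),
    diffexp = list(group_a = "G2M", group_b = "G1S", s0 = 0.3,
                   fdr_target = 0.05, n_permutations = 250,
                   min_group_completeness = 0.5),
    variability = list(core_min_completeness = 0.70, core_k = 200)
  )
}

validate_config <- function(config) {
  ref <- pipeline_config()
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (sec in intersect(names(config), setdiff(names(ref), "seed"))) {
    bad <- setdiff(names(config[[sec]]), names(ref[[sec]]))
    if (length(bad)) {
      stop(sprintf("unknown key(s) in config$%s: %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  merged <- utils::modifyList(ref, config)
  merged
}

#' Run the full downstream pipeline
#'
#' Executes the stages in fixed order — simulate, QC funnel (cells,
#' features, CV), median-ratio normalization, log transform + imputation,
#' cell-cycle scoring with ROC, differential expression with permutation
#' FDR, CV / core-proteome / completeness analysis, and the cross-modal
#' proteome-RNA comparison — writing each stage's tables as TSV into
#' `outdir` and a machine-readable run report (parameters, filter funnel
#' counts, seeds, output paths) as JSON. Identical config and seed give
#' identical outputs; a stage failure aborts with the stage name while
#' earlier outputs are retained.
#'
#' @param config a [pipeline_config()] (possibly partial; missing entries
#'   take the defaults; unknown keys are rejected).
#' @param outdir output directory (created if needed).
#' @return the run report, invisibly (also written to
#'   `file.path(outdir, "run_report.json")`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("scpv_run_")) {
  config <- validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, config = config, stages = list())
  seed <- config$seed
  path <- function(f) file.path(outdir, f)
  finish <- function() {
    jsonlite::write_json(report, path("run_report.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    invisible(report)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  if (!config$stages$simulate) {
    return(finish())
  }
  sim <- run_stage("simulate", {
    cohort <- generate_proteome_cohort(proteome_sim_config(
      n_cells_per_stage = config$simulate$n_cells_per_stage,
      n_proteins = config$simulate$n_proteins,
      seed = child_seed(seed, 1L)))
    rna <- generate_rna_counts(rna_sim_config(
      n_cells = config$simulate$rna_n_cells,
      n_genes = config$simulate$rna_n_genes,
      protein_rna_coupling = config$simulate$rna_coupling,
      protein_log_abundance = stats::setNames(
        cohort$truth$base_abundance_log10, genes(cohort$intensities)),
      gene_symbols = default_gene_symbols(config$simulate$rna_n_genes),
      seed = child_seed(seed, 2L)))
    write_intensity_table(cohort$intensities, path("intensities_raw.tsv"), "wide")
    utils::write.table(cohort$cells, path("cells.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_mtx_counts(rna$counts, path("rna_counts.mtx"),
                     path("rna_features.tsv"), path("rna_barcodes.tsv"))
    write_ground_truth(cohort$truth, path("ground_truth.json"))
    list(cohort = cohort, rna = rna)
  })
  report$stages$simulate <- list(
    n_cells = nrow(sim$cohort$intensities),
    n_proteins = ncol(sim$cohort$intensities),
    completeness = completeness(sim$cohort$intensities),
    rna_dim = dim(sim$rna$counts))

  m <- sim$cohort$intensities
  cells <- sim$cohort$cells

  # matrix for phase scoring: cell/completeness-filtered but NOT CV-filtered,
  # since the CV cut would discard exactly the strongly regulated markers
  m_score <- m
  if (config$stages$qc) {
    m <- run_stage("qc", {
      a <- filter_cells(m, config$qc$min_proteins)
      b <- filter_features(a, config$qc$min_completeness)
      d <- filter_feature_cv(b, config$qc$max_cv)
      report$stages$qc <- list(
        cells = c(before = nrow(m), after_cell_filter = nrow(a)),
        proteins = c(before = ncol(m), after_completeness = ncol(b),
                     after_cv = ncol(d)))
      m_score <- b
      d
    })
    cells <- cells[cells$cell_id %in% rownames(m), ]
  }

  cell_size <- total_signal_per_cell(m)
  utils::write.table(
    data.frame(cell_id = names(cell_size), total_signal = cell_size,
               stage = cells$stage[match(names(cell_size), cells$cell_id)]),
    path("cell_size.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  if (config$stages$normalize) {
    m <- run_stage("normalize", {
      norm <- normalize_cells_median_ratio(m)
      report$stages$normalize <- list(
        factor_range = range(norm$factors))
      norm$normalized
    })
    write_intensity_table(m, path("intensities_normalized.tsv"), "wide")
  }

  logm <- log1p_transform(m)
  if (config$stages$impute) {
    imputed <- run_stage("impute", {
      impute_downshifted_normal(logm, width = config$impute$width,
                                downshift = config$impute$downshift,
                                scope = config$impute$scope,
                                seed = child_seed(seed, 3L))
    })
    report$stages$impute <- list(n_imputed = sum(is.na(logm)))
  } else {
    imputed <- logm
  }

  if (config$stages$cellcycle) {
    run_stage("cellcycle", {
      score_m <- if (config$stages$normalize) {
        normalize_cells_median_ratio(m_score)$normalized
      } else {
        m_score
      }
      zeroed <- as_plain_matrix(log1p_transform(score_m))
      zeroed[is.na(zeroed)] <- 0
      attr(zeroed, "genes") <- genes(score_m)
      tab <- score_phases(zeroed, n_bins = config$cellcycle$n_bins,
                          ctrl_per_gene = config$cellcycle$ctrl_per_gene,
                          seed = child_seed(seed, 4L))
      tab$stage <- cells$stage[match(tab$cell_id, cells$cell_id)]
      utils::write.table(tab, path("phase_scores.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      pos <- tab$stage %in% c("G2", "G2M")
      neg <- tab$stage %in% c("G1", "G1S")
      roc <- roc_auc(tab$G2M_score[pos | neg], pos[pos | neg])
      utils::write.table(roc$curve, path("roc_g2m.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      report$stages$cellcycle <- list(auc_g2m = roc$auc)
    })
  }

  if (config$stages$diffexp) {
    run_stage("diffexp", {
      dc <- config$diffexp
      sel <- cells$stage %in% c(dc$group_a, dc$group_b)
      de <- permutation_fdr(logm[cells$cell_id[sel], , drop = FALSE],
                            cells$stage[sel], s0 = dc$s0,
                            fdr_target = dc$fdr_target,
                            n_permutations = dc$n_permutations,
                            min_group_completeness = dc$min_group_completeness,
                            seed = child_seed(seed, 5L))
      utils::write.table(de, path("diffexp.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      report$stages$diffexp <- list(
        n_tested = nrow(de), n_significant = sum(de$significant),
        d_threshold = attr(de, "d_threshold"))
    })
  }

  if (config$stages$variability) {
    run_stage("variability", {
      vc <- config$variability
      core <- select_core_proteome(m, vc$core_min_completeness, vc$core_k)
      utils::write.table(core$members, path("core_proteome.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(cv_vs_mean_table(m), path("cv_vs_mean.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(completeness_profile(m),
                         path("completeness_profile.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      report$stages$variability <- list(
        core_size = nrow(core$members), n_eligible = core$n_eligible,
        median_cv = stats::median(cv_per_feature(m), na.rm = TRUE))
    })
  }

  if (config$stages$crossmodal) {
    run_stage("crossmodal", {
      rna_prep <- rna_filter_and_scale(sim$rna$counts, min_genes = 0,
                                       min_cell_fraction = 0,
                                       target = "mean_cell_size")
      bundle <- intersect_genes(list(proteome = logm, rna = rna_prep$matrix))
      prot_shared <- bundle$matrices$proteome
      rna_shared <- bundle$matrices$rna
      prot_corr <- pairwise_cell_correlations(prot_shared, "pairwise_complete")
      rna_corr <- pairwise_cell_correlations(rna_shared, "zeros")
      writeLines(bundle$genes, path("shared_genes.txt"))
      utils::write.table(prot_corr, path("cell_corr_proteome.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(rna_corr, path("cell_corr_rna.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      cvcv <- cv_correlation_across(
        stats::setNames(cv_per_feature(m), toupper(genes(m))),
        cv_per_feature(sim$rna$counts, zeros_as_values = TRUE))
      report$stages$crossmodal <- list(
        n_shared_genes = length(bundle$genes),
        median_r_proteome = stats::median(prot_corr$r),
        median_r_rna = stats::median(rna_corr$r),
        cv_cv_r = cvcv$r, cv_cv_n = cvcv$n_genes)
    })
  }

  finish()
}
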