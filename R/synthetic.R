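#' Configuration for the synthetic proteome cohort generator
#'
#' Defines the generative model for cell-by-protein intensity matrices that
#' emulate drug-arrested single-cell proteome cohorts measured one cell per
#' LC-MS run:
#'
#' * protein base abundances are log-normal over roughly four decades
#'   (`10^Normal(base_abundance_log_mean, base_abundance_log_sd)`),
#' * each cell carries the size factor of its cell-cycle stage (G2-arrested
#'   cells hold about 1.8-fold more protein than G1 cells),
#' * marker proteins receive stage-specific log2 fold-changes,
#' * measurement noise is multiplicative log-normal with a target
#'   coefficient of variation (`noise_cv`, default 0.3, the median
#'   per-protein CV observed in such cohorts),
#' * an entry is detected with probability
#'   `plogis(detection_slope * (log10(intensity) - detection_midpoint))`,
#'   the simplest monotone missing-not-at-random curve; the default midpoint
#'   sits at the population mean log10 intensity so that average
#'   completeness is close to 0.5.
#'
#' @param n_cells_per_stage named integer vector, cells per cell-cycle stage.
#' @param n_proteins number of protein groups.
#' @param base_abundance_log_mean,base_abundance_log_sd mean and SD of the
#'   log10 base abundance distribution.
#' @param stage_size_factors named positive scalars, per-stage cell size
#'   factor (total-protein multiplier).
#' @param noise_cv target multiplicative measurement CV.
#' @param detection_midpoint,detection_slope logistic detection curve
#'   parameters in log10-intensity units.
#' @param marker_effects data frame with columns `gene`, `stage`, `log2fc`:
#'   stage-specific abundance shifts for marker proteins. The default gives
#'   every built-in cell-cycle marker a +2.5 log2 shift in its own phase
#'   (G1 markers in G1, S markers in the G1/S arrest, G2/M markers in G2 and
#'   G2/M).
#' @param batch_offsets optional named numeric vector of per-batch log2
#'   offsets; `NULL` disables the batch model.
#' @param seed integer seed; all randomness derives from it via
#'   deterministic sub-streams.
#' @return a `proteome_sim_config` list.
#' @seealso [generate_proteome_cohort()]
#' @export
proteome_sim_config <- function(n_cells_per_stage = c(G1 = 120, G1S = 120,
                                                      G2 = 120, G2M = 120),
                                n_proteins = 2000,
                                base_abundance_log_mean = 4,
                                base_abundance_log_sd = 1,
                                stage_size_factors = c(G1 = 1, G1S = 1.4,
                                                       G2 = 1.8, G2M = 1.8),
                                noise_cv = 0.3,
                                detection_midpoint = 4.15,
                                detection_slope = 1.5,
                                marker_effects = default_marker_effects(),
                                batch_offsets = NULL,
                                seed = 1) {
  if (is.null(names(n_cells_per_stage)) || anyDuplicated(names(n_cells_per_stage))) {
    stop("`n_cells_per_stage` must be named with unique stage labels", call. = FALSE)
  }
  if (any(n_cells_per_stage < 0)) {
    stop("cell counts must be >= 0", call. = FALSE)
  }
  missing_sf <- setdiff(names(n_cells_per_stage), names(stage_size_factors))
  if (length(missing_sf)) {
    stop("no size factor for stage(s): ", paste(missing_sf, collapse = ", "),
         call. = FALSE)
  }
  if (any(stage_size_factors <= 0)) {
    stop("size factors must be > 0", call. = FALSE)
  }
  stopifnot_scalar(n_proteins, "n_proteins", lower = 0)
  stopifnot_scalar(noise_cv, "noise_cv", lower = 0)
  stopifnot_scalar(detection_slope, "detection_slope", lower = 0)
  if (!is.null(marker_effects) &&
      !all(c("gene", "stage", "log2fc") %in% names(marker_effects))) {
    stop("`marker_effects` needs columns gene, stage, log2fc", call. = FALSE)
  }
  structure(list(
    n_cells_per_stage = n_cells_per_stage,
    n_proteins = as.integer(n_proteins),
    base_abundance_log_mean = base_abundance_log_mean,
    base_abundance_log_sd = base_abundance_log_sd,
    stage_size_factors = stage_size_factors,
    noise_cv = noise_cv,
    detection_midpoint = detection_midpoint,
    detection_slope = detection_slope,
    marker_effects = marker_effects,
    batch_offsets = batch_offsets,
    seed = as.integer(seed)
  ), class = "proteome_sim_config")
}

#' Default stage-specific marker fold-changes
#'
#' Every built-in cell-cycle marker is up-shifted by +2.5 log2 units (about
#' 5.7-fold, the order of change seen for the most differentially expressed
#' proteins under drug-induced arrest) in the stage(s) it marks: G1 markers in `G1`, S markers in `G1S` (the
#' thymidine-arrest state), G2/M markers in both `G2` and `G2M`.
#'
#' @return data frame with columns `gene`, `stage`, `log2fc`.
#' @export
default_marker_effects <- function() {
  ms <- cell_cycle_markers()
  rbind(
    data.frame(gene = ms$G1$genes, stage = "G1", log2fc = 2.5),
    data.frame(gene = ms$S$genes, stage = "G1S", log2fc = 2.5),
    data.frame(gene = ms$G2M$genes, stage = "G2", log2fc = 2.5),
    data.frame(gene = ms$G2M$genes, stage = "G2M", log2fc = 2.5)
  )
}

#' Generate a synthetic single-cell proteome cohort
#'
#' Draws an intensity matrix under the generative model described in
#' [proteome_sim_config()]: the true intensity of protein p in cell c is
#' `base_p * size_factor_c * 2^(marker effect) * lognormal noise`, and the
#' entry is retained with the logistic detection probability of its
#' log10 intensity. Retained entries are strictly positive; dropped entries
#' are `NA`. Identical config and seed give bit-identical output.
#'
#' @param config a [proteome_sim_config()].
#' @return list with
#'   * `intensities`: an [intensity_matrix()] (cells x proteins, NA = not
#'     detected),
#'   * `cells`: data frame of per-cell annotations (`cell_id`, `stage`,
#'     `size_factor`),
#'   * `truth`: ground-truth generator state (per-protein base abundance,
#'     marker effects, noise CV, detection curve) for recovery tests.
#' @examples
#' cohort <- generate_proteome_cohort(proteome_sim_config(
#'   n_cells_per_stage = c(G1 = 10, G2 = 10), n_proteins = 100, seed = 7))
#' cohort$intensities
#' @export
generate_proteome_cohort <- function(config = proteome_sim_config()) {
  stopifnot(inherits(config, "proteome_sim_config"))
  stages <- rep(names(config$n_cells_per_stage), config$n_cells_per_stage)
  n_cells <- length(stages)
  n_prot <- config$n_proteins

  protein_ids <- sprintf("PG%04d", seq_len(n_prot))
  gene_syms <- default_gene_symbols(n_prot)
  cell_ids <- if (n_cells) sprintf("cell%04d", seq_len(n_cells)) else character(0)
  size_factors <- unname(config$stage_size_factors[stages])

  me <- config$marker_effects
  base_log10 <- with_seed(child_seed(config$seed, 1L), {
    stats::rnorm(n_prot, config$base_abundance_log_mean, config$base_abundance_log_sd)
  })
  names(base_log10) <- protein_ids
  # Marker panels are, by construction of their selection procedure,
  # restricted to proteins quantified in a large majority of cells, i.e. to
  # the upper part of the abundance range. Emulate that by reflecting marker
  # abundances above the population mean (half-normal upper tail).
  if (!is.null(me) && nrow(me)) {
    is_marker <- toupper(gene_syms) %in% toupper(me$gene)
    base_log10[is_marker] <- config$base_abundance_log_mean +
      abs(base_log10[is_marker] - config$base_abundance_log_mean)
  }

  # log2 marker effect matrix: stage x protein (0 where no effect)
  eff <- matrix(0, nrow = length(config$n_cells_per_stage), ncol = n_prot,
                dimnames = list(names(config$n_cells_per_stage), protein_ids))
  if (!is.null(me) && nrow(me)) {
    idx_g <- match(toupper(me$gene), toupper(gene_syms))
    keep <- !is.na(idx_g) & me$stage %in% rownames(eff)
    if (any(keep)) {
      eff[cbind(me$stage[keep], protein_ids[idx_g[keep]])] <- me$log2fc[keep]
    }
  }

  if (n_cells == 0 || n_prot == 0) {
    m <- intensity_matrix(
      matrix(numeric(0), nrow = n_cells, ncol = n_prot,
             dimnames = list(cell_ids, protein_ids)),
      genes = gene_syms)
    cells <- data.frame(cell_id = cell_ids, stage = stages[seq_len(n_cells)],
                        size_factor = size_factors[seq_len(n_cells)],
                        stringsAsFactors = FALSE)
    truth <- list(cells = cells, base_abundance_log10 = base_log10,
                  marker_effects = me, noise_cv = config$noise_cv,
                  detection = list(midpoint = config$detection_midpoint,
                                   slope = config$detection_slope))
    return(list(intensities = m, cells = cells, truth = truth))
  }

  true_int <- outer(size_factors, 10^base_log10) * 2^eff[stages, , drop = FALSE]

  sdlog <- sqrt(log1p(config$noise_cv^2))
  noise <- with_seed(child_seed(config$seed, 2L), {
    matrix(stats::rlnorm(n_cells * n_prot, meanlog = -sdlog^2 / 2, sdlog = sdlog),
           nrow = n_cells)
  })
  intens <- true_int * noise

  p_det <- stats::plogis(config$detection_slope *
                           (log10(intens) - config$detection_midpoint))
  detected <- with_seed(child_seed(config$seed, 3L), {
    matrix(stats::runif(n_cells * n_prot) < p_det, nrow = n_cells)
  })
  intens[!detected] <- NA_real_
  dimnames(intens) <- list(cell_ids, protein_ids)

  cells <- data.frame(cell_id = cell_ids, stage = stages,
                      size_factor = size_factors, stringsAsFactors = FALSE)
  if (!is.null(config$batch_offsets)) {
    batches <- names(config$batch_offsets)
    cells$batch <- rep(batches, length.out = n_cells)
    intens <- intens * 2^unname(config$batch_offsets[cells$batch])
  }

  truth <- list(cells = cells, base_abundance_log10 = base_log10,
                marker_effects = me, noise_cv = config$noise_cv,
                detection = list(midpoint = config$detection_midpoint,
                                 slope = config$detection_slope))
  list(intensities = intensity_matrix(intens, genes = gene_syms),
       cells = cells, truth = truth)
}

# Gene symbols for simulated protein groups: the built-in cell-cycle markers
# first (so marker effects are applicable), then synthetic symbols.
default_gene_symbols <- function(n_proteins) {
  ms <- cell_cycle_markers()
  syms <- unique(unlist(lapply(ms, `[[`, "genes"), use.names = FALSE))
  if (n_proteins <= length(syms)) {
    return(syms[seq_len(n_proteins)])
  }
  c(syms, sprintf("GENE%04d", seq_len(n_proteins - length(syms))))
}

#' Generate a fragment-level long report from a proteome matrix
#'
#' Expands each detected (cell, protein) intensity into
#' `peptides_per_protein * fragments_per_peptide` fragment-ion rows. Response
#' factors are fixed per peptide and per fragment (geometric ladders
#' `2^-(i-1)` and `2^-((j-1)/2)`), so with one peptide, one fragment and no
#' noise the fragment table equals the protein matrix, and within a cell the
#' log-ratio between two fragments of one peptide is constant across cells
#' when noise is zero.
#'
#' @param m an [intensity_matrix()] (typically from
#'   [generate_proteome_cohort()]).
#' @param peptides_per_protein,fragments_per_peptide counts (>= 1).
#' @param noise_cv multiplicative log-normal fragment measurement CV.
#' @param seed integer seed.
#' @return data frame with columns `cell_id`, `protein_group`, `peptide`,
#'   `fragment`, `intensity` (one row per detected fragment ion).
#' @export
generate_fragment_report <- function(m, peptides_per_protein = 3,
                                     fragments_per_peptide = 3,
                                     noise_cv = 0.1, seed = 1) {
  stopifnot(peptides_per_protein >= 1, fragments_per_peptide >= 1, noise_cv >= 0)
  m <- as_plain_matrix(m)
  obs <- which(!is.na(m), arr.ind = TRUE)
  n_pep <- as.integer(peptides_per_protein)
  n_frag <- as.integer(fragments_per_peptide)
  pep_idx <- rep(seq_len(n_pep), each = n_frag)
  frag_idx <- rep(seq_len(n_frag), times = n_pep)
  pf <- 2^-(pep_idx - 1)
  ff <- 2^-((frag_idx - 1) / 2)
  n_ions <- n_pep * n_frag

  cell <- rep(rownames(m)[obs[, 1]], each = n_ions)
  prot <- rep(colnames(m)[obs[, 2]], each = n_ions)
  base <- rep(m[obs], each = n_ions)
  pep <- paste0(prot, "_pep", rep(pep_idx, nrow(obs)))
  frag <- paste0(pep, "_f", rep(frag_idx, nrow(obs)))
  resp <- rep(pf * ff, nrow(obs))

  sdlog <- sqrt(log1p(noise_cv^2))
  noise <- if (noise_cv > 0) {
    with_seed(child_seed(seed, 4L), {
      stats::rlnorm(length(base), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    })
  } else {
    rep(1, length(base))
  }

  data.frame(cell_id = cell, protein_group = prot, peptide = pep,
             fragment = frag, intensity = base * resp * noise,
             stringsAsFactors = FALSE)
}

#' Configuration for the synthetic RNA count generator
#'
#' Emulates single-cell RNA-seq count matrices of the same cell line in two
#' flavours: a UMI-controlled droplet protocol, where counts are pure
#' Poisson samples of the per-gene mean (the shot-noise regime: dropout is
#' `exp(-mean)` and detection `1 - exp(-mean)`), and a full-length protocol
#' with Gamma-Poisson overdispersion followed by a saturating transform
#' `round(K * x / (x + K))` that mimics sequencing saturation. Gene mean
#' expression defaults to a log-normal with most genes below one copy per
#' cell, optionally correlated with protein base abundances.
#'
#' @param protocol `"umi"` or `"full_length"`.
#' @param n_cells,n_genes dimensions.
#' @param gene_mean_expression optional numeric vector of per-gene mean
#'   copies per cell (named by gene symbol); drawn log-normally when `NULL`.
#' @param mean_log10,sd_log10 parameters of the default log10 gene-mean
#'   distribution (defaults put ~60% of genes below one copy per cell).
#' @param protein_rna_coupling correlation in \[0, 1\] between gene log-means
#'   and protein log base abundances (requires `protein_log_abundance`).
#' @param protein_log_abundance named log10 protein base abundances (e.g.
#'   `truth$base_abundance_log10` with `genes()` names applied) used for
#'   coupling.
#' @param gene_symbols optional symbols; defaults to the same symbol ladder
#'   as the proteome generator so proteome and RNA share genes.
#' @param cell_size scalar or per-cell vector of relative cell sizes.
#' @param dispersion Gamma-Poisson dispersion (full-length only).
#' @param saturation_scale saturation constant K (full-length only).
#' @param seed integer seed.
#' @return an `rna_sim_config` list.
#' @export
rna_sim_config <- function(protocol = c("umi", "full_length"),
                           n_cells = 500, n_genes = 3000,
                           gene_mean_expression = NULL,
                           mean_log10 = -0.3, sd_log10 = 1,
                           protein_rna_coupling = 0,
                           protein_log_abundance = NULL,
                           gene_symbols = NULL,
                           cell_size = 1,
                           dispersion = 0.5,
                           saturation_scale = 100,
                           seed = 1) {
  protocol <- match.arg(protocol)
  stopifnot_scalar(n_cells, "n_cells", lower = 0)
  stopifnot_scalar(n_genes, "n_genes", lower = 0)
  stopifnot_scalar(protein_rna_coupling, "protein_rna_coupling", 0, 1)
  stopifnot_scalar(saturation_scale, "saturation_scale", lower = 1e-9)
  if (!is.null(gene_mean_expression) && any(gene_mean_expression < 0)) {
    stop("gene mean expression must be >= 0", call. = FALSE)
  }
  if (any(cell_size <= 0)) {
    stop("cell sizes must be > 0", call. = FALSE)
  }
  structure(list(
    protocol = protocol, n_cells = as.integer(n_cells),
    n_genes = as.integer(n_genes),
    gene_mean_expression = gene_mean_expression,
    mean_log10 = mean_log10, sd_log10 = sd_log10,
    protein_rna_coupling = protein_rna_coupling,
    protein_log_abundance = protein_log_abundance,
    gene_symbols = gene_symbols, cell_size = cell_size,
    dispersion = dispersion, saturation_scale = saturation_scale,
    seed = as.integer(seed)
  ), class = "rna_sim_config")
}

#' Generate a synthetic single-cell RNA count matrix
#'
#' @param config an [rna_sim_config()].
#' @return list with `counts` (integer matrix, cells x genes, zeros are
#'   observed values) and `cells` (data frame of cell annotations including
#'   the true cell size), plus `gene_means` (the true per-gene mean copies
#'   per cell at size 1).
#' @examples
#' r <- generate_rna_counts(rna_sim_config(n_cells = 50, n_genes = 200, seed = 3))
#' mean(r$counts == 0)
#' @export
generate_rna_counts <- function(config = rna_sim_config()) {
  stopifnot(inherits(config, "rna_sim_config"))
  n_cells <- config$n_cells
  n_genes <- config$n_genes
  syms <- config$gene_symbols %||% default_gene_symbols(n_genes)
  if (length(syms) != n_genes) {
    stop("`gene_symbols` must have length n_genes", call. = FALSE)
  }
  cell_ids <- if (n_cells) sprintf("rna_cell%04d", seq_len(n_cells)) else character(0)

  means <- config$gene_mean_expression
  if (is.null(means)) {
    means <- with_seed(child_seed(config$seed, 10L), {
      z_noise <- stats::rnorm(n_genes)
      rho <- config$protein_rna_coupling
      z <- z_noise
      if (rho > 0 && !is.null(config$protein_log_abundance)) {
        pa <- config$protein_log_abundance
        idx <- match(toupper(syms), toupper(names(pa)))
        z_prot <- rep(0, n_genes)
        hit <- !is.na(idx)
        if (any(hit)) {
          z_prot[hit] <- as.numeric(scale(pa))[idx[hit]]
        }
        z <- rho * z_prot + sqrt(1 - rho^2) * z_noise
      }
      10^(config$mean_log10 + config$sd_log10 * z)
    })
  }
  means <- as.numeric(means)
  names(means) <- syms

  sizes <- rep(config$cell_size, length.out = n_cells)
  lambda <- outer(sizes, means)

  counts <- with_seed(child_seed(config$seed, 11L), {
    if (config$protocol == "umi") {
      matrix(stats::rpois(length(lambda), lambda), nrow = n_cells)
    } else {
      shape <- 1 / config$dispersion
      lam <- matrix(stats::rgamma(length(lambda), shape = shape,
                                  rate = shape / pmax(lambda, 1e-12)),
                    nrow = n_cells)
      lam[lambda == 0] <- 0
      raw <- matrix(stats::rpois(length(lam), lam), nrow = n_cells)
      k <- config$saturation_scale
      round(k * raw / (raw + k))
    }
  })
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(cell_ids, syms)

  list(counts = counts,
       cells = data.frame(cell_id = cell_ids, size = sizes,
                          stringsAsFactors = FALSE),
       gene_means = means)
}
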