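#' Select phase marker sets from a differential table
#'
#' Per phase, takes the `top_n` genes by descending differential value
#' (e.g. z-scored fold-change ratios from a bulk cell-cycle study; ties are
#' broken by gene symbol, ascending), then drops candidates quantified in
#' fewer than `min_completeness` of the cells of the target matrix. The
#' defaults — top 60 filtered at 70% completeness — reproduce the standard
#' marker-selection recipe.
#'
#' @param diff_table data frame with columns `gene`, `phase`, `value`.
#' @param m an [intensity_matrix()] used for the completeness filter.
#' @param top_n candidates per phase (default 60).
#' @param min_completeness completeness filter (default 0.70).
#' @return named list of [marker_set()] objects, one per phase present in
#'   `diff_table` (empty phases yield an empty set with a warning).
#' @export
select_markers <- function(diff_table, m, top_n = 60, min_completeness = 0.70) {
  if (!all(c("gene", "phase", "value") %in% names(diff_table))) {
    stop("`diff_table` needs columns gene, phase, value", call. = FALSE)
  }
  comp <- colMeans(!is.na(m))
  names(comp) <- toupper(genes(m))
  phases <- unique(diff_table$phase)
  out <- lapply(phases, function(p) {
    sub <- diff_table[diff_table$phase == p, ]
    sub <- sub[order(-sub$value, sub$gene), ]
    cand <- utils::head(sub$gene, top_n)
    keep <- cand[!is.na(comp[toupper(cand)]) &
                   comp[toupper(cand)] >= min_completeness]
    if (length(keep) == 0) {
      warning("no markers retained for phase ", p)
      return(structure(list(phase = p, genes = character(0)),
                       class = "marker_set"))
    }
    marker_set(p, keep)
  })
  names(out) <- phases
  out
}

#' Gene-set expression score per cell
#'
#' The score_genes-style statistic used for cell-cycle phase calling: the
#' average expression of the marker set minus the average expression of a
#' sampled reference set chosen to mirror the marker set's expression
#' levels. All genes are placed into `n_bins` equal-frequency bins by mean
#' expression over cells; for each marker, `ctrl_per_gene` reference genes
#' are sampled without replacement from its bin (marker genes excluded).
#'
#' Input must be complete (in this workflow cells are filtered, `log(x+1)`
#' transformed, and missing values replaced by zeros — not imputed).
#'
#' @param m complete numeric matrix, cells x genes (gene symbols as column
#'   names or via [genes()]).
#' @param set a [marker_set()] or character vector of gene symbols. Symbols
#'   absent from `m` are dropped with a warning; an empty intersection is an
#'   error.
#' @param n_bins number of equal-frequency expression bins (default 25).
#' @param ctrl_per_gene reference genes sampled per marker gene (default 50).
#' @param seed integer seed for the reference sampling.
#' @return named numeric vector, one signed score per cell.
#' @export
score_gene_set <- function(m, set, n_bins = 25, ctrl_per_gene = 50, seed = 1) {
  if (anyNA(m)) {
    stop("score_gene_set requires a complete matrix (replace missing values by zeros first)",
         call. = FALSE)
  }
  set_genes <- if (inherits(set, "marker_set")) set$genes else as.character(set)
  sym <- toupper(trimws(genes(m)))
  vals <- as_plain_matrix(m)
  colnames(vals) <- sym
  want <- toupper(trimws(set_genes))
  hit <- want %in% sym
  if (!all(hit)) {
    warning(sum(!hit), " marker gene(s) absent from the matrix: ",
            paste(utils::head(set_genes[!hit], 5), collapse = ", "))
  }
  want <- unique(want[hit])
  if (length(want) == 0) {
    stop("no marker genes present in the matrix", call. = FALSE)
  }

  gene_means <- colMeans(vals)
  n_bins_eff <- max(1, min(n_bins, length(gene_means)))
  # equal-frequency bins by rank; robust to heavily tied/skewed means
  bin <- ceiling(rank(gene_means, ties.method = "first") * n_bins_eff /
                   length(gene_means))
  names(bin) <- sym

  is_set <- sym %in% want
  ctrl_idx <- with_seed(seed, {
    unlist(lapply(which(is_set), function(j) {
      pool <- which(bin == bin[j] & !is_set)
      if (length(pool) == 0) {
        return(integer(0))
      }
      pool[sample.int(length(pool), min(ctrl_per_gene, length(pool)))]
    }), use.names = FALSE)
  })

  set_mean <- rowMeans(vals[, is_set, drop = FALSE])
  ctrl_mean <- if (length(ctrl_idx)) {
    rowMeans(vals[, ctrl_idx, drop = FALSE])
  } else {
    rep(0, nrow(vals))
  }
  out <- set_mean - ctrl_mean
  names(out) <- rownames(m)
  out
}

#' Phase score table for the three cell-cycle scores
#'
#' Computes one [score_gene_set()] score per marker set and the argmax
#' phase call per cell.
#'
#' @param m complete matrix (see [score_gene_set()]).
#' @param marker_sets named list of [marker_set()] objects (default the
#'   built-in cell-cycle sets).
#' @param n_bins,ctrl_per_gene,seed passed to [score_gene_set()]; each set
#'   uses a sub-seed so sets are independently sampled but reproducible.
#' @return data frame with one row per cell: `cell_id`, one `<phase>_score`
#'   column per set, and `predicted_phase`.
#' @export
score_phases <- function(m, marker_sets = cell_cycle_markers(),
                         n_bins = 25, ctrl_per_gene = 50, seed = 1) {
  scores <- lapply(seq_along(marker_sets), function(i) {
    score_gene_set(m, marker_sets[[i]], n_bins = n_bins,
                   ctrl_per_gene = ctrl_per_gene,
                   seed = child_seed(seed, 100L + i))
  })
  names(scores) <- paste0(names(marker_sets), "_score")
  tab <- data.frame(cell_id = rownames(m), scores,
                    stringsAsFactors = FALSE, check.names = FALSE)
  tab$predicted_phase <- predict_phase(tab)
  tab
}

#' Predict the phase of each cell from its scores
#'
#' Argmax over the score columns; ties are broken by the fixed column order
#' (G1 before S before G2M for the built-in sets).
#'
#' @param scores data frame with `<phase>_score` columns (finite values).
#' @return character vector of phase labels, one per row.
#' @export
predict_phase <- function(scores) {
  score_cols <- grep("_score$", names(scores), value = TRUE)
  if (length(score_cols) == 0) {
    stop("no *_score columns found", call. = FALSE)
  }
  sm <- as.matrix(scores[score_cols])
  if (anyNA(sm) || any(!is.finite(sm))) {
    stop("scores must be finite", call. = FALSE)
  }
  phases <- sub("_score$", "", score_cols)
  phases[apply(sm, 1, which.max)]
}

#' ROC curve and AUC from per-cell scores
#'
#' Ranks cells by score and accumulates true/false positive rates; the AUC
#' equals the Mann-Whitney statistic U / (n+ * n-), with ties contributing
#' one half (equivalently, the trapezoidal area under the tie-aware curve).
#'
#' @param scores numeric vector.
#' @param positives logical vector, `TRUE` for the positive class. Both
#'   classes must be non-empty.
#' @return list with `curve` (data frame of `fpr`, `tpr`, monotone
#'   non-decreasing, from (0,0) to (1,1)) and `auc`.
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE))$auc
#' @export
roc_auc <- function(scores, positives) {
  positives <- as.logical(positives)
  stopifnot(length(scores) == length(positives), !anyNA(scores), !anyNA(positives))
  n_pos <- sum(positives)
  n_neg <- sum(!positives)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  # sweep the threshold over distinct score values, descending;
  # ties enter together, which draws the diagonal tie segments
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- positives[ord]
  steps <- cumsum(p)[!duplicated(s, fromLast = TRUE)]
  fsteps <- cumsum(!p)[!duplicated(s, fromLast = TRUE)]
  tpr <- c(0, steps / n_pos)
  fpr <- c(0, fsteps / n_neg)
  # Mann-Whitney with ties at 1/2 via midranks
  r <- rank(scores)
  u <- sum(r[positives]) - n_pos * (n_pos + 1) / 2
  auc <- u / (n_pos * n_neg)
  list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}
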