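#' Filter cells by number of quantified proteins
#'
#' Retains exactly the cells with at least `min_proteins` quantified entries
#' ("at least" is inclusive: a cell with exactly the threshold is kept).
#' The protein set is unchanged and the operation is idempotent. The default
#' of 600 is the standard stringency for single-cell proteome matrices of
#' this depth.
#'
#' @param m an [intensity_matrix()].
#' @param min_proteins minimum number of quantified proteins per cell.
#' @param verbose log before/after counts.
#' @return the filtered [intensity_matrix()] (possibly 0 cells).
#' @export
filter_cells <- function(m, min_proteins = 600, verbose = FALSE) {
  stopifnot_scalar(min_proteins, "min_proteins", lower = 0)
  n_obs <- rowSums(!is.na(m))
  keep <- n_obs >= min_proteins
  if (verbose) {
    message(sprintf("filter_cells: %d -> %d cells (>= %d proteins)",
                    nrow(m), sum(keep), as.integer(min_proteins)))
  }
  m[keep, , drop = FALSE]
}

#' Filter proteins by quantification completeness
#'
#' Retains proteins quantified in at least `min_completeness` of the cells
#' currently in the matrix (completeness is computed after any preceding
#' cell filter). Default 15%.
#'
#' @param m an [intensity_matrix()].
#' @param min_completeness fraction in \[0, 1\].
#' @param verbose log before/after counts.
#' @return the filtered [intensity_matrix()].
#' @export
filter_features <- function(m, min_completeness = 0.15, verbose = FALSE) {
  stopifnot_scalar(min_completeness, "min_completeness", 0, 1)
  frac <- if (nrow(m)) colMeans(!is.na(m)) else rep(1, ncol(m))
  keep <- frac >= min_completeness
  if (verbose) {
    message(sprintf("filter_features: %d -> %d proteins (completeness >= %.2f)",
                    ncol(m), sum(keep), min_completeness))
  }
  m[, keep, drop = FALSE]
}

#' Filter proteins by coefficient of variation
#'
#' Drops proteins whose linear-scale CV (sample SD / mean over non-missing
#' entries) is not strictly below `max_cv` ("below 0.75" is strict).
#' Proteins with fewer than two observations have an undefined CV and are
#' dropped.
#'
#' @param m an [intensity_matrix()] on the linear intensity scale.
#' @param max_cv CV cutoff (default 0.75).
#' @param verbose log before/after counts.
#' @return the filtered [intensity_matrix()].
#' @export
filter_feature_cv <- function(m, max_cv = 0.75, verbose = FALSE) {
  stopifnot_scalar(max_cv, "max_cv", lower = 0)
  cvs <- apply(as_plain_matrix(m), 2, cv_of)
  keep <- !is.na(cvs) & cvs < max_cv
  if (verbose) {
    message(sprintf("filter_feature_cv: %d -> %d proteins (CV < %.2f; %d with < 2 obs dropped)",
                    ncol(m), sum(keep), max_cv, sum(is.na(cvs))))
  }
  m[, keep, drop = FALSE]
}

#' Natural log(x + 1) transform
#'
#' Applies `ln(1 + x)` to every present value; missing entries stay missing.
#'
#' @param m an [intensity_matrix()] or numeric matrix with values >= 0.
#' @return matrix of the same shape and class on the log1p scale.
#' @export
log1p_transform <- function(m) {
  if (any(m < 0, na.rm = TRUE)) {
    stop("log1p_transform requires non-negative values", call. = FALSE)
  }
  out <- log1p(as_plain_matrix(m))
  attributes(out) <- attributes(m)
  if (inherits(m, "intensity_matrix")) {
    # log scale breaks the strict-positivity invariant of the constructor,
    # so keep the class but bypass validation
    class(out) <- class(m)
  }
  out
}

#' Per-cell median-ratio normalization
#'
#' Fold-change-based normalization with one factor per cell: a
#' pseudo-reference profile is built as the per-protein median over the
#' cells in which the protein is present; each cell's factor is the median,
#' over the proteins it shares with the reference, of cell intensity /
#' reference intensity; the cell is divided by its factor. Afterwards every
#' cell's median log-ratio to the reference is zero. This cancels
#' cell-size-dependent abundance differences before comparative analyses.
#'
#' @param m an [intensity_matrix()] on the linear scale (>= 2 cells).
#' @return list with `normalized` (the scaled [intensity_matrix()]) and
#'   `factors` (named per-cell scalars). A cell sharing no proteins with the
#'   reference keeps factor 1 with a warning.
#' @export
normalize_cells_median_ratio <- function(m) {
  if (nrow(m) < 2) {
    stop("median-ratio normalization needs at least 2 cells", call. = FALSE)
  }
  vals <- as_plain_matrix(m)
  ref <- apply(vals, 2, stats::median, na.rm = TRUE)
  # factor = exp(median log fold-change to the reference): working on the
  # log scale keeps the post-normalization median log-ratio exactly zero
  log_ratio <- sweep(log(vals), 2, log(ref), "-")
  factors <- exp(apply(log_ratio, 1, stats::median, na.rm = TRUE))
  lonely <- !is.finite(factors)
  if (any(lonely)) {
    warning(sum(lonely), " cell(s) share no proteins with the reference; factor set to 1")
    factors[lonely] <- 1
  }
  names(factors) <- rownames(m)
  out <- vals / factors
  attributes(out) <- attributes(m)
  list(normalized = out, factors = factors)
}

#' Impute missing values from a downshifted normal distribution
#'
#' The standard missing-not-at-random imputation for log-transformed
#' proteomics matrices: each missing entry is drawn from
#' `Normal(mean_obs - downshift * sd_obs, (width * sd_obs)^2)` where the
#' moments are computed over the observed values in scope — per cell (each
#' cell's own observed distribution; the default, matching the convention
#' that samples are imputed one by one) or globally. This places imputed
#' values in the low-abundance tail where undetected proteins live.
#'
#' @param m log-transformed [intensity_matrix()] or matrix.
#' @param width imputation SD as a fraction of the observed SD (default 0.3).
#' @param downshift centre shift in multiples of the observed SD (default 1.8).
#' @param scope `"per_cell"` or `"global"`.
#' @param seed integer seed; identical seeds give identical imputations.
#' @return complete matrix of the same shape; observed entries untouched.
#' @export
impute_downshifted_normal <- function(m, width = 0.3, downshift = 1.8,
                                      scope = c("per_cell", "global"),
                                      seed = 1) {
  scope <- match.arg(scope)
  stopifnot_scalar(width, "width", lower = 1e-12)
  stopifnot_scalar(downshift, "downshift", lower = 0)
  vals <- as_plain_matrix(m)
  miss <- is.na(vals)
  if (!any(miss)) {
    return(m)
  }
  g_mean <- mean(vals, na.rm = TRUE)
  g_sd <- stats::sd(vals[!miss])
  out <- with_seed(seed, {
    if (scope == "global") {
      vals[miss] <- stats::rnorm(sum(miss), g_mean - downshift * g_sd,
                                 width * g_sd)
    } else {
      n_fallback <- 0
      for (i in seq_len(nrow(vals))) {
        mi <- miss[i, ]
        if (!any(mi)) next
        obs <- vals[i, !mi]
        if (length(obs) >= 2) {
          mu <- mean(obs)
          s <- stats::sd(obs)
        } else {
          mu <- g_mean
          s <- g_sd
          n_fallback <- n_fallback + 1
        }
        vals[i, mi] <- stats::rnorm(sum(mi), mu - downshift * s, width * s)
      }
      if (n_fallback > 0) {
        message(sprintf("impute: %d cell(s) with < 2 observed values fell back to global moments",
                        n_fallback))
      }
    }
    vals
  })
  attributes(out) <- attributes(m)
  out
}

#' Total protein signal per cell
#'
#' Sums all quantified protein intensities of each cell — the proxy for the
#' total protein amount (cell size). Computed on raw, unnormalized
#' intensities by default since normalization is designed to cancel exactly
#' this signal.
#'
#' @param m an [intensity_matrix()] on the linear scale.
#' @return named numeric vector, one sum per cell (0 for an empty cell).
#' @export
total_signal_per_cell <- function(m) {
  out <- rowSums(as_plain_matrix(m), na.rm = TRUE)
  names(out) <- rownames(m)
  out
}

#' Filter and scale an RNA count matrix
#'
#' The standardized RNA preprocessing: cells with fewer than `min_genes`
#' expressed (nonzero) genes are removed (strictly "less than"), then genes
#' detected in fewer than `min_cell_fraction` of the remaining cells are
#' removed; each cell is linearly scaled so its total equals the target
#' (the dataset mean cell size, or 1e6), followed by `ln(1 + x)`.
#'
#' @param counts integer matrix, cells x genes.
#' @param min_genes minimum expressed genes per cell (default 600).
#' @param min_cell_fraction minimum detection fraction per gene (default 0.15).
#' @param target `"mean_cell_size"` (used before correlation analyses) or
#'   `"1e6"` (used before PCA).
#' @param log_transform apply `ln(1 + x)` after scaling (default `TRUE`).
#' @param verbose log filter funnel counts.
#' @return list with `matrix` (the transformed matrix), `scale_target` (the
#'   per-cell total after scaling) and the retained cell/gene names.
#' @export
rna_filter_and_scale <- function(counts, min_genes = 600,
                                 min_cell_fraction = 0.15,
                                 target = c("mean_cell_size", "1e6"),
                                 log_transform = TRUE, verbose = FALSE) {
  target <- match.arg(target)
  if (any(counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  keep_cells <- rowSums(counts > 0) >= min_genes
  sub <- counts[keep_cells, , drop = FALSE]
  keep_genes <- if (nrow(sub)) colMeans(sub > 0) >= min_cell_fraction else
    rep(FALSE, ncol(sub))
  sub <- sub[, keep_genes, drop = FALSE]
  if (verbose) {
    message(sprintf("rna_filter: %d -> %d cells (>= %d genes); %d -> %d genes (>= %.0f%% of cells)",
                    nrow(counts), nrow(sub), as.integer(min_genes),
                    ncol(counts), ncol(sub), 100 * min_cell_fraction))
  }
  if (nrow(sub) == 0 || ncol(sub) == 0) {
    message("rna_filter_and_scale: empty matrix after filtering")
    return(list(matrix = sub * 0, scale_target = NA_real_,
                cells = rownames(sub), genes = colnames(sub)))
  }
  totals <- rowSums(sub)
  tgt <- if (target == "mean_cell_size") mean(totals) else 1e6
  scaled <- sub * (tgt / totals)
  if (log_transform) {
    scaled <- log1p(scaled)
  }
  list(matrix = scaled, scale_target = tgt,
       cells = rownames(sub), genes = colnames(sub))
}
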