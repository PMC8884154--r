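#' Intersect gene symbols across matrices
#'
#' Harmonizes two or more matrices (proteome intensity matrices and/or RNA
#' count matrices) on their shared gene symbols. Matching is
#' case-insensitive after uppercasing and trimming; the result is ordered
#' alphabetically and each returned matrix has its columns aligned to that
#' order. Where a matrix carries several protein groups for one symbol, the
#' first is used.
#'
#' @param matrices named list of matrices (gene symbols from [genes()] for
#'   intensity matrices, column names otherwise).
#' @return list with `genes` (shared uppercase symbols, alphabetical) and
#'   `matrices` (the inputs restricted and aligned to them). Empty
#'   intersection is an error.
#' @export
intersect_genes <- function(matrices) {
  if (length(matrices) < 2) {
    stop("need at least two matrices", call. = FALSE)
  }
  sym_list <- lapply(matrices, function(m) toupper(trimws(genes(m))))
  shared <- Reduce(intersect, sym_list)
  if (length(shared) == 0) {
    stop("no shared gene symbols across the matrices", call. = FALSE)
  }
  shared <- sort(shared)
  aligned <- lapply(seq_along(matrices), function(i) {
    idx <- match(shared, sym_list[[i]])
    out <- as_plain_matrix(matrices[[i]])[, idx, drop = FALSE]
    colnames(out) <- shared
    out
  })
  names(aligned) <- names(matrices)
  list(genes = shared, matrices = aligned)
}

#' Pairwise cell-cell Pearson correlations
#'
#' Computes the Pearson correlation for every unordered pair of cells.
#' Proteomics convention (`missing_policy = "pairwise_complete"`): entries
#' missing in either cell are excluded from that pair's computation and
#' pairs with fewer than `min_shared` shared observations are skipped.
#' RNA convention (`"zeros"`): `NA`s (if any) are replaced by zeros and all
#' genes enter every pair.
#'
#' @param m matrix, cells x genes (typically log-transformed).
#' @param missing_policy `"pairwise_complete"` or `"zeros"`.
#' @param min_shared minimum shared observations per pair (default 3).
#' @return data frame with one row per retained pair: `cell_a`, `cell_b`,
#'   `n_shared`, `r`; the number of skipped pairs is in attribute
#'   `n_skipped`.
#' @export
pairwise_cell_correlations <- function(m,
                                       missing_policy = c("pairwise_complete",
                                                          "zeros"),
                                       min_shared = 3) {
  missing_policy <- match.arg(missing_policy)
  vals <- as_plain_matrix(m)
  if (nrow(vals) < 2) {
    stop("need at least 2 cells", call. = FALSE)
  }
  if (missing_policy == "zeros") {
    vals[is.na(vals)] <- 0
    cmat <- stats::cor(t(vals))
    n_shared <- matrix(ncol(vals), nrow(vals), nrow(vals))
  } else {
    cmat <- suppressWarnings(stats::cor(t(vals), use = "pairwise.complete.obs"))
    present <- !is.na(vals)
    n_shared <- tcrossprod(present * 1)
  }
  pairs <- which(upper.tri(cmat), arr.ind = TRUE)
  ok <- n_shared[pairs] >= min_shared & !is.na(cmat[pairs])
  out <- data.frame(cell_a = rownames(vals)[pairs[ok, 1]],
                    cell_b = rownames(vals)[pairs[ok, 2]],
                    n_shared = n_shared[pairs][ok],
                    r = cmat[pairs][ok],
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Correlation of per-gene CVs between two technologies
#'
#' Pearson correlation of coefficients of variation over the genes shared
#' between two datasets; genes with an undefined CV in either are excluded.
#'
#' @param cv_a,cv_b named numeric vectors of per-gene CVs (names = gene
#'   symbols, matched case-insensitively).
#' @return list with `r`, `n_genes`, and the shared `genes` used.
#' @export
cv_correlation_across <- function(cv_a, cv_b) {
  names(cv_a) <- toupper(trimws(names(cv_a)))
  names(cv_b) <- toupper(trimws(names(cv_b)))
  shared <- intersect(names(cv_a)[!is.na(cv_a)], names(cv_b)[!is.na(cv_b)])
  if (length(shared) < 3) {
    stop("need at least 3 shared genes with defined CVs", call. = FALSE)
  }
  r <- stats::cor(cv_a[shared], cv_b[shared])
  list(r = r, n_genes = length(shared), genes = shared)
}

#' PCA embedding of a complete matrix
#'
#' Mean-centered singular value decomposition with components ordered by
#' decreasing explained variance. The sign of each component is fixed so
#' that its largest-magnitude loading is positive, making embeddings
#' reproducible across platforms. Callers impute or zero-fill first,
#' matching the two standard recipes (downshifted-normal imputation for
#' within-technology PCA; zero-fill plus 1e6 scaling for cross-technology
#' PCA).
#'
#' @param m complete numeric matrix, cells x features.
#' @param n_components number of components (<= min(dim)).
#' @return list with `coords` (cells x components), `loadings`
#'   (features x components) and `explained_variance` (fractions of total
#'   variance, non-increasing, summing to <= 1).
#' @export
pca_embedding <- function(m, n_components = 2) {
  vals <- as_plain_matrix(m)
  if (anyNA(vals)) {
    stop("PCA requires a complete matrix; impute or zero-fill first", call. = FALSE)
  }
  if (n_components > min(dim(vals))) {
    stop("n_components exceeds matrix rank bound", call. = FALSE)
  }
  centered <- sweep(vals, 2, colMeans(vals))
  sv <- svd(centered, nu = n_components, nv = n_components)
  # sign convention: largest-|loading| entry of each component positive
  for (k in seq_len(n_components)) {
    j <- which.max(abs(sv$v[, k]))
    if (sv$v[j, k] < 0) {
      sv$v[, k] <- -sv$v[, k]
      sv$u[, k] <- -sv$u[, k]
    }
  }
  coords <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  rownames(coords) <- rownames(vals)
  colnames(coords) <- paste0("PC", seq_len(n_components))
  loadings <- sv$v
  rownames(loadings) <- colnames(vals)
  colnames(loadings) <- colnames(coords)
  ev <- sv$d^2 / sum(sv$d^2)
  list(coords = coords, loadings = loadings,
       explained_variance = ev[seq_len(n_components)])
}
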