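#' Per-feature coefficient of variation
#'
#' CV = sample SD / mean on linear-scale values. For proteomics matrices
#' missing entries are excluded; for RNA count matrices zeros are observed
#' values and must be included (`zeros_as_values = TRUE`, following the
#' convention that UMI-controlled single-cell RNA-seq is not zero
#' inflated). Features with fewer than `min_obs` usable values get `NA`.
#'
#' @param m matrix, cells x features, linear scale.
#' @param min_obs minimum observations for a defined CV (default 2).
#' @param zeros_as_values include zeros as observed values (RNA convention).
#' @return named numeric vector of CVs (NA where undefined).
#' @export
cv_per_feature <- function(m, min_obs = 2, zeros_as_values = FALSE) {
  vals <- as_plain_matrix(m)
  out <- apply(vals, 2, function(x) {
    if (!zeros_as_values) {
      x <- x[!is.na(x)]
    }
    if (length(x) < min_obs) {
      return(NA_real_)
    }
    mu <- mean(x)
    if (mu == 0) NA_real_ else stats::sd(x) / mu
  })
  names(out) <- colnames(m)
  out
}

#' Select the core proteome
#'
#' The stable backbone of the single-cell proteome: among proteins
#' quantified in at least `min_completeness` of all cells (including any
#' perturbed populations), the `k` with the smallest CV are selected
#' (ties broken by protein identifier). If fewer than `k` proteins are
#' eligible, all of them are returned with a warning.
#'
#' @param m filtered, normalized [intensity_matrix()], linear scale.
#' @param min_completeness eligibility threshold (default 0.70).
#' @param k core size (default 200).
#' @return list with `members` (data frame: `protein_group`, `gene`, `cv`,
#'   `completeness`, `mean_intensity`, ordered by CV) and the selection
#'   parameters.
#' @export
select_core_proteome <- function(m, min_completeness = 0.70, k = 200) {
  stopifnot_scalar(min_completeness, "min_completeness", 0, 1)
  stopifnot_scalar(k, "k", lower = 0)
  comp <- colMeans(!is.na(m))
  cvs <- cv_per_feature(m)
  eligible <- comp >= min_completeness & !is.na(cvs)
  if (sum(eligible) < k) {
    warning(sprintf("only %d proteins eligible (< k = %d); returning all",
                    sum(eligible), as.integer(k)))
  }
  idx <- which(eligible)
  ord <- idx[order(cvs[idx], colnames(m)[idx])]
  sel <- utils::head(ord, k)
  members <- data.frame(
    protein_group = colnames(m)[sel],
    gene = unname(genes(m)[sel]),
    cv = unname(cvs[sel]),
    completeness = unname(comp[sel]),
    mean_intensity = unname(colMeans(as_plain_matrix(m), na.rm = TRUE)[sel]),
    stringsAsFactors = FALSE
  )
  list(members = members, min_completeness = min_completeness,
       k = as.integer(k), n_eligible = sum(eligible))
}

#' Completeness profile with the Poisson shot-noise expectation
#'
#' For each feature: the observed detection fraction (proteomics: present;
#' RNA: nonzero), the mean abundance on the requested scale, and the
#' completeness expected if missingness were purely Poisson shot noise,
#' `1 - exp(-mean)`, with the mean on the count scale. For intensity data
#' the Poisson curve is not directly applicable (intensities are not
#' molecule counts) and is emitted on the same pseudo-count scale for
#' plotting parity only.
#'
#' @param m matrix, cells x features.
#' @param zeros_as_values RNA convention: zeros observed, detection =
#'   nonzero; otherwise detection = non-missing.
#' @param abundance_scale `"log1p_mean"` (mean of `ln(1+x)` over detected
#'   entries) or `"count_mean"` (plain mean with zeros included where
#'   applicable).
#' @return data frame per feature: `feature`, `mean_abundance`,
#'   `mean_count` (the scale the Poisson term uses), `observed`, `expected`.
#' @export
completeness_profile <- function(m, zeros_as_values = FALSE,
                                 abundance_scale = c("log1p_mean", "count_mean")) {
  abundance_scale <- match.arg(abundance_scale)
  vals <- as_plain_matrix(m)
  if (zeros_as_values) {
    observed <- colMeans(vals > 0, na.rm = TRUE)
    mean_count <- colMeans(vals, na.rm = TRUE)
    detected_mean <- apply(vals, 2, function(x) {
      x <- x[!is.na(x) & x > 0]
      if (length(x)) mean(log1p(x)) else NA_real_
    })
  } else {
    observed <- colMeans(!is.na(vals))
    mean_count <- colMeans(vals, na.rm = TRUE)
    detected_mean <- apply(vals, 2, function(x) {
      x <- x[!is.na(x)]
      if (length(x)) mean(log1p(x)) else NA_real_
    })
  }
  mean_abundance <- if (abundance_scale == "log1p_mean") detected_mean else
    mean_count
  data.frame(feature = colnames(vals),
             mean_abundance = unname(mean_abundance),
             mean_count = unname(mean_count),
             observed = unname(observed),
             expected = unname(1 - exp(-mean_count)),
             stringsAsFactors = FALSE)
}

#' Mean-versus-CV table
#'
#' Joins [cv_per_feature()] with the per-feature mean abundance, the input
#' for CV-versus-mean scatter plots. Features with fewer than `min_obs`
#' observations are excluded.
#'
#' @param m matrix, cells x features, linear scale.
#' @param min_obs minimum observations per feature (default 2).
#' @param zeros_as_values RNA convention (see [cv_per_feature()]).
#' @return data frame: `feature`, `mean`, `cv`, `n_obs`.
#' @export
cv_vs_mean_table <- function(m, min_obs = 2, zeros_as_values = FALSE) {
  vals <- as_plain_matrix(m)
  cvs <- cv_per_feature(vals, min_obs = min_obs,
                        zeros_as_values = zeros_as_values)
  means <- if (zeros_as_values) colMeans(vals, na.rm = TRUE) else
    colMeans(vals, na.rm = TRUE)
  n_obs <- if (zeros_as_values) colSums(!is.na(vals)) else colSums(!is.na(vals))
  keep <- !is.na(cvs)
  data.frame(feature = colnames(vals)[keep],
             mean = unname(means[keep]),
             cv = unname(cvs[keep]),
             n_obs = unname(n_obs[keep]),
             stringsAsFactors = FALSE)
}
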