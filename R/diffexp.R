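#' SAM d statistic for two groups
#'
#' The moderated t-like statistic
#' `d = (mean_a - mean_b) / (s + s0)` where `s` is the classical pooled
#' two-sample standard error and `s0` a small positive offset that
#' stabilizes the variance estimate of low-variance features. At `s0 = 0`
#' the statistic reduces exactly to the pooled-variance Student t.
#'
#' @param group_a,group_b numeric vectors (>= 2 values each).
#' @param s0 variance-stabilizing offset (default 0.3).
#' @return the d statistic (scalar).
#' @examples
#' sam_statistic(c(1, 2, 3), c(3, 4, 5), s0 = 0.3)
#' @export
sam_statistic <- function(group_a, group_b, s0 = 0.3) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  na <- length(group_a)
  nb <- length(group_b)
  if (na < 2 || nb < 2) {
    return(NA_real_)
  }
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  (mean(group_a) - mean(group_b)) / (se + s0)
}

# Vectorized per-protein two-group moments on a cells x proteins matrix.
# Returns a list of per-protein summary vectors; proteins with < 2
# observations in a group get NA statistics.
group_stats <- function(vals, in_a, in_b, s0 = 0, welch = FALSE) {
  a <- vals[in_a, , drop = FALSE]
  b <- vals[in_b, , drop = FALSE]
  na <- colSums(!is.na(a))
  nb <- colSums(!is.na(b))
  mean_a <- colMeans(a, na.rm = TRUE)
  mean_b <- colMeans(b, na.rm = TRUE)
  var_a <- apply(a, 2, stats::var, na.rm = TRUE)
  var_b <- apply(b, 2, stats::var, na.rm = TRUE)
  ok <- na >= 2 & nb >= 2
  if (welch) {
    se2 <- var_a / na + var_b / nb
    df <- se2^2 / ((var_a / na)^2 / (na - 1) + (var_b / nb)^2 / (nb - 1))
    se <- sqrt(se2)
  } else {
    sp2 <- ((na - 1) * var_a + (nb - 1) * var_b) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  diff <- mean_a - mean_b
  t_stat <- ifelse(ok & se > 0, diff / se, NA_real_)
  d_stat <- ifelse(ok & (se + s0) > 0, diff / (se + s0), NA_real_)
  p <- ifelse(is.na(t_stat), NA_real_, 2 * stats::pt(-abs(t_stat), df))
  list(n_a = na, n_b = nb, mean_a = mean_a, mean_b = mean_b, diff = diff,
       t = t_stat, d = d_stat, p = p, ok = ok)
}

#' Per-protein two-sided unpaired t-test with BH correction
#'
#' Tests every protein with sufficient coverage for a mean difference
#' between two groups on the (log-transformed) matrix. Proteins are kept
#' for testing if their quantification completeness is at least
#' `min_group_completeness` in at least one of the two groups (default 50%);
#' proteins with fewer than two observations in either group are untested.
#' P-values are Benjamini-Hochberg adjusted over the tested proteins.
#'
#' @param m log-transformed [intensity_matrix()] or matrix.
#' @param labels per-cell group labels (exactly two distinct values).
#' @param s0 SAM offset carried into the `d` column (default 0.3).
#' @param min_group_completeness within-group completeness filter.
#' @param welch use Welch's unequal-variance t instead of pooled (default
#'   pooled, the classical SAM convention).
#' @param verbose log how many proteins were filtered/untested.
#' @return data frame, one row per filtered-in protein: group sizes, group
#'   means, `diff` (mean difference on the input scale), `log2fc`
#'   (`diff / log(2)` for natural-log input), `t`, `d`, `p`, `q`.
#' @export
t_test_per_protein <- function(m, labels, s0 = 0.3,
                               min_group_completeness = 0.5,
                               welch = FALSE, verbose = FALSE) {
  groups <- unique(labels)
  if (length(groups) != 2) {
    stop("`labels` must contain exactly two groups", call. = FALSE)
  }
  vals <- as_plain_matrix(m)
  in_a <- labels == groups[1]
  in_b <- labels == groups[2]
  comp_a <- colMeans(!is.na(vals[in_a, , drop = FALSE]))
  comp_b <- colMeans(!is.na(vals[in_b, , drop = FALSE]))
  tested <- pmax(comp_a, comp_b) >= min_group_completeness
  if (verbose) {
    message(sprintf("diffexp: %d/%d proteins pass the %.0f%% within-one-group filter",
                    sum(tested), ncol(vals), 100 * min_group_completeness))
  }
  sub <- vals[, tested, drop = FALSE]
  st <- group_stats(sub, in_a, in_b, s0 = s0, welch = welch)
  res <- data.frame(
    protein_group = colnames(sub),
    gene = unname(genes(m)[tested]),
    n_a = st$n_a, n_b = st$n_b,
    mean_a = st$mean_a, mean_b = st$mean_b,
    diff = st$diff, log2fc = st$diff / log(2),
    t = st$t, d = st$d, p = st$p,
    stringsAsFactors = FALSE
  )
  res$q <- stats::p.adjust(res$p, method = "BH")
  if (verbose && anyNA(res$t)) {
    message(sprintf("diffexp: %d protein(s) untested (< 2 observations in a group)",
                    sum(is.na(res$t))))
  }
  attr(res, "groups") <- groups
  res
}

#' Permutation-based FDR control on the SAM statistic
#'
#' Estimates a significance threshold on `|d|` by shuffling group labels:
#' for a candidate threshold t, `FDR(t)` is the mean number of permutation
#' statistics with `|d*| >= t` divided by the observed count with
#' `|d| >= t`. The smallest threshold with `FDR <= fdr_target` is chosen
#' and proteins at or above it are flagged. When the number of distinct
#' label assignments is smaller than `n_permutations`, all are enumerated
#' exactly.
#'
#' @param m log-transformed matrix ([intensity_matrix()] or plain).
#' @param labels per-cell group labels (two groups).
#' @param s0 SAM offset (default 0.3).
#' @param fdr_target target FDR (default 0.05).
#' @param n_permutations label shuffles (default 250).
#' @param min_group_completeness within-group completeness filter.
#' @param seed integer seed for the shuffles.
#' @return the [t_test_per_protein()] table with extra columns
#'   `significant` (logical) and attributes `d_threshold`, `fdr_table`
#'   (candidate thresholds with estimated FDR) and `n_permutations_used`.
#'   If no threshold achieves the target, nothing is flagged.
#' @export
permutation_fdr <- function(m, labels, s0 = 0.3, fdr_target = 0.05,
                            n_permutations = 250,
                            min_group_completeness = 0.5, seed = 1) {
  stopifnot_scalar(fdr_target, "fdr_target", 1e-12, 1 - 1e-12)
  if (n_permutations < 10) {
    stop("need at least 10 permutations", call. = FALSE)
  }
  res <- t_test_per_protein(m, labels, s0 = s0,
                            min_group_completeness = min_group_completeness)
  groups <- attr(res, "groups")
  vals <- as_plain_matrix(m)[, res$protein_group, drop = FALSE]
  n <- length(labels)
  n_a <- sum(labels == groups[1])

  n_distinct <- choose(n, n_a)
  if (n_distinct <= n_permutations) {
    combos <- utils::combn(n, n_a, simplify = FALSE)
    perms <- lapply(combos, function(idx) {
      lab <- rep(groups[2], n)
      lab[idx] <- groups[1]
      lab
    })
  } else {
    perms <- with_seed(seed, {
      lapply(seq_len(n_permutations), function(i) sample(labels))
    })
  }

  d_obs <- abs(res$d)
  d_perm <- vapply(perms, function(lab) {
    abs(group_stats(vals, lab == groups[1], lab == groups[2], s0 = s0)$d)
  }, numeric(nrow(res)))
  if (is.null(dim(d_perm))) {
    d_perm <- matrix(d_perm, nrow = nrow(res))
  }

  cand <- sort(unique(d_obs[!is.na(d_obs)]))
  fdr_tab <- data.frame(threshold = cand, fdr = NA_real_)
  d_perm_v <- as.vector(d_perm[!is.na(d_perm)])
  n_perm_used <- length(perms)
  for (i in seq_along(cand)) {
    n_obs_hits <- sum(d_obs >= cand[i], na.rm = TRUE)
    mean_perm_hits <- sum(d_perm_v >= cand[i]) / n_perm_used
    fdr_tab$fdr[i] <- mean_perm_hits / n_obs_hits
  }
  ok <- which(fdr_tab$fdr <= fdr_target)
  if (length(ok)) {
    thr <- fdr_tab$threshold[min(ok)]
    res$significant <- !is.na(d_obs) & d_obs >= thr
  } else {
    thr <- Inf
    res$significant <- rep(FALSE, nrow(res))
    message("permutation_fdr: no |d| threshold achieves the target FDR; nothing flagged")
  }
  attr(res, "d_threshold") <- thr
  attr(res, "fdr_table") <- fdr_tab
  attr(res, "n_permutations_used") <- n_perm_used
  res
}

#' Grouped log2 fragment-intensity profiles
#'
#' Builds boxplot-style summaries of fragment-ion intensities per protein
#' and group, as used to visualize differential proteins at the fragment
#' level. Optionally applies one median-ratio normalization factor per cell
#' (estimated on the cells x fragments matrix) to cancel cell-size
#' dependent abundance changes, then log2-transforms.
#'
#' @param report long fragment report (columns `cell_id`, `protein_group`,
#'   `peptide`, `fragment`, `intensity`; see [generate_fragment_report()]).
#' @param labels named per-cell group labels (names = cell ids), or a
#'   vector aligned with the unique cells of the report.
#' @param normalize apply per-cell median-ratio factors first (default TRUE).
#' @param proteins optional subset of protein groups (default all).
#' @return data frame with one row per (protein_group, fragment, group):
#'   `n`, `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi` (whiskers at
#'   1.5 x IQR, clipped to the data range) of the log2 intensities.
#' @export
fragment_profiles <- function(report, labels, normalize = TRUE,
                              proteins = NULL) {
  need <- c("cell_id", "protein_group", "fragment", "intensity")
  if (!all(need %in% names(report))) {
    stop("report must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(report[c("cell_id", "fragment")])) {
    stop("(cell, fragment) pairs must be unique", call. = FALSE)
  }
  cells <- unique(report$cell_id)
  if (!is.null(names(labels))) {
    labels <- labels[cells]
  } else if (length(labels) != length(cells)) {
    stop("`labels` must be named by cell id or aligned with the report's cells",
         call. = FALSE)
  }

  intens <- report$intensity
  if (normalize) {
    # cells x fragments matrix for factor estimation
    frags <- unique(report$fragment)
    fm <- matrix(NA_real_, length(cells), length(frags),
                 dimnames = list(cells, frags))
    fm[cbind(match(report$cell_id, cells), match(report$fragment, frags))] <-
      intens
    ref <- apply(fm, 2, stats::median, na.rm = TRUE)
    factors <- exp(apply(sweep(log(fm), 2, log(ref), "-"), 1,
                         stats::median, na.rm = TRUE))
    factors[!is.finite(factors)] <- 1
    intens <- intens / factors[match(report$cell_id, cells)]
  }
  lg <- log2(intens)

  sub <- data.frame(protein_group = report$protein_group,
                    fragment = report$fragment,
                    group = labels[match(report$cell_id, cells)],
                    value = lg, stringsAsFactors = FALSE)
  if (!is.null(proteins)) {
    sub <- sub[sub$protein_group %in% proteins, , drop = FALSE]
  }
  if (nrow(sub) == 0) {
    return(data.frame(protein_group = character(0), fragment = character(0),
                      group = character(0), n = integer(0), median = numeric(0),
                      q1 = numeric(0), q3 = numeric(0),
                      whisker_lo = numeric(0), whisker_hi = numeric(0)))
  }
  keys <- interaction(sub$protein_group, sub$fragment, sub$group, drop = TRUE)
  pieces <- split(sub, keys)
  out <- do.call(rbind, lapply(pieces, function(d) {
    qs <- stats::quantile(d$value, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- qs[3] - qs[1]
    lo_fence <- qs[1] - 1.5 * iqr
    hi_fence <- qs[3] + 1.5 * iqr
    data.frame(protein_group = d$protein_group[1], fragment = d$fragment[1],
               group = d$group[1], n = nrow(d), median = qs[2],
               q1 = qs[1], q3 = qs[3],
               whisker_lo = min(d$value[d$value >= lo_fence]),
               whisker_hi = max(d$value[d$value <= hi_fence]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$protein_group, out$fragment, out$group), ]
}
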