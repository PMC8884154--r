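# Fixtures are generated in code; no binary data ships with the package.

# A small two-stage cohort for module tests.
small_cohort <- function(seed = 42, cells = 40, proteins = 300,
                         stages = c(G1 = 1, G2 = 1.8)) {
  generate_proteome_cohort(proteome_sim_config(
    n_cells_per_stage = stats::setNames(rep(cells, length(stages)), names(stages)),
    stage_size_factors = stages,
    n_proteins = proteins,
    seed = seed))
}

# Random intensity matrix with a given missing fraction (MCAR, for tests
# that need controlled missingness rather than the MNAR generator).
random_intensity <- function(n_cells, n_proteins, missing = 0.3, seed = 1) {
  withr::with_seed(seed, {
    vals <- matrix(rlnorm(n_cells * n_proteins, meanlog = 8, sdlog = 1.5),
                   nrow = n_cells,
                   dimnames = list(sprintf("c%03d", seq_len(n_cells)),
                                   sprintf("P%04d", seq_len(n_proteins))))
    vals[runif(length(vals)) < missing] <- NA_real_
    intensity_matrix(vals)
  })
}

# Independent brute-force CV: plain loop, sd/mean over non-missing entries.
brute_force_cv <- function(m) {
  m <- unclass(m)
  out <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    x <- x[!is.na(x)]
    out[j] <- if (length(x) >= 2) sd(x) / mean(x) else NA_real_
  }
  out
}

# Independent AUC oracle: average over all (positive, negative) pairs of
# the indicator that the positive scores higher, ties counting one half.
brute_force_auc <- function(scores, positives) {
  sp <- scores[positives]
  sn <- scores[!positives]
  tot <- 0
  for (a in sp) {
    for (b in sn) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(sp) * length(sn))
}

# Independent BH oracle: step-up adjustment written out directly.
brute_force_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(ord)]
}
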