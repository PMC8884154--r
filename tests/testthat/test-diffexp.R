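test_that("SAM statistic matches hand computation and definitional limits", {
  expect_equal(sam_statistic(c(1, 2, 3), c(1, 2, 3), s0 = 0.3), 0)
  # a = (1,2,3), b = (3,4,5): mean diff -2, pooled SE sqrt(1 * (1/3 + 1/3))
  d <- sam_statistic(c(1, 2, 3), c(3, 4, 5), s0 = 0.3)
  expect_equal(d, -2 / (sqrt(2 / 3) + 0.3), tolerance = 1e-12)
  expect_equal(d, -1.7913, tolerance = 1e-4)

  for (seed in 1:5) {
    withr::with_seed(seed, {
      a <- rnorm(6)
      b <- rnorm(9, mean = 1)
      t_ref <- t.test(a, b, var.equal = TRUE)$statistic
      expect_equal(sam_statistic(a, b, s0 = 0), unname(t_ref), tolerance = 1e-12)
      # antisymmetry and s0 monotonicity
      expect_equal(sam_statistic(a, b, 0.3), -sam_statistic(b, a, 0.3),
                   tolerance = 1e-12)
      expect_lte(abs(sam_statistic(a, b, 0.5)), abs(sam_statistic(a, b, 0.2)))
    })
  }
  expect_true(is.na(sam_statistic(1, c(1, 2), 0.3)))
})

make_two_group_matrix <- function(n_per_group, n_proteins, effect = 0,
                                  n_effect = 0, seed = 1) {
  withr::with_seed(seed, {
    vals <- matrix(rnorm(2 * n_per_group * n_proteins, mean = 10),
                   nrow = 2 * n_per_group,
                   dimnames = list(sprintf("c%03d", seq_len(2 * n_per_group)),
                                   sprintf("P%04d", seq_len(n_proteins))))
    if (n_effect > 0) {
      vals[seq_len(n_per_group), seq_len(n_effect)] <-
        vals[seq_len(n_per_group), seq_len(n_effect)] + effect
    }
    labels <- rep(c("A", "B"), each = n_per_group)
    list(m = vals, labels = labels)
  })
}

test_that("per-protein q-values reproduce an independent BH computation", {
  tg <- make_two_group_matrix(8, 50, seed = 3)
  res <- t_test_per_protein(tg$m, tg$labels)
  expect_equal(res$q, brute_force_bh(res$p), tolerance = 1e-12)
  expect_true(all(res$q <= 1))
  # q monotone in p order
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-15))
})

test_that("p-values are uniform under the null", {
  tg <- make_two_group_matrix(10, 1000, seed = 5)
  res <- t_test_per_protein(tg$m, tg$labels)
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the within-one-group completeness filter gates testing", {
  vals <- matrix(rnorm(40, 10), 10, 4,
                 dimnames = list(paste0("c", 1:10), paste0("P", 1:4)))
  labels <- rep(c("A", "B"), each = 5)
  vals[c(1:3, 6:8), 1] <- NA   # 40% / 40%: filtered out
  vals[6:9, 2] <- NA           # 100% / 20%: kept (one group passes)
  res <- t_test_per_protein(vals, labels, min_group_completeness = 0.5)
  expect_false("P1" %in% res$protein_group)
  expect_true("P2" %in% res$protein_group)

  # zero-variance identical groups are untested rather than p = 0
  const <- matrix(5, 6, 2, dimnames = list(paste0("c", 1:6), c("Pa", "Pb")))
  res2 <- t_test_per_protein(const, rep(c("A", "B"), each = 3))
  expect_true(all(is.na(res2$t)))
})

test_that("log2 fold-change is the mean difference in log2 units", {
  vals <- matrix(c(rep(4, 4), rep(2, 4)), 8, 1,
                 dimnames = list(paste0("c", 1:8), "P1"))
  res <- t_test_per_protein(vals, rep(c("A", "B"), each = 4),
                            min_group_completeness = 0)
  expect_equal(res$diff, 2)
  expect_equal(res$log2fc, 2 / log(2), tolerance = 1e-12)
})

test_that("a strong single effect among many nulls is flagged", {
  tg <- make_two_group_matrix(6, 1000, effect = 10, n_effect = 1, seed = 7)
  res <- permutation_fdr(tg$m, tg$labels, n_permutations = 64, seed = 9)
  expect_true(res$significant[res$protein_group == "P0001"])
  expect_lt(sum(res$significant), 20)
})

test_that("permutation FDR controls the realized false discovery proportion", {
  fdp <- vapply(1:20, function(rep_seed) {
    tg <- make_two_group_matrix(5, 120, seed = 100 + rep_seed)
    res <- suppressMessages(
      permutation_fdr(tg$m, tg$labels, n_permutations = 60,
                      seed = 200 + rep_seed))
    n_flagged <- sum(res$significant)
    if (n_flagged == 0) 0 else 1  # every flag is false under the null
  }, numeric(1))
  mc_se <- sd(fdp) / sqrt(length(fdp))
  expect_lte(mean(fdp), 0.05 + 2 * max(mc_se, 0.05))
})

test_that("permutation flags are seed-deterministic and enumerate small designs", {
  tg <- make_two_group_matrix(4, 60, effect = 6, n_effect = 3, seed = 11)
  r1 <- permutation_fdr(tg$m, tg$labels, n_permutations = 250, seed = 13)
  r2 <- permutation_fdr(tg$m, tg$labels, n_permutations = 250, seed = 13)
  expect_identical(r1$significant, r2$significant)
  # choose(8, 4) = 70 < 250: all label assignments enumerated exactly
  expect_equal(attr(r1, "n_permutations_used"), 70)
})

test_that("fragment profiles log2-transform and summarize like a boxplot", {
  rep_df <- data.frame(cell_id = c("c1", "c2"), protein_group = "P1",
                       peptide = "P1_pep1", fragment = "P1_pep1_f1",
                       intensity = c(4, 8))
  out <- fragment_profiles(rep_df, labels = c(c1 = "A", c2 = "A"),
                           normalize = FALSE)
  expect_equal(out$median, median(c(2, 3)))
  expect_equal(out$n, 2)

  withr::with_seed(15, {
    vals <- rlnorm(40, 5, 1)
    rep2 <- data.frame(cell_id = paste0("c", 1:40), protein_group = "PX",
                       peptide = "PX_p1", fragment = "PX_p1_f1",
                       intensity = vals)
    out2 <- fragment_profiles(rep2, labels = setNames(rep("A", 40),
                                                      paste0("c", 1:40)),
                              normalize = FALSE)
    lg <- log2(vals)
    qs <- quantile(lg, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- qs[3] - qs[1]
    expect_equal(out2$q1, qs[1])
    expect_equal(out2$median, qs[2])
    expect_equal(out2$q3, qs[3])
    expect_equal(out2$whisker_lo, min(lg[lg >= qs[1] - 1.5 * iqr]))
    expect_equal(out2$whisker_hi, max(lg[lg <= qs[3] + 1.5 * iqr]))
  })
})

test_that("per-cell normalization cancels a 2x scaling of a cell", {
  # rank-one design: intensity = cell size x fragment response, so the
  # median-ratio factor recovers each cell size exactly
  sizes <- c(1, 2, 3, 4, 5)
  resp <- c(f1 = 1, f2 = 0.5, f3 = 8, f4 = 2)
  grid <- expand.grid(cell_id = paste0("c", 1:5), fragment = names(resp),
                      stringsAsFactors = FALSE)
  grid$protein_group <- "P1"
  grid$peptide <- "P1_p1"
  grid$intensity <- sizes[as.integer(sub("c", "", grid$cell_id))] *
    resp[grid$fragment]
  labels <- setNames(c("A", "A", "A", "B", "B"), paste0("c", 1:5))
  base <- fragment_profiles(grid, labels, normalize = TRUE)

  scaled <- grid
  doubled <- scaled$cell_id == "c5"  # stays above the median cell
  scaled$intensity[doubled] <- scaled$intensity[doubled] * 2
  out <- fragment_profiles(scaled, labels, normalize = TRUE)
  expect_equal(out$median, base$median, tolerance = 1e-12)
  expect_equal(out$q1, base$q1, tolerance = 1e-12)
  expect_equal(out$whisker_hi, base$whisker_hi, tolerance = 1e-12)
})

test_that("duplicate (cell, fragment) pairs are rejected", {
  bad <- data.frame(cell_id = c("c1", "c1"), protein_group = "P1",
                    peptide = "p", fragment = "f", intensity = c(1, 2))
  expect_error(fragment_profiles(bad, labels = c(c1 = "A")), "unique")
})
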