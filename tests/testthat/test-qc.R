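# Build a matrix where cell i has a prescribed number of quantified proteins.
matrix_with_counts <- function(counts, n_proteins) {
  vals <- matrix(NA_real_, length(counts), n_proteins,
                 dimnames = list(paste0("c", seq_along(counts)),
                                 paste0("P", seq_len(n_proteins))))
  for (i in seq_along(counts)) {
    if (counts[i] > 0) vals[i, seq_len(counts[i])] <- 10
  }
  intensity_matrix(vals)
}

test_that("cell filter is inclusive at the threshold and idempotent", {
  m <- matrix_with_counts(c(100, 599, 600, 601, 2000), 2000)
  out <- filter_cells(m, 600)
  # brute-force count of qualifying cells
  expect_equal(nrow(out), sum(c(100, 599, 600, 601, 2000) >= 600))
  expect_setequal(rownames(out), c("c3", "c4", "c5"))
  expect_equal(ncol(out), 2000)
  expect_identical(filter_cells(out, 600), out)
  expect_identical(filter_cells(m, 0), m)
})

test_that("feature filter keeps proteins at or above the completeness fraction", {
  vals <- matrix(NA_real_, 10, 3,
                 dimnames = list(paste0("c", 1:10), c("seen1", "seen2", "full")))
  vals[1, "seen1"] <- 5          # 10% complete
  vals[1:2, "seen2"] <- 5        # 20% complete
  vals[, "full"] <- 5
  m <- intensity_matrix(vals)
  out <- filter_features(m, 0.15)
  expect_setequal(colnames(out), c("seen2", "full"))
  expect_identical(filter_features(m, 0), m)
  expect_equal(colnames(filter_features(m, 1)), "full")
})

test_that("CV filter is strict at the cutoff and drops undefined CVs", {
  vals <- matrix(NA_real_, 2, 3,
                 dimnames = list(c("a", "b"), c("const", "spread", "single")))
  vals[, "const"] <- 4
  vals[, "spread"] <- c(1, 3)    # CV = sqrt(2)/2 = 0.7071
  vals["a", "single"] <- 9
  m <- intensity_matrix(vals)
  expect_equal(brute_force_cv(m)[2], sqrt(2) / 2, tolerance = 1e-12)
  expect_setequal(colnames(filter_feature_cv(m, 0.75)), c("const", "spread"))
  expect_equal(colnames(filter_feature_cv(m, 0.70)), "const")
  expect_false("single" %in% colnames(filter_feature_cv(m, 10)))
})

test_that("the QC funnel applied to its own output changes nothing", {
  co <- small_cohort(seed = 21, cells = 60, proteins = 500)
  funnel <- function(m) {
    filter_feature_cv(filter_features(filter_cells(m, 150), 0.15), 0.75)
  }
  once <- funnel(co$intensities)
  expect_identical(funnel(once), once)
})

test_that("log1p transform matches its analytic inverse and keeps missingness", {
  vals <- matrix(c(exp(1) - 1, NA, 4, 9), 2, 2,
                 dimnames = list(c("a", "b"), c("P1", "P2")))
  m <- intensity_matrix(vals)
  lg <- log1p_transform(m)
  expect_equal(unclass(lg)["a", "P1"], 1)
  expect_true(is.na(lg["b", "P1"]))
  expect_equal(expm1(unclass(lg)[, ]), unclass(m)[, ], tolerance = 1e-12)
  expect_error(log1p_transform(matrix(-1)), "non-negative")
})

test_that("median-ratio normalization equalizes scaled cells", {
  vals <- matrix(rlnorm(200, 8, 1), 2, 100, byrow = TRUE,
                 dimnames = list(c("a", "b"), paste0("P", 1:100)))
  vals["b", ] <- vals["a", ] * 2
  m <- intensity_matrix(vals)
  res <- normalize_cells_median_ratio(m)
  expect_equal(unname(res$factors["b"] / res$factors["a"]), 2, tolerance = 1e-12)
  expect_equal(unclass(res$normalized)["a", ], unclass(res$normalized)["b", ],
               tolerance = 1e-12)

  ident <- intensity_matrix(matrix(c(5, 5, 7, 7), 2, 2,
                                   dimnames = list(c("x", "y"), c("P1", "P2"))))
  expect_equal(unname(normalize_cells_median_ratio(ident)$factors), c(1, 1))
})

test_that("after normalization every cell's median log-ratio to the reference is zero", {
  m <- random_intensity(100, 500, missing = 0.35, seed = 9)
  res <- normalize_cells_median_ratio(m)
  ref <- apply(unclass(m), 2, median, na.rm = TRUE)
  for (i in seq_len(nrow(m))) {
    lr <- log(unclass(res$normalized)[i, ] / ref)
    expect_lt(abs(median(lr, na.rm = TRUE)), 1e-9)
  }
})

test_that("normalization never creates or destroys missingness", {
  m <- random_intensity(30, 80, missing = 0.5, seed = 10)
  res <- normalize_cells_median_ratio(m)
  expect_identical(is.na(unclass(res$normalized)), is.na(unclass(m)))
})

test_that("imputed values follow the downshifted normal moments", {
  m <- random_intensity(200, 1000, missing = 0.4, seed = 12)
  lg <- log1p_transform(m)
  obs <- unclass(lg)[!is.na(lg)]
  full <- impute_downshifted_normal(lg, width = 0.3, downshift = 1.8,
                                    scope = "global", seed = 55)
  imp <- unclass(full)[is.na(unclass(lg))]
  n <- length(imp)
  target_mean <- mean(obs) - 1.8 * sd(obs)
  target_sd <- 0.3 * sd(obs)
  expect_lt(abs(mean(imp) - target_mean), 3 * target_sd / sqrt(n))
  expect_lt(abs(sd(imp) - target_sd), 3 * target_sd / sqrt(2 * n))
  # observed entries untouched, nothing left missing
  expect_identical(unclass(full)[!is.na(unclass(lg))], obs)
  expect_false(anyNA(full))
})

test_that("per-cell imputation uses each cell's own observed moments", {
  m <- random_intensity(40, 2000, missing = 0.5, seed = 14)
  lg <- log1p_transform(m)
  full <- impute_downshifted_normal(lg, scope = "per_cell", seed = 77)
  i <- 1
  obs_i <- unclass(lg)[i, !is.na(unclass(lg)[i, ])]
  imp_i <- unclass(full)[i, is.na(unclass(lg)[i, ])]
  expect_lt(abs(mean(imp_i) - (mean(obs_i) - 1.8 * sd(obs_i))),
            4 * 0.3 * sd(obs_i) / sqrt(length(imp_i)))
})

test_that("imputation is a no-op on complete matrices and seed-deterministic", {
  complete <- intensity_matrix(matrix(c(1, 2, 3, 4), 2, 2,
                                      dimnames = list(c("a", "b"), c("P1", "P2"))))
  expect_identical(impute_downshifted_normal(complete, seed = 1), complete)
  m <- log1p_transform(random_intensity(20, 100, missing = 0.3, seed = 16))
  expect_identical(impute_downshifted_normal(m, seed = 5),
                   impute_downshifted_normal(m, seed = 5))
})

test_that("total signal per cell sums present intensities and is additive", {
  vals <- matrix(c(7, NA, 2, 3), 2, 2,
                 dimnames = list(c("a", "b"), c("P1", "P2")))
  ts <- total_signal_per_cell(intensity_matrix(vals))
  expect_equal(unname(ts), c(7 + 2, 3))
  empty <- intensity_matrix(matrix(NA_real_, 1, 2,
                                   dimnames = list("z", c("P1", "P2"))))
  expect_equal(unname(total_signal_per_cell(empty)), 0)

  m <- small_cohort(seed = 18, cells = 10, proteins = 50)$intensities
  split_sum <- total_signal_per_cell(m[, 1:20]) + total_signal_per_cell(m[, 21:50])
  expect_equal(split_sum, total_signal_per_cell(m), tolerance = 1e-12)
})

test_that("RNA filtering is strict below the gene threshold and scales to target", {
  counts <- matrix(0L, 3, 700,
                   dimnames = list(c("keep600", "drop599", "rich"),
                                   paste0("g", 1:700)))
  counts["keep600", 1:600] <- 1L
  counts["drop599", 1:599] <- 1L
  counts["rich", ] <- 1L
  out <- rna_filter_and_scale(counts, min_genes = 600, min_cell_fraction = 0,
                              log_transform = FALSE)
  expect_setequal(out$cells, c("keep600", "rich"))

  toy <- matrix(c(10, 20, 30), 3, 1, dimnames = list(c("a", "b", "c"), "g1"))
  scaled <- rna_filter_and_scale(toy, min_genes = 0, min_cell_fraction = 0,
                                 target = "mean_cell_size", log_transform = FALSE)
  expect_equal(unname(rowSums(scaled$matrix)), c(20, 20, 20))
  million <- rna_filter_and_scale(toy, min_genes = 0, min_cell_fraction = 0,
                                  target = "1e6", log_transform = FALSE)
  expect_equal(unname(rowSums(million$matrix)), rep(1e6, 3))
})

test_that("RNA gene filter removes genes detected in too few cells", {
  counts <- matrix(c(1L, 1L, 1L, 0L, 0L, 0L,
                     1L, 1L, 1L, 1L, 1L, 1L), 6, 2,
                   dimnames = list(paste0("c", 1:6), c("rare", "common")))
  out <- rna_filter_and_scale(counts, min_genes = 0, min_cell_fraction = 0.6,
                              log_transform = FALSE)
  expect_equal(out$genes, "common")
})
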