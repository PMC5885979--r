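test_that("size-factor correlations behave as rank and linear measures", {
  expect_equal(sizefactor_correlation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(sizefactor_correlation(c(1, 2, 3), c(1, 2, 3),
                                      method = "pearson"), 1)
  expect_equal(sizefactor_correlation(c(1, 2, 3), c(3, 2, 1)), -1)
  # monotone transform: rank correlation stays 1, linear drops below
  x <- c(1, 2, 5, 9)
  expect_equal(sizefactor_correlation(exp(x), x), 1)
  expect_lt(sizefactor_correlation(exp(x), x, method = "pearson"), 1)
  expect_true(is.na(sizefactor_correlation(c(2, 2, 2), c(1, 2, 3))))
  # named alignment follows sample ids
  sf <- size_factors(c(a = 1, b = 2, c = 3), method = "TSS")
  expect_equal(sizefactor_correlation(sf, c(c = 3, a = 1, b = 2)), 1)
})

test_that("the perturbation benchmark is reproducible and complete", {
  a <- run_perturbation_benchmark(zero_targets = 0.6, fractions = c(0, 0.32),
                                  methods = c("GMPR", "TSS"), reps = 3,
                                  q = 150, n = 20, seed = 71)
  b <- run_perturbation_benchmark(zero_targets = 0.6, fractions = c(0, 0.32),
                                  methods = c("GMPR", "TSS"), reps = 3,
                                  q = 150, n = 20, seed = 71)
  expect_identical(a, b)
  expect_equal(nrow(a), 4L)  # 2 fractions x 2 methods
  # GMPR always returns: n_ok equals reps in every cell
  expect_true(all(a$n_ok[a$method == "GMPR"] == 3L))
  expect_true(all(a$ci_lo <= a$mean_cor & a$mean_cor <= a$ci_hi))
  expect_true(all(abs(a$mean_cor) <= 1))
})

test_that("RLE failures surface as NA cells, not crashes", {
  # high sparsity at small q: most replicates have no common feature
  rep <- run_perturbation_benchmark(zero_targets = 0.85, fractions = 0,
                                    methods = c("GMPR", "RLE"), reps = 3,
                                    q = 100, n = 25, seed = 72)
  expect_true(all(rep$n_ok[rep$method == "GMPR"] == 3L))
  expect_true(all(rep$n_ok >= 0))
})

test_that("variance ranking puts RAW last on multiplicative data", {
  set.seed(73)
  m <- 1 + rpois(50, 20)
  tabs <- lapply(1:3, function(d) {
    d_i <- exp(rnorm(8, 0, 1))
    count_table(round(outer(m, d_i) * 4))
  })
  res <- variance_rank_analysis(tabs, methods = c("RAW", "GMPR", "TSS"))
  expect_true(all(res$dataset_ranks[, "RAW"] == 3))
  # exact normalizations drive the variance to (near) zero
  expect_true(all(res$median_variance[, "GMPR"] <
                    res$median_variance[, "RAW"]))
  # scale invariance: multiplying one dataset by 10 leaves ranks unchanged
  tabs10 <- tabs
  tabs10[[2]] <- count_table(unclass(tabs[[2]]) * 10)
  res10 <- variance_rank_analysis(tabs10, methods = c("RAW", "GMPR", "TSS"))
  expect_equal(res10$dataset_ranks, res$dataset_ranks)
  # identical methods tie with average ranks
  res_tie <- variance_rank_analysis(tabs[1], methods = c("TSS", "TSS"))
  expect_equal(as.numeric(res_tie$dataset_ranks[1, ]), c(1.5, 1.5))
})

test_that("prevalence strata are near-equal thirds with ordered ties", {
  tab <- count_table(matrix(c(1, 1, 1, 1,
                              1, 1, 0, 0,
                              1, 0, 0, 0), nrow = 3, byrow = TRUE,
                            dimnames = list(paste0("F", 1:3),
                                            paste0("S", 1:4))))
  expect_equal(as.character(prevalence_stratify(tab)),
               c("top", "middle", "bottom"))
  # all features everywhere: degenerate single stratum
  allp <- count_table(matrix(1L, 4, 3))
  expect_true(all(prevalence_stratify(allp) == "top"))
  set.seed(74)
  big <- random_table(31, 10, zero_prob = 0.5)
  sizes <- table(prevalence_stratify(big))
  expect_lte(max(sizes) - min(sizes), 1L)
  expect_error(prevalence_stratify(count_table(matrix(1, 2, 2))),
               "three features")
})

test_that("signed-rank test: hand cases, enumeration oracle, branches", {
  expect_equal(paired_signed_rank(1:6, 1:6), 1)
  expect_equal(paired_signed_rank(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5)),
               0.0625)  # all positive, m = 5: 2 / 2^5
  set.seed(75)
  for (rep in 1:40) {
    m <- sample(3:10, 1)
    a <- sample(1:6, m, replace = TRUE)
    b <- sample(1:6, m, replace = TRUE)
    expect_equal(paired_signed_rank(a, b), brute_signed_rank(a, b),
                 tolerance = 1e-12)
  }
  # no ties: the exact branch agrees with wilcox.test's exact p
  for (rep in 1:10) {
    a <- rnorm(15); b <- rnorm(15)
    expect_equal(paired_signed_rank(a, b),
                 wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # exact (m = 25) and approximate (m = 26) branches agree closely
  for (rep in 1:10) {
    a <- rnorm(26); b <- rnorm(26)
    p_apx <- paired_signed_rank(a, b)
    p_ex <- paired_signed_rank(a[1:25], b[1:25])
    expect_lt(abs(paired_signed_rank(a[1:25], b[1:25]) -
                    wilcox.test(a[1:25], b[1:25], paired = TRUE,
                                exact = FALSE, correct = TRUE)$p.value),
              0.011)
    expect_true(p_apx >= 0 && p_apx <= 1)
  }
})

test_that("ICC recovers variance components of a one-way model", {
  # perfect reproducibility: identical replicates, distinct subjects
  v <- rep(c(1, 5, 9), each = 3)
  s <- rep(letters[1:3], each = 3)
  expect_equal(icc(v, s)$rho, 1)
  # pure noise around a common mean: clamped at 0
  set.seed(76)
  v2 <- rnorm(30)
  s2 <- rep(letters[1:10], each = 3)
  v2 <- v2 - ave(v2, s2) # remove all between-subject signal
  expect_equal(icc(v2, s2)$rho, 0)
  expect_error(icc(1:4, rep("a", 4)), "two subjects")
  # matches the balanced brute-force estimator
  for (rep in 1:20) {
    vals <- rnorm(24, rep(rnorm(8, 0, 2), each = 3))
    subj <- rep(paste0("p", 1:8), each = 3)
    got <- icc(vals, subj)
    want <- brute_icc_balanced(vals, subj)
    expect_equal(got$sigma_b_sq, want$sigma_b_sq, tolerance = 1e-12)
    expect_equal(got$sigma_e_sq, want$sigma_e_sq, tolerance = 1e-12)
    expect_equal(got$rho, want$rho, tolerance = 1e-12)
  }
})

test_that("ICC estimates the true ratio sigma_b^2 / (sigma_b^2 + sigma_e^2)", {
  set.seed(77)
  rhos <- replicate(200, {
    subj_eff <- rnorm(20, 0, sqrt(3))
    vals <- rep(subj_eff, each = 3) + rnorm(60, 0, 1)
    icc(vals, rep(paste0("p", 1:20), each = 3))$rho
  })
  expect_equal(mean(rhos), 0.75, tolerance = 0.03)
})

test_that("size factors from one table transfer to aggregated counts", {
  # the genus-level workflow: factors estimated at feature level, applied
  # to a coarser table with the same samples
  set.seed(78)
  tab <- random_table(40, 6)
  sf <- gmpr_size_factors(tab, min_shared = 1)
  agg <- count_table(rowsum(unclass(tab), rep(1:8, each = 5)),
                     sample_ids = colnames(tab))
  norm <- normalize_counts(agg, sf)
  expect_equal(dim(norm), c(8L, 6L))
  expect_equal(norm[1, ], colSums(unclass(tab)[1:5, ]) / as.numeric(sf),
               ignore_attr = TRUE)
})
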