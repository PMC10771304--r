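test_that("pooled-variance t-test matches the closed form and handles edge cases", {
  a <- c(1, 2, 3); b <- c(1.1, 2.1, 3.1)
  sp <- sqrt((var(a) * 2 + var(b) * 2) / 4)
  t_oracle <- (mean(a) - mean(b)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(t_oracle, -0.1224745, tolerance = 1e-6)
  expect_equal(t_test_pvalue(a, b), 2 * pt(-abs(t_oracle), df = 4),
               tolerance = 1e-10)
  expect_equal(t_test_pvalue(a, a), 1)
  expect_equal(t_test_pvalue(a, b), t_test_pvalue(b, a))
  ## zero pooled variance
  expect_equal(t_test_pvalue(c(2, 2), c(2, 2)), 1)
  expect_equal(t_test_pvalue(c(2, 2), c(3, 3)), 1e-15)
  expect_error(t_test_pvalue(1, c(1, 2)), ">= 2")
})

test_that("rank-sum p is exact by enumeration on tie-free small samples", {
  expect_equal(ranksum_pvalue(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(ranksum_pvalue(c(1, 2, 3), c(1, 2, 3)), 1)
  set.seed(41)
  for (i in 1:25) {
    a <- rnorm(3); b <- rnorm(3)
    expect_equal(ranksum_pvalue(a, b), oracle_ranksum(a, b))
    expect_equal(ranksum_pvalue(a, b), ranksum_pvalue(b, a))
    ## agreement with the standard exact Wilcoxon two-sided p
    expect_equal(ranksum_pvalue(a, b),
                 wilcox.test(a, b, exact = TRUE)$p.value)
  }
})

test_that("rank-sum normal approximation engages on ties and large n", {
  a <- c(1, 1, 2, 3); b <- c(1, 2, 2, 4)   # ties force the approximation
  expect_equal(ranksum_pvalue(a, b),
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
  set.seed(8)
  a <- rnorm(60); b <- rnorm(60)           # choose(120,60) >> 10000
  expect_equal(ranksum_pvalue(a, b),
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("median-difference permutation test matches enumeration", {
  ## degenerate two-valued input: every assignment reaches |T| = 10,
  ## because a 3-sample median is a majority vote
  res <- median_diff_pvalue(c(10, 10, 10), c(0, 0, 0))
  expect_equal(res$p, oracle_median_diff(c(10, 10, 10), c(0, 0, 0)))
  expect_equal(res$p, 1)
  expect_equal(res$sign, 1)
  ## identical groups
  res0 <- median_diff_pvalue(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res0$p, 1)
  expect_equal(res0$sign, 0)
  set.seed(42)
  for (i in 1:25) {
    a <- rnorm(3); b <- rnorm(3)
    res <- median_diff_pvalue(a, b)
    expect_equal(res$p, oracle_median_diff(a, b))
    ## negation flips the sign, preserves p
    neg <- median_diff_pvalue(-a, -b)
    expect_equal(neg$p, res$p)
    expect_equal(neg$sign, -res$sign)
  }
})

test_that("Monte-Carlo median-difference branch is seeded and sane", {
  set.seed(5)
  a <- rnorm(10, 1); b <- rnorm(10)   # choose(20,10) = 184756 > 10000
  r1 <- median_diff_pvalue(a, b, n_mc = 2000, seed = 7)
  r2 <- median_diff_pvalue(a, b, n_mc = 2000, seed = 7)
  expect_identical(r1$p, r2$p)
  expect_gte(r1$p, 1 / 2001)  # add-one correction floor
})

test_that("Stouffer combination matches the closed-form oracle", {
  r <- stouffer_combine(c(1, 1, 1), 1)
  expect_equal(r$z_comb, 0)
  expect_equal(r$p_comb, 1)
  r <- stouffer_combine(c(0.5, 0.5, 0.5), 1)
  expect_equal(r$z_comb, 1.16826, tolerance = 1e-5)
  expect_equal(r$p_comb, 0.24269, tolerance = 1e-4)
  r <- stouffer_combine(c(0.05, 0.05, 0.05), 1)
  expect_equal(r$z_comb, 3.39476, tolerance = 1e-5)
  expect_equal(r$p_comb, 6.87e-4, tolerance = 1e-2)
  ## sign carries through; sign 0 collapses to the null
  expect_equal(stouffer_combine(c(0.05, 0.5, 0.9), -1)$z_comb,
               -stouffer_combine(c(0.05, 0.5, 0.9), 1)$z_comb)
  expect_equal(stouffer_combine(c(0.01, 0.01, 0.01), 0)$p_comb, 1)
  expect_error(stouffer_combine(c(0, 0.5, 0.5), 1), "0, 1")
  expect_error(stouffer_combine(c(0.5, 0.5), 1), "three")
})

test_that("combined p is monotone in each component p-value", {
  grid <- c(0.01, 0.05, 0.2, 0.5, 0.9)
  for (p2 in c(0.05, 0.5)) for (p3 in c(0.1, 0.8)) {
    pc <- vapply(grid, function(p1)
      stouffer_combine(c(p1, p2, p3), 1)$p_comb, numeric(1))
    expect_true(all(diff(pc) >= -1e-12))
  }
})

test_that("Storey q-values reduce to BH with pi0 = 1 and estimate pi0 on nulls", {
  expect_equal(as.numeric(storey_qvalues(0.05)), 0.05)
  expect_equal(attr(storey_qvalues(0.05), "pi0"), 1)  # m too small
  q <- storey_qvalues(c(0.01, 0.02, 0.03, 0.04), pi0 = 1)
  expect_equal(as.numeric(q), rep(0.04, 4))
  set.seed(19)
  for (i in 1:10) {
    p <- runif(sample(50:500, 1))
    expect_equal(as.numeric(storey_qvalues(p, pi0 = 1)),
                 p.adjust(p, "BH"), tolerance = 1e-12)
  }
  set.seed(23)
  p <- runif(10000)
  expect_equal(attr(storey_qvalues(p), "pi0"), 1, tolerance = 0.1)
  ## q is monotone non-decreasing in p rank
  set.seed(31)
  p <- runif(200)
  q <- as.numeric(storey_qvalues(p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(storey_qvalues(numeric(0)), "empty")
})

test_that("log2-median-ratio respects the declared scale", {
  expect_equal(log2_median_ratio(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(log2_median_ratio(c(4, 5, 6), c(2, 3, 4), "log2"), 2)
  expect_equal(log2_median_ratio(c(7, 8, 9), c(1, 2, 3), "linear"), 2)
  expect_error(log2_median_ratio(c(-2, -1, 0), c(1, 2, 3), "linear"),
               "positive")
})

test_that("permutation lmr null enumerates 3-vs-3 exhaustively and matches brute force", {
  sim <- generate_de_experiment(de_plant_spec(n_genes = 40, n_de = 4,
                                              seed = 13))
  null <- permutation_null_lmr(sim$matrix, n_perm = 1000, seed = 13)
  expect_true(null$exhaustive)
  expect_identical(null$n_perm, 20L)
  expect_length(null$pooled_abs_lmr, 40L * 20L)
  ## brute-force oracle: pool |median diff| over all 20 splits by hand
  v <- sim$matrix$values
  idx <- combn(6, 3)
  pool <- as.numeric(sapply(seq_len(20), function(k) {
    ia <- idx[, k]
    abs(apply(v[, ia], 1, median) - apply(v[, -ia], 1, median))
  }))
  expect_equal(sort(null$pooled_abs_lmr), sort(pool), tolerance = 1e-12)
  expect_equal(null$threshold, sort(pool)[ceiling(0.95 * length(pool))])
})

test_that("lmr null threshold is 0 for constant genes and ratio-invariant on linear scale", {
  v <- matrix(5, 10, 6, dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  ann <- data.frame(sample_id = paste0("s", 1:6),
                    group = rep(c("treated", "control"), each = 3))
  em <- expr_matrix(v, "log2", ann)
  expect_equal(permutation_null_lmr(em)$threshold, 0)
  set.seed(2)
  vl <- matrix(2^rnorm(60, 4), 10, 6,
               dimnames = dimnames(v))
  em1 <- expr_matrix(vl, "linear", ann)
  em2 <- expr_matrix(vl * 37.5, "linear", ann)
  expect_equal(permutation_null_lmr(em1)$threshold,
               permutation_null_lmr(em2)$threshold, tolerance = 1e-12)
})

test_that("integrated caller recovers a noise-free planted gene", {
  ## planted fraction kept below 5%: a 3-sample median preserves a
  ## planted shift under label permutation, so planted genes feed their
  ## full effect into the pooled null — with more than 5% of genes
  ## planted the 95th-percentile threshold rises to the effect size
  ## itself (see the methods vignette)
  sim <- generate_de_experiment(
    de_plant_spec(n_genes = 60, n_de = 2, effect_log2 = 1,
                  noise_sd = 1e-6, seed = 21))
  res <- suppressMessages(run_integrated_deg(sim$matrix, seed = 21))
  planted <- which(sim$truth$is_de)
  expect_equal(abs(res$deg$lmr[planted]), rep(1, 2), tolerance = 1e-4)
  expect_true(all(res$deg$is_deg[planted]))
  expect_false(any(res$deg$is_deg[-planted]))
  ## direction follows the planted sign
  expect_identical(res$deg$sign[planted],
                   sign(sim$truth$effect_log2[planted]))
})

test_that("integrated caller output respects the DEG-table invariants", {
  sim <- generate_de_experiment(
    de_plant_spec(n_genes = 200, n_de = 20, seed = 17))
  res <- suppressMessages(run_integrated_deg(sim$matrix, seed = 17))
  d <- res$deg
  expect_true(all(d$p_t > 0 & d$p_t <= 1))
  expect_true(all(d$p_rs > 0 & d$p_rs <= 1))
  expect_true(all(d$p_md > 0 & d$p_md <= 1))
  expect_true(all(d$q >= 0 & d$q <= 1))
  expect_true(all(diff(d$q[order(d$p_comb)]) >= -1e-12))
  expect_true(all(d$is_deg == (d$q < 0.05 & abs(d$lmr) > res$null$threshold)))
  ## determinism under the seed
  res2 <- suppressMessages(run_integrated_deg(sim$matrix, seed = 17))
  expect_identical(res$deg, res2$deg)
  expect_identical(res$null$threshold, res2$null$threshold)
  ## planted genes dominate the q ranking
  expect_lt(median(d$q[sim$truth$is_de]), median(d$q[!sim$truth$is_de]))
})
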