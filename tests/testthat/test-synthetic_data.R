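test_that("DE generator is deterministic and honors the planted design", {
  spec <- de_plant_spec(n_genes = 100, n_de = 10, effect_log2 = 1,
                        noise_sd = 0.25, seed = 3)
  sim1 <- generate_de_experiment(spec)
  sim2 <- generate_de_experiment(spec)
  expect_identical(sim1$matrix$values, sim2$matrix$values)
  expect_identical(sum(sim1$truth$is_de), 10L)
  expect_identical(table(sim1$matrix$annotations$group),
                   table(factor(rep(c("control", "treated"), each = 3))))
  ## alternating signs
  expect_identical(unique(abs(sim1$truth$effect_log2[sim1$truth$is_de])), 1)
  expect_true(any(sim1$truth$effect_log2 < 0) &&
              any(sim1$truth$effect_log2 > 0))
})

test_that("pure-null spec plants nothing", {
  sim <- generate_de_experiment(de_plant_spec(n_genes = 50, n_de = 0,
                                              seed = 1))
  expect_false(any(sim$truth$is_de))
  expect_true(all(sim$truth$effect_log2 == 0))
})

test_that("noise-free limit recovers the planted shift exactly", {
  sim <- generate_de_experiment(
    de_plant_spec(n_genes = 20, n_de = 4, effect_log2 = 1,
                  noise_sd = 1e-9, seed = 2))
  grp <- sim$matrix$annotations$group
  lmr <- apply(sim$matrix$values, 1, function(v)
    median(v[grp == "treated"]) - median(v[grp == "control"]))
  expect_equal(unname(abs(lmr[1:4])), rep(1, 4), tolerance = 1e-6)
})

test_that("planted mean shift is recovered at the Monte-Carlo scale", {
  sim <- generate_de_experiment(
    de_plant_spec(n_genes = 1000, n_de = 100, effect_log2 = 1,
                  noise_sd = 0.25, n_per_group = 3, seed = 7))
  grp <- sim$matrix$annotations$group
  de <- which(sim$truth$is_de)
  shift <- vapply(de, function(g)
    mean(sim$matrix$values[g, grp == "treated"]) -
      mean(sim$matrix$values[g, grp == "control"]), numeric(1))
  expect_equal(mean(abs(shift)), 1, tolerance = 0.1)
})

test_that("cohort generator plants the driver-signature Spearman rho", {
  co <- generate_cohort(cohort_plant_spec(n_patients = 300,
                                          driver_rho = -0.5, seed = 11))
  block_mean <- colMeans(co$matrix$values[co$signature$genes, ])
  est <- cor(co$matrix$values[co$driver_gene, ], block_mean,
             method = "spearman")
  expect_lt(est, 0)
  expect_lt(abs(est - (-0.5)), 0.15)

  null <- generate_cohort(cohort_plant_spec(n_patients = 300,
                                            driver_rho = 0, seed = 11))
  est0 <- cor(null$matrix$values[null$driver_gene, ],
              colMeans(null$matrix$values[null$signature$genes, ]),
              method = "spearman")
  expect_lt(abs(est0), 0.15)
})

test_that("stratified cohorts recover per-stratum ordering", {
  co <- generate_cohort(cohort_plant_spec(
    driver_rho = c(-0.5, 0), strata = c(primary = 150, advanced = 150),
    seed = 4))
  st <- co$matrix$annotations$stratum
  est <- vapply(c("primary", "advanced"), function(s) {
    idx <- st == s
    cor(co$matrix$values[co$driver_gene, idx],
        colMeans(co$matrix$values[co$signature$genes, idx]),
        method = "spearman")
  }, numeric(1))
  expect_lt(est[["primary"]], est[["advanced"]])
  expect_lt(est[["primary"]], -0.3)
})

test_that("cohort spec invariants reject bad configurations", {
  expect_error(cohort_plant_spec(driver_rho = 1), "in \\(-1, 1\\)")
  expect_error(cohort_plant_spec(strata = c(a = 5, b = 100)), "n >= 10")
  expect_error(de_plant_spec(n_genes = 10, n_de = 11), "n_de")
  expect_error(de_plant_spec(n_per_group = 1), "n_per_group")
  expect_error(de_plant_spec(noise_sd = 0), "noise_sd")
})

test_that("qPCR generator plants the fold change on the Ct scale", {
  expect_error(generate_qpcr(planted_fold = 0), "planted_fold")
  ## noise-free limit: estimator returns the planted fold exactly
  tab <- generate_qpcr(planted_fold = 0.5, ct_sd = 1e-9, seed = 3,
                       loading_sd = 0)
  res <- delta_delta_ct(tab, "TARGET1", "GAPDH")
  expect_equal(res$fold_change, 0.5, tolerance = 1e-6)
  ## null fold
  tab1 <- generate_qpcr(planted_fold = 1, ct_sd = 1e-9, seed = 3,
                        loading_sd = 0)
  expect_equal(delta_delta_ct(tab1, "TARGET1", "GAPDH")$ddct, 0,
               tolerance = 1e-6)
  ## recovery at validation-scale n with realistic noise
  tab2 <- generate_qpcr(planted_fold = 0.5, ct_sd = 0.2, n_per_group = 3,
                        seed = 3)
  expect_equal(delta_delta_ct(tab2, "TARGET1", "GAPDH")$fold_change, 0.5,
               tolerance = 0.15)
})

test_that("identical spec and seed give byte-identical written bundles", {
  cfg <- list(seed = 9L,
              simulate = list(experiment = list(n_genes = 40, n_de = 4)))
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  p1 <- simulate_inputs(read_run_config(c(cfg, out_dir = d1)))
  p2 <- simulate_inputs(read_run_config(c(cfg, out_dir = d2)))
  for (k in names(p1))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
  ## different seeds differ
  d3 <- file.path(tempfile(), "c")
  cfg$seed <- 10L
  p3 <- simulate_inputs(read_run_config(c(cfg, out_dir = d3)))
  expect_false(identical(readLines(p1[["experiment"]]),
                         readLines(p3[["experiment"]])))
})
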