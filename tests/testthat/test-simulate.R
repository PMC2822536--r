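test_that("simulation is reproducible from its seed", {
  cfg <- simulation_config(n_genes = 60, n_samples = 40, n_groups = 1,
                           group_size = 3, n_platforms = 2,
                           affine_jitter = 0.3, n_controls = 5, seed = 91)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$datasets[[1]]$values, b$datasets[[1]]$values)
  expect_identical(a$datasets[[2]]$values, b$datasets[[2]]$values)
  expect_identical(a$truth, b$truth)
  # different seed: different draws
  c <- simulate_cohort(simulation_config(n_genes = 60, n_samples = 40,
                                         n_groups = 1, group_size = 3,
                                         seed = 92))
  expect_false(identical(a$datasets[[1]]$values, c$datasets[[1]]$values))
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(frac_bimodal = 1.2),
               class = "bimodr_validation_error")
  expect_error(simulation_config(group_agreement = 0.4),
               class = "bimodr_validation_error")
  expect_error(simulation_config(n_genes = 100, frac_bimodal = 0.05,
                                 n_groups = 3, group_size = 4),
               class = "bimodr_validation_error")
  expect_error(simulation_config(n_controls = 300, n_samples = 200),
               class = "bimodr_validation_error")
})

test_that("structural truth matches the config", {
  sim <- simulate_cohort(simulation_config(n_genes = 200, n_samples = 50,
                                           frac_bimodal = 0.2, n_groups = 2,
                                           group_size = c(4, 6),
                                           n_controls = 6, seed = 93))
  tr <- sim$truth
  expect_length(tr$bimodal_genes, 40)
  expect_length(tr$group_membership, 2)
  sizes <- lengths(tr$group_membership)
  expect_true(all(sizes >= 4 & sizes <= 6))
  expect_true(all(unlist(tr$group_membership) %in% tr$bimodal_genes))
  expect_length(tr$control_samples, 6)
  # controls pinned to the upper mode for every bimodal gene
  expect_true(all(tr$gene_modes[, tr$control_samples] == 1L))
  # no bimodal genes requested -> none planted
  none <- simulate_cohort(simulation_config(n_genes = 50, n_samples = 20,
                                            frac_bimodal = 0, n_groups = 0,
                                            seed = 94))
  expect_length(none$truth$bimodal_genes, 0)
})

test_that("mode occupancy matches the balance within binomial error", {
  sim <- simulate_cohort(simulation_config(n_genes = 600, n_samples = 100,
                                           frac_bimodal = 0.3, n_groups = 0,
                                           balance = 0.7, seed = 95))
  occ <- mean(sim$truth$gene_modes)
  se <- sqrt(0.7 * 0.3 / length(sim$truth$gene_modes))
  expect_lt(abs(occ - 0.7), 6 * se + 0.01)
})

test_that("indistinguishable modes (delta 0) are called no more than null genes", {
  sim <- simulate_cohort(simulation_config(n_genes = 600, n_samples = 100,
                                           frac_bimodal = 0.3, delta = 0,
                                           n_groups = 0, seed = 96))
  fits <- detect_bimodal(sim$datasets[[1]])
  called <- fits$gene[fits$is_bimodal]
  rate_labeled <- mean(sim$truth$bimodal_genes %in% called)
  rate_null <- mean(setdiff(fits$gene, sim$truth$bimodal_genes) %in% called)
  expect_lt(abs(rate_labeled - rate_null), 0.15)
})

test_that("detection sensitivity is non-decreasing in separation and cohort size", {
  sens <- function(delta, n_samples) {
    sim <- simulate_cohort(simulation_config(n_genes = 300,
                                             n_samples = n_samples,
                                             frac_bimodal = 0.2,
                                             delta = delta, n_groups = 0,
                                             seed = 97))
    fits <- detect_bimodal(sim$datasets[[1]])
    recovery_report(sim$truth, fits)$sensitivity
  }
  by_delta <- vapply(c(1, 3, 6), sens, n_samples = 100, numeric(1))
  expect_true(all(diff(by_delta) >= 0))
  expect_gt(by_delta[3], 0.9)
  by_n <- vapply(c(20, 60, 150), function(n) sens(4, n), numeric(1))
  expect_true(all(diff(by_n) >= -0.02))  # small-sample noise allowance
})

test_that("platforms distort raw values but not normalized profiles", {
  sim <- simulate_cohort(simulation_config(n_genes = 300, n_samples = 120,
                                           frac_bimodal = 0.15, n_groups = 0,
                                           n_platforms = 2,
                                           affine_jitter = 0.5, seed = 98))
  d1 <- sim$datasets[[1]]; d2 <- sim$datasets[[2]]
  expect_gt(mean(abs(d1$values - d2$values)), 0.1)  # raw values differ
  f1 <- detect_bimodal(d1); f2 <- detect_bimodal(d2)
  n1 <- normalize_dataset(d1, f1, genes = sim$truth$bimodal_genes)
  n2 <- normalize_dataset(d2, f2, genes = sim$truth$bimodal_genes)
  rep <- recovery_report(sim$truth, f1, normalized = list(n1, n2))
  expect_lt(rep$platform_mean_abs_diff, 1e-9)
})

test_that("recovery report scores a perfect and an imperfect call set", {
  sim <- simulate_cohort(simulation_config(n_genes = 100, n_samples = 30,
                                           frac_bimodal = 0.1, n_groups = 0,
                                           seed = 99))
  fits <- data.frame(gene = sprintf("G%05d", 1:100),
                     is_bimodal = sprintf("G%05d", 1:100) %in%
                       sim$truth$bimodal_genes)
  rep <- recovery_report(sim$truth, fits)
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$specificity, 1)
  fits$is_bimodal <- FALSE
  rep0 <- recovery_report(sim$truth, fits)
  expect_equal(rep0$sensitivity, 0)
  expect_equal(rep0$specificity, 1)
})
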