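test_that("optimal partition reproduces worked splits", {
  f <- optimal_partition(c(0, 0, 0, 1, 1, 1))
  expect_equal(f$K, 3L)
  expect_equal(f$l, 0); expect_equal(f$u, 1)
  expect_equal(f$gamma, 0); expect_equal(f$T, 0.5)

  # exhaustive scan by hand: split after 3 gives SS 2 + 2 = 4, others >= 50.5
  f <- optimal_partition(c(10, 1, 12, 2, 11, 3))  # order must not matter
  expect_equal(f$K, 3L)
  expect_equal(f$l, 2); expect_equal(f$u, 11)
  expect_equal(f$gamma, 4); expect_equal(f$T, 6.5)

  expect_error(optimal_partition(c(5, 5, 5, 5)),
               class = "bimodr_degenerate_error")
  expect_error(optimal_partition(c(1, NA)),
               class = "bimodr_insufficient_error")
})

test_that("gamma matches the exhaustive-scan oracle with smallest-K ties", {
  set.seed(101)
  gens <- list(function(n) rnorm(n),
               function(n) runif(n, -3, 3),
               function(n) rpois(n, 3),          # heavy exact ties
               function(n) sample(0:2, n, TRUE)) # heavier ties
  for (i in 1:400) {
    n <- sample(4:50, 1)
    x <- gens[[(i %% 4) + 1]](n)
    if (length(unique(x)) < 2) next
    f <- optimal_partition(x)
    o <- brute_partition(x)
    expect_equal(f$gamma, o$gamma, tolerance = 1e-9)
    expect_equal(f$K, min(o$ties))
  }
})

test_that("tau matches hand arithmetic and the infinity sentinel", {
  f <- optimal_partition(c(1, 2, 3, 10, 11, 12))
  expect_equal(tau_statistic(f, 6), 9 / sqrt(4 / 6), tolerance = 1e-12)
  expect_equal(round(tau_statistic(f, 6), 4), 11.0227)
  f0 <- optimal_partition(c(0, 0, 0, 1, 1, 1))
  expect_identical(tau_statistic(f0, 6), Inf)
  expect_error(tau_statistic(f, 1), class = "bimodr_validation_error")
})

test_that("tau is invariant under positive affine transforms", {
  set.seed(21)
  for (i in 1:25) {
    x <- rnorm(sample(10:200, 1), 8, 2)
    a <- exp(runif(1, -2, 2)); b <- runif(1, -20, 20)
    t1 <- tau_statistic(optimal_partition(x))
    t2 <- tau_statistic(optimal_partition(a * x + b))
    expect_lt(abs(t1 - t2), 1e-9)
  }
})

test_that("tau grows with mode separation and approaches the Gaussian baseline", {
  # monotone in the planted gap, all else fixed
  set.seed(31)
  noise <- rnorm(100, 0, 0.5)
  modes <- rep(c(0, 1), each = 50)
  taus <- vapply(c(1, 2, 4, 8), function(gap) {
    tau_statistic(optimal_partition(noise + gap * modes))
  }, numeric(1))
  expect_true(all(diff(taus) > 0))

  # closed form 2*sqrt(2/pi)/sqrt(1-2/pi), reached for large cohorts
  expect_equal(tau_normal_baseline(), 2.6472, tolerance = 1e-4)
  set.seed(32)
  taus <- replicate(40, tau_statistic(optimal_partition(rnorm(20000))))
  expect_equal(mean(taus), tau_normal_baseline(), tolerance = 0.005)
})

test_that("small outlying subsets are trimmed against the original n", {
  set.seed(41)
  x <- c(rnorm(97, 0, 1), 50, 51, 52)   # 3 of 100 far above the rest
  tr <- trim_outliers(x, fraction = 0.05)
  expect_equal(tr$outlier_idx, 98:100)
  expect_length(tr$values, 97)

  balanced <- c(rnorm(50, 0, 0.2), rnorm(50, 10, 0.2))
  tr <- trim_outliers(balanced, fraction = 0.05)
  expect_length(tr$outlier_idx, 0)

  # disabled rule is the identity
  tr0 <- trim_outliers(x, fraction = 0)
  expect_length(tr0$outlier_idx, 0)
  expect_equal(tr0$values, x)

  # idempotent once it reports no removals
  tr1 <- trim_outliers(x, 0.05)
  tr2 <- trim_outliers(tr1$values, 0.05)
  expect_length(tr2$outlier_idx, 0)
  expect_equal(tr2$values, tr1$values)

  expect_error(trim_outliers(x, 0.5), class = "bimodr_validation_error")
  expect_error(trim_outliers(c(0, 0, 0, 100), 0.3),
               class = "bimodr_insufficient_error")
})

test_that("sd percentile filter uses strict inequality on an interpolated quantile", {
  # rows built to have sds exactly 1, 2, 3, 4; 25th percentile = 1.75
  vals <- rbind(c(-1, 0, 1), c(-2, 0, 2), c(-3, 0, 3), c(-4, 0, 4))
  d <- make_dataset(vals)
  expect_equal(std_percentile_filter(d, 25), c("G002", "G003", "G004"))
  # percentile 0: everything strictly above the minimum sd
  expect_equal(std_percentile_filter(d, 0), c("G002", "G003", "G004"))
  # all sds equal: strictness means nothing passes
  flat <- make_dataset(rbind(c(-1, 0, 1), c(-1, 0, 1), c(-1, 0, 1)))
  expect_length(std_percentile_filter(flat, 25), 0L)
})

test_that("detect_bimodal calls planted genes and flags degenerate ones", {
  set.seed(51)
  bimodal <- rnorm(200, 0, 0.5) + rep(c(-2, 2), each = 100)
  flat <- rep(3, 200)
  noise <- matrix(rnorm(8 * 200, 0, 0.5), 8)
  d <- make_dataset(rbind(bimodal, flat, noise),
                    gene_ids = c("BI", "FLAT", sprintf("N%d", 1:8)))
  fits <- detect_bimodal(d)
  expect_s3_class(fits, "bimodal_fits")
  expect_true(fits$is_bimodal[fits$gene == "BI"])
  expect_gt(fits$tau[fits$gene == "BI"], 5)
  frow <- fits[fits$gene == "FLAT", ]
  expect_false(frow$is_bimodal)
  expect_equal(frow$flag, "degenerate")
  expect_true(is.na(frow$tau))

  # too few samples is a per-gene flag, not a batch error
  tiny <- make_dataset(matrix(rnorm(12), 3), sample_ids = sprintf("S%d", 1:4))
  fits <- detect_bimodal(tiny, min_samples = 10)
  expect_true(all(fits$flag == "insufficient"))
  expect_true(all(!fits$is_bimodal))
})
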