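#' Configuration for a simulated expression cohort
#'
#' Defines the statistical structure the detection method assumes: most
#' genes unimodal Gaussian, a fraction bimodal (two-Gaussian mixture with a
#' mean gap of `delta` within-mode standard deviations), some bimodal genes
#' organised into groups that follow a shared per-sample latent mode,
#' optional control samples confined to the upper mode, and one or more
#' "platforms" that each observe the same cohort through per-gene positive
#' affine distortions.
#'
#' The defaults describe a mid-sized two-channel-array-like cohort: 2,000
#' genes by 200 samples on a log-like scale (baseline means ~ N(8, 2),
#' within-mode sd 0.5), 10% bimodal genes with a 6-sd mode gap, five
#' synchronous groups of 4-6 genes whose members follow the group mode in
#' 95% of samples.
#'
#' @param n_genes,n_samples cohort dimensions.
#' @param frac_bimodal fraction of genes that are bimodal.
#' @param delta mode-mean separation in units of `sigma`.
#' @param sigma within-mode standard deviation.
#' @param balance expected fraction of samples in the upper mode.
#' @param outlier_rate per-cell probability of an extreme spike (placed
#'   well above the upper mode).
#' @param n_groups number of planted synchronous groups.
#' @param group_size group size; a single integer, or a length-2 range from
#'   which each group's size is drawn.
#' @param group_agreement probability that a member follows its group's
#'   latent mode in a given sample, in `(0.5, 1]`.
#' @param n_platforms number of platform renderings of the cohort.
#' @param affine_jitter spread of the per-gene per-platform distortion:
#'   scale `exp(N(0, affine_jitter))`, offset `N(0, affine_jitter)`.
#' @param n_controls number of control samples (the last `n_controls`
#'   samples; their latent mode is pinned to the upper mode).
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000L, n_samples = 200L,
                              frac_bimodal = 0.10, delta = 6, sigma = 0.5,
                              balance = 0.5, outlier_rate = 0,
                              n_groups = 5L, group_size = c(4L, 6L),
                              group_agreement = 0.95, n_platforms = 1L,
                              affine_jitter = 0, n_controls = 0L,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples = as.integer(n_samples),
              frac_bimodal = frac_bimodal, delta = delta, sigma = sigma,
              balance = balance, outlier_rate = outlier_rate,
              n_groups = as.integer(n_groups),
              group_size = as.integer(group_size),
              group_agreement = group_agreement,
              n_platforms = as.integer(n_platforms),
              affine_jitter = affine_jitter,
              n_controls = as.integer(n_controls),
              seed = as.integer(seed))
  with(cfg, {
    if (n_genes < 2L || n_samples < 2L)
      stop_validation("need at least 2 genes and 2 samples")
    if (frac_bimodal < 0 || frac_bimodal > 1)
      stop_validation("frac_bimodal must be in [0, 1]")
    if (balance <= 0 || balance >= 1)
      stop_validation("balance must be in (0, 1)")
    if (outlier_rate < 0 || outlier_rate >= 1)
      stop_validation("outlier_rate must be in [0, 1)")
    if (group_agreement <= 0.5 || group_agreement > 1)
      stop_validation("group_agreement must be in (0.5, 1]")
    if (sigma <= 0 || delta < 0)
      stop_validation("sigma must be positive and delta non-negative")
    if (!length(group_size) %in% 1:2 || any(group_size < 2L))
      stop_validation("group_size must be one integer >= 2 or a range")
    if (n_groups > 0L &&
        n_groups * max(group_size) > floor(frac_bimodal * n_genes))
      stop_validation("planted groups do not fit among the bimodal genes")
    if (n_platforms < 1L) stop_validation("need at least one platform")
    if (n_controls < 0L || n_controls >= n_samples)
      stop_validation("n_controls must be in [0, n_samples)")
  })
  structure(cfg, class = "simulation_config")
}

#' Simulate a multi-platform expression cohort with known truth
#'
#' Draws a cohort according to a [simulation_config()]:
#' \itemize{
#'   \item unimodal genes: `N(mu_g, sigma)` around a gene baseline
#'     `mu_g ~ N(8, 2)`;
#'   \item bimodal genes: the same plus `+- delta*sigma/2` according to a
#'     per-sample binary mode, `P(upper) = balance`;
#'   \item grouped genes: the gene's mode equals its group's latent
#'     per-sample mode, flipped independently with probability
#'     `1 - group_agreement` (synchronous within the group, independent
#'     between groups);
#'   \item controls: the last `n_controls` samples have every latent mode
#'     pinned to the upper mode (a homogeneous reference tissue), so the
#'     control mode is "upper" throughout;
#'   \item outlier spikes: with probability `outlier_rate` a cell is
#'     replaced by a value far above the upper mode;
#'   \item platforms: each platform renders the same base matrix through
#'     per-gene distortions `a_g * x + b_g`, `a_g > 0`.
#' }
#'
#' @param config a [simulation_config()] (or arguments for one via `...`).
#' @param ... used to build a config when `config` is missing.
#' @return List with `datasets` (list of [expression_dataset()], one per
#'   platform), `truth` (list: `bimodal_genes`, `group_membership`,
#'   `sample_modes` group-by-sample 0/1 matrix, `gene_modes`
#'   bimodal-gene-by-sample 0/1 matrix, `control_samples`, `control_mode`)
#'   and `config`.
#' @export
simulate_cohort <- function(config = simulation_config(...), ...) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cf <- config
  genes <- sprintf("G%05d", seq_len(cf$n_genes))
  samples <- sprintf("S%04d", seq_len(cf$n_samples))
  n_bi <- round(cf$frac_bimodal * cf$n_genes)
  bimodal_genes <- sort(sample(genes, n_bi))
  control_idx <- if (cf$n_controls > 0L)
    (cf$n_samples - cf$n_controls + 1L):cf$n_samples else integer(0)

  # planted groups among the bimodal genes
  sizes <- if (cf$n_groups == 0L) integer(0)
           else if (length(cf$group_size) == 1L)
             rep(cf$group_size, cf$n_groups)
           else sample(seq(cf$group_size[1], cf$group_size[2]),
                       cf$n_groups, replace = TRUE)
  pool <- sample(bimodal_genes)
  group_membership <- list()
  taken <- 0L
  for (g in seq_len(cf$n_groups)) {
    group_membership[[sprintf("group%d", g)]] <-
      sort(pool[(taken + 1L):(taken + sizes[g])])
    taken <- taken + sizes[g]
  }
  grouped <- unlist(group_membership, use.names = FALSE)

  # latent modes: per group, and per ungrouped bimodal gene
  draw_modes <- function() {
    z <- stats::rbinom(cf$n_samples, 1L, cf$balance)
    z[control_idx] <- 1L
    z
  }
  sample_modes <- matrix(0L, nrow = max(cf$n_groups, 0L),
                         ncol = cf$n_samples,
                         dimnames = list(names(group_membership), samples))
  for (g in seq_len(cf$n_groups)) sample_modes[g, ] <- draw_modes()

  gene_modes <- matrix(0L, nrow = n_bi, ncol = cf$n_samples,
                       dimnames = list(bimodal_genes, samples))
  for (gi in bimodal_genes) {
    grp <- which(vapply(group_membership, function(m) gi %in% m, logical(1)))
    base_mode <- if (length(grp)) sample_modes[grp[1], ] else draw_modes()
    flips <- stats::rbinom(cf$n_samples, 1L, 1 - cf$group_agreement)
    flips[control_idx] <- 0L          # controls stay a homogeneous reference
    m <- ifelse(flips == 1L, 1L - base_mode, base_mode)
    if (!length(grp)) m <- base_mode  # ungrouped genes have their own mode
    gene_modes[gi, ] <- m
  }

  mu <- stats::rnorm(cf$n_genes, 8, 2)
  names(mu) <- genes
  base <- matrix(stats::rnorm(cf$n_genes * cf$n_samples, 0, cf$sigma),
                 nrow = cf$n_genes, dimnames = list(genes, samples))
  base <- base + mu
  base[bimodal_genes, ] <- base[bimodal_genes, ] +
    (gene_modes - 0.5) * cf$delta * cf$sigma
  if (cf$outlier_rate > 0) {
    spike <- matrix(stats::runif(length(base)) < cf$outlier_rate,
                    nrow = nrow(base))
    base[spike] <- mu[row(base)[spike]] + cf$delta * cf$sigma / 2 +
      6 * cf$sigma + abs(stats::rnorm(sum(spike), 0, cf$sigma))
  }

  control_mask <- seq_len(cf$n_samples) %in% control_idx
  datasets <- lapply(seq_len(cf$n_platforms), function(p) {
    vals <- base
    if (cf$affine_jitter > 0) {
      a <- exp(stats::rnorm(cf$n_genes, 0, cf$affine_jitter))
      b <- stats::rnorm(cf$n_genes, 0, cf$affine_jitter)
      vals <- vals * a + b
    }
    expression_dataset(vals,
                       control_mask = if (cf$n_controls > 0L) control_mask,
                       platform = sprintf("platform%d", p))
  })

  list(datasets = datasets,
       truth = list(bimodal_genes = bimodal_genes,
                    group_membership = group_membership,
                    sample_modes = sample_modes,
                    gene_modes = gene_modes,
                    control_samples = samples[control_idx],
                    control_mode = "upper"),
       config = config)
}

#' Score detection, grouping and normalization against simulation truth
#'
#' @param truth the `truth` element of a [simulate_cohort()] result.
#' @param fits a [detect_bimodal()] table computed on a simulated dataset.
#' @param groups optional list of `GeneGroup` results (e.g. one per planted
#'   group, seeded from a member gene) to score for exact membership.
#' @param normalized optional list of >= 2 `NormalizedDataset`s from
#'   different platforms of the same simulation; scored for cross-platform
#'   agreement on the true bimodal genes.
#' @return A list of class `recovery_report`: `sensitivity`, `specificity`,
#'   `n_called`, and (when supplied) `group_exact`, `group_exact_rate`,
#'   `platform_mean_abs_diff`.
#' @export
recovery_report <- function(truth, fits, groups = NULL, normalized = NULL) {
  fits <- as.data.frame(fits)
  all_genes <- toupper(fits$gene)
  true_bi <- toupper(truth$bimodal_genes)
  if (!all(true_bi %in% all_genes))
    stop_validation("fits do not cover the simulated bimodal genes")
  called <- all_genes[fits$is_bimodal %in% TRUE]
  is_true <- all_genes %in% true_bi
  is_called <- all_genes %in% called
  out <- list(
    sensitivity = mean(is_called[is_true]),
    specificity = mean(!is_called[!is_true]),
    n_called = length(called))
  if (!is.null(groups)) {
    exact <- vapply(seq_along(truth$group_membership), function(i) {
      planted <- toupper(truth$group_membership[[i]])
      found <- groups[[i]]
      !is.null(found) && setequal(toupper(found$members), planted)
    }, logical(1))
    names(exact) <- names(truth$group_membership)
    out$group_exact <- exact
    out$group_exact_rate <- mean(exact)
  }
  if (!is.null(normalized) && length(normalized) >= 2L) {
    diffs <- utils::combn(length(normalized), 2, function(ij) {
      a <- normalized[[ij[1]]]$values
      b <- normalized[[ij[2]]]$values
      shared <- intersect(intersect(rownames(a), rownames(b)), true_bi)
      if (length(shared) == 0L) return(NA_real_)
      mean(abs(a[shared, ] - b[shared, ]), na.rm = TRUE)
    })
    out$platform_mean_abs_diff <- mean(diffs, na.rm = TRUE)
  }
  structure(out, class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery_report: sensitivity %.3f, specificity %.3f (%d called)\n",
              x$sensitivity, x$specificity, x$n_called))
  if (!is.null(x$group_exact_rate))
    cat(sprintf("  exact group recovery: %.0f%% (%d/%d)\n",
                100 * x$group_exact_rate, sum(x$group_exact),
                length(x$group_exact)))
  if (!is.null(x$platform_mean_abs_diff))
    cat(sprintf("  cross-platform mean |diff| of normalized profiles: %.4g\n",
                x$platform_mean_abs_diff))
  invisible(x)
}
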