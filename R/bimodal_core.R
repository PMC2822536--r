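#' Optimal two-way partition of a signal vector
#'
#' Sorts the signals and scans every split of the sorted vector into a lower
#' subset `L` (the `k` smallest values, `k = 1..n-1`) and an upper subset
#' `U`, choosing the split that minimizes
#' `gamma = SS(L) + SS(U)`, the total sum of squared deviations of each
#' subset around its own mean — the one-dimensional two-means objective.
#' One-sided "partitions" with an empty subset are not admissible.
#'
#' Ties in `gamma` are broken by the smallest `K` (first minimum in scan
#' order), which is deterministic and stable under reordering of the input.
#' The inter-mode threshold is the midpoint
#' `T = (max(L) + min(U)) / 2`, which lies strictly between the two modes
#' whenever the boundary values differ and maps to exactly 0 under bimodal
#' normalization.
#'
#' @param x numeric vector of signals; missing values are dropped.
#' @return An object of class `bimodal_fit`: list with `K` (size of the
#'   lower subset), `n_lower`, `n_upper`, `l` and `u` (subset means),
#'   `T` (threshold), `gamma` (minimized within-subset SS, clamped at 0
#'   against floating-point cancellation) and `n` (number of values used).
#' @seealso [tau_statistic()], [detect_bimodal()]
#' @export
#' @examples
#' optimal_partition(c(1, 2, 3, 10, 11, 12))  # K = 3, l = 2, u = 11, gamma = 4
optimal_partition <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L)
    stop_insufficient("need at least 2 non-missing values to partition")
  xs <- sort(x)
  if (xs[1L] == xs[n])
    stop_degenerate("all values identical: no partition with u > l exists")
  cs <- cumsum(xs)
  cs2 <- cumsum(xs * xs)
  k <- seq_len(n - 1L)
  ss_lower <- cs2[k] - cs[k]^2 / k
  ss_upper <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  gamma <- pmax(ss_lower + ss_upper, 0)
  # smallest K among ties; the tolerance absorbs float round-off between
  # mathematically equal splits (heavy exact ties occur with discrete data)
  gmin <- min(gamma)
  K <- which(gamma <= gmin + 1e-9 * max(1, gmin))[1L]
  l <- cs[K] / K
  u <- (cs[n] - cs[K]) / (n - K)
  structure(list(K = K, n_lower = K, n_upper = n - K,
                 l = l, u = u, T = (xs[K] + xs[K + 1L]) / 2,
                 gamma = gamma[K], n = n),
            class = "bimodal_fit")
}

#' @export
print.bimodal_fit <- function(x, ...) {
  cat(sprintf(
    "bimodal_fit: n=%d K=%d  l=%.4g u=%.4g T=%.4g  gamma=%.4g\n",
    x$n, x$K, x$l, x$u, x$T, x$gamma))
  invisible(x)
}

#' The tau separation statistic
#'
#' A t-like measure of how isolated the two modes of the optimal partition
#' are: `tau = (u - l) / sqrt(gamma / M)`, the gap between subset means in
#' units of pooled within-subset spread. For iid draws from a single
#' Gaussian, tau approaches `2*sqrt(2/pi)/sqrt(1 - 2/pi) = 2.6472` as the
#' cohort grows (optimal split at the mean; half-normal mean and variance),
#' so values well above ~2.64 indicate a wider-than-normal, typically
#' bimodal, distribution. When `gamma = 0` with `u > l` (perfectly
#' separated constant modes) the statistic is `Inf`.
#'
#' tau is invariant under positive affine transforms of the signals
#' (`a*x + b`, `a > 0`), which is what makes the calls comparable across
#' array platforms.
#'
#' @param fit a [optimal_partition()] result.
#' @param M total number of experiments (cohort size) used in the
#'   denominator; defaults to the number of values in the fit.
#' @return tau (non-negative; possibly `Inf`).
#' @export
tau_statistic <- function(fit, M = fit$n) {
  if (M < 2) stop_validation("M must be at least 2")
  if (fit$gamma <= 0) return(Inf)
  (fit$u - fit$l) / sqrt(fit$gamma / M)
}

#' Closed-form single-Gaussian baseline of tau
#'
#' The large-cohort value of [tau_statistic()] for iid Gaussian signals:
#' the optimal split converges to the mean, the subset means to the
#' half-normal means `-+ sqrt(2/pi)`, and the pooled within-subset variance
#' to the half-normal variance `1 - 2/pi`, giving
#' `2*sqrt(2/pi)/sqrt(1 - 2/pi)` (about 2.6472).
#'
#' @return The baseline constant.
#' @export
tau_normal_baseline <- function() {
  2 * sqrt(2 / pi) / sqrt(1 - 2 / pi)
}

#' Remove small outlying subsets before partitioning
#'
#' A handful of extreme values would otherwise be taken as a "mode": if the
#' optimal partition isolates a subset whose relative size (against the
#' ORIGINAL number of non-missing values) is below `fraction`, those values
#' are flagged as outliers and removed, and the remainder is re-partitioned;
#' this repeats until both subsets hold at least `fraction` of the original
#' values. `fraction = 0` disables the rule. The procedure is idempotent
#' once it reports no removals.
#'
#' @param x numeric vector (missing values are ignored and never flagged).
#' @param fraction minimum relative subset size, in `[0, 0.5)`; default 0.05
#'   (the "less than 5 percent" rule).
#' @return List with `values` (surviving signals, original order),
#'   `outlier_idx` (integer positions of outliers in the original vector)
#'   and `n_original` (non-missing count).
#' @export
trim_outliers <- function(x, fraction = 0.05) {
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 0.5)
    stop_validation("fraction must be in [0, 0.5)")
  keep_idx <- which(!is.na(x))
  vals <- x[keep_idx]
  n0 <- length(vals)
  out_idx <- integer(0)
  if (fraction > 0 && n0 >= 2L) {
    repeat {
      if (length(vals) < 4L)
        stop_insufficient("fewer than 4 values survive outlier trimming")
      if (min(vals) == max(vals)) break    # constant remainder: nothing to split
      fit <- optimal_partition(vals)
      if (min(fit$n_lower, fit$n_upper) / n0 >= fraction) break
      ord <- order(vals)
      drop <- if (fit$n_lower <= fit$n_upper) ord[seq_len(fit$K)]
              else ord[(fit$K + 1L):length(vals)]
      out_idx <- c(out_idx, keep_idx[drop])
      vals <- vals[-drop]
      keep_idx <- keep_idx[-drop]
      if (length(vals) < 4L)
        stop_insufficient("fewer than 4 values survive outlier trimming")
    }
  }
  list(values = vals, outlier_idx = sort(out_idx), n_original = n0)
}

#' Hypervariable-gene filter on the standard deviation distribution
#'
#' Computes each gene's sample standard deviation (n-1 denominator, missing
#' entries dropped) and keeps the genes whose sd is strictly greater than
#' the given percentile (linear interpolation) of the per-gene sd
#' distribution. With the default 25th percentile this discards the
#' flattest quarter of genes before bimodality is assessed.
#'
#' @param dataset an [expression_dataset()] (or a plain numeric matrix).
#' @param percentile percentile of the sd distribution, in `[0, 100)`.
#' @return Character vector of gene ids passing the filter.
#' @export
std_percentile_filter <- function(dataset, percentile = 25) {
  mat <- if (inherits(dataset, "ExpressionDataset")) dataset$values
         else as.matrix(dataset)
  if (nrow(mat) < 2L) stop_validation("need at least 2 genes")
  stds <- apply(mat, 1, stats::sd, na.rm = TRUE)
  thr <- stats::quantile(stds, probs = percentile / 100, type = 7,
                         na.rm = TRUE, names = FALSE)
  names(stds)[!is.na(stds) & stds > thr]
}

#' Detect bimodal genes in a cohort
#'
#' Per gene: drop missing values, trim small outlying subsets
#' ([trim_outliers()]), find the optimal two-way partition
#' ([optimal_partition()]) and compute [tau_statistic()] with `M` equal to
#' the number of surviving values. A gene is called bimodal when
#' `tau > tau_threshold` (strict) AND its pre-trim standard deviation passes
#' [std_percentile_filter()]. Genes that cannot be fit (constant signal,
#' too few values) are returned as non-bimodal rows with an explanatory
#' `flag`, never as batch-level errors.
#'
#' @param dataset an [expression_dataset()].
#' @param tau_threshold call threshold on tau; default 2.64, the single-
#'   Gaussian baseline (see [tau_normal_baseline()]).
#' @param outlier_fraction passed to [trim_outliers()]; 0 disables trimming.
#' @param std_percentile passed to [std_percentile_filter()].
#' @param min_samples genes with fewer non-missing values are skipped with
#'   flag `"insufficient"`.
#' @return A data frame of class `bimodal_fits`, one row per gene, with
#'   columns `gene, n, K, l, u, T, gamma, tau, std, n_outliers,
#'   outlier_samples, is_bimodal, flag`. Parameters are stored in
#'   `attr(, "params")`.
#' @export
detect_bimodal <- function(dataset, tau_threshold = 2.64,
                           outlier_fraction = 0.05, std_percentile = 25,
                           min_samples = 10L) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  mat <- dataset$values
  samples <- colnames(mat)
  std_pass <- std_percentile_filter(dataset, std_percentile)
  rows <- lapply(rownames(mat), function(g) {
    x <- mat[g, ]
    std <- stats::sd(x, na.rm = TRUE)
    n_nonmiss <- sum(!is.na(x))
    base <- data.frame(gene = g, n = NA_integer_, K = NA_integer_,
                       l = NA_real_, u = NA_real_, T = NA_real_,
                       gamma = NA_real_, tau = NA_real_, std = std,
                       n_outliers = 0L, outlier_samples = "",
                       is_bimodal = FALSE, flag = "ok",
                       stringsAsFactors = FALSE)
    if (n_nonmiss < min_samples) {
      base$flag <- "insufficient"
      return(base)
    }
    res <- tryCatch({
      tr <- trim_outliers(x, outlier_fraction)
      fit <- optimal_partition(tr$values)
      tau <- tau_statistic(fit, M = fit$n)
      base$n <- fit$n; base$K <- fit$K
      base$l <- fit$l; base$u <- fit$u; base$T <- fit$T
      base$gamma <- fit$gamma; base$tau <- tau
      base$n_outliers <- length(tr$outlier_idx)
      base$outlier_samples <- paste(samples[tr$outlier_idx], collapse = ";")
      base$is_bimodal <- (tau > tau_threshold) && (g %in% std_pass)
      base
    },
    bimodr_degenerate_error = function(e) { base$flag <- "degenerate"; base },
    bimodr_insufficient_error = function(e) { base$flag <- "insufficient"; base })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "params") <- list(tau_threshold = tau_threshold,
                              outlier_fraction = outlier_fraction,
                              std_percentile = std_percentile,
                              min_samples = min_samples)
  class(out) <- c("bimodal_fits", "data.frame")
  out
}

#' Write a bimodal fit table as TSV
#'
#' Infinite tau values (perfectly separated modes) are serialized as the
#' token `"inf"`; [read_fits()] restores them.
#'
#' @param fits a [detect_bimodal()] result.
#' @param path output path.
#' @param header_lines optional `#`-prefixed provenance lines.
#' @export
write_fits <- function(fits, path, header_lines = NULL) {
  df <- as.data.frame(fits)
  df$tau <- ifelse(is.infinite(df$tau), "inf",
                   ifelse(is.na(df$tau), "NA", sprintf("%.17g", df$tau)))
  for (col in c("l", "u", "T", "gamma", "std"))
    df[[col]] <- ifelse(is.na(df[[col]]), "NA", sprintf("%.17g", df[[col]]))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bimodal fit table written by [write_fits()]
#'
#' @param path path to the fits TSV.
#' @return A `bimodal_fits` data frame.
#' @export
read_fits <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  df$gene <- toupper(df$gene)
  df$tau <- suppressWarnings(
    ifelse(df$tau %in% c("inf", "Inf"), Inf, as.numeric(df$tau)))
  for (col in c("l", "u", "T", "gamma", "std"))
    df[[col]] <- as.numeric(df[[col]])
  df$is_bimodal <- as.logical(df$is_bimodal)
  if (is.null(df$outlier_samples)) df$outlier_samples <- ""
  df$outlier_samples[is.na(df$outlier_samples)] <- ""
  class(df) <- c("bimodal_fits", "data.frame")
  df
}
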