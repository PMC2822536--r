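#' Rescale one gene's signals to the binary -1/+1 scale
#'
#' Piecewise-linear map anchored at the fitted lower-mode mean `l`, the
#' inter-mode threshold `T` and the upper-mode mean `u`:
#' values at or below `T` map as `(x - T) / (T - l)`, values above `T` as
#' `(x - T) / (u - T)`. The anchors land exactly on
#' `l -> -1`, `T -> 0`, `u -> +1`; the map is strictly increasing, and
#' values beyond the mode means map beyond +-1 (no clipping, so outliers
#' stay visible).
#'
#' Two hinged linear segments are used because a single linear map can only
#' satisfy all three anchors when `T` is exactly the midpoint of `l` and
#' `u`, which the data-driven threshold generally is not.
#'
#' @param x numeric vector of raw signals (missing values pass through).
#' @param fit a [optimal_partition()] result (or one row of a
#'   [detect_bimodal()] table) supplying `l`, `T`, `u`.
#' @return Numeric vector of normalized signals.
#' @export
normalize_gene <- function(x, fit) {
  l <- fit$l; T <- fit$T; u <- fit$u
  if (!is.finite(l) || !is.finite(u) || !is.finite(T))
    stop_validation("fit has no finite anchors (degenerate gene?)")
  if (T <= l || T >= u)
    stop_degenerate("threshold coincides with a mode mean: cannot anchor the map")
  ifelse(x <= T, (x - T) / (T - l), (x - T) / (u - T))
}

#' Normalize the bimodal genes of a dataset
#'
#' Applies [normalize_gene()] to every selected gene, producing a matrix on
#' the common -1/+1 scale. Because the anchors are estimated from each
#' gene's own distribution, the normalized profile is invariant under any
#' positive per-gene affine transform of the raw signals — profiles become
#' comparable across genes, studies and array platforms.
#'
#' @param dataset an [expression_dataset()].
#' @param fits a [detect_bimodal()] table for (at least) the selected genes.
#' @param genes genes to normalize; defaults to the genes called bimodal
#'   in `fits`. Genes without a usable fit are dropped with a warning.
#' @return An object of class `NormalizedDataset`: list with `values`
#'   (genes x samples matrix), `orientation` (named character,
#'   `"as-is"`/`"flipped"`/`"excluded"`), `nu` (named numeric, control
#'   means; filled by [orient_by_controls()]) and `platform`.
#' @export
normalize_dataset <- function(dataset, fits, genes = NULL) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  fits <- as.data.frame(fits)
  if (is.null(genes)) genes <- fits$gene[fits$is_bimodal %in% TRUE]
  genes <- toupper(genes)
  missing <- setdiff(genes, rownames(dataset$values))
  if (length(missing))
    stop_validation(sprintf("genes not in dataset: %s",
                            paste(utils::head(missing, 3), collapse = ", ")))
  idx <- match(genes, fits$gene)
  usable <- !is.na(idx) & is.finite(fits$l[idx]) & is.finite(fits$u[idx]) &
    is.finite(fits$T[idx]) & fits$T[idx] > fits$l[idx] &
    fits$T[idx] < fits$u[idx]
  if (any(!usable)) {
    warning(sprintf("dropping %d gene(s) without a usable fit", sum(!usable)))
    genes <- genes[usable]
    idx <- idx[usable]
  }
  if (length(genes) == 0L) stop_validation("no genes left to normalize")
  mat <- t(vapply(seq_along(genes), function(i)
    normalize_gene(dataset$values[genes[i], ], fits[idx[i], ]),
    numeric(ncol(dataset$values))))
  dimnames(mat) <- list(genes, colnames(dataset$values))
  structure(list(values = mat,
                 orientation = stats::setNames(rep("as-is", length(genes)),
                                               genes),
                 nu = NULL, platform = dataset$platform),
            class = "NormalizedDataset")
}

#' @export
print.NormalizedDataset <- function(x, ...) {
  tab <- table(factor(x$orientation,
                      levels = c("as-is", "flipped", "excluded")))
  cat(sprintf(
    "NormalizedDataset: %d genes x %d samples (as-is %d, flipped %d, excluded %d)\n",
    nrow(x$values), ncol(x$values), tab[["as-is"]], tab[["flipped"]],
    tab[["excluded"]]))
  invisible(x)
}

#' Orient the -1/+1 scale by control samples
#'
#' When the cohort contains control/normal samples, the two modes acquire a
#' biological direction: the mode occupied by controls is taken as +1. Per
#' gene, the mean raw control value `nu` is computed; if every control lies
#' above the threshold `T` the gene is kept as-is, if every control lies
#' below (`nu < T`) the normalized values are negated (`"flipped"`), and if
#' controls straddle `T` the gene's direction is ambiguous and it is
#' `"excluded"` (its normalized values are set to missing). A control value
#' exactly at `T` counts as the upper side.
#'
#' @param normalized a [normalize_dataset()] result.
#' @param dataset the raw [expression_dataset()] with `control_mask` set.
#' @param fits the [detect_bimodal()] table used for normalization.
#' @return The `NormalizedDataset` with orientation applied and `nu` filled.
#' @export
orient_by_controls <- function(normalized, dataset, fits) {
  stopifnot(inherits(normalized, "NormalizedDataset"),
            inherits(dataset, "ExpressionDataset"))
  mask <- dataset$control_mask
  if (is.null(mask) || !any(mask)) {
    warning("no control samples: orientation left as-is")
    return(normalized)
  }
  fits <- as.data.frame(fits)
  genes <- rownames(normalized$values)
  nu <- stats::setNames(rep(NA_real_, length(genes)), genes)
  for (g in genes) {
    T <- fits$T[match(g, fits$gene)]
    ctrl <- dataset$values[g, mask]
    ctrl <- ctrl[!is.na(ctrl)]
    if (length(ctrl) == 0L) next
    nu[g] <- mean(ctrl)
    lower <- ctrl < T
    if (all(lower)) {
      normalized$values[g, ] <- -normalized$values[g, ]
      normalized$orientation[g] <- "flipped"
    } else if (any(lower)) {
      normalized$values[g, ] <- NA_real_
      normalized$orientation[g] <- "excluded"
    }  # all on/above T: control mode already +1
  }
  normalized$nu <- nu
  normalized
}

#' Read back a normalized matrix written by [write_expression()]
#'
#' @param path path to the normalized TSV.
#' @param orientation_path optional sidecar TSV (columns `gene`,
#'   `orientation`) written by [write_orientation()].
#' @return A `NormalizedDataset`.
#' @export
read_normalized <- function(path, orientation_path = NULL) {
  d <- read_expression(path)
  ori <- stats::setNames(rep("as-is", nrow(d$values)), rownames(d$values))
  if (!is.null(orientation_path)) {
    tab <- utils::read.delim(orientation_path, comment.char = "#",
                             stringsAsFactors = FALSE)
    ori[toupper(tab$gene)] <- tab$orientation
  }
  structure(list(values = d$values, orientation = ori, nu = NULL,
                 platform = d$platform),
            class = "NormalizedDataset")
}

#' Write the per-gene orientation sidecar table
#'
#' @param normalized a `NormalizedDataset`.
#' @param path output path.
#' @param header_lines optional `#`-prefixed provenance lines.
#' @export
write_orientation <- function(normalized, path, header_lines = NULL) {
  df <- data.frame(gene = names(normalized$orientation),
                   orientation = unname(normalized$orientation))
  if (!is.null(normalized$nu)) df$nu <- unname(normalized$nu)
  write_table(df, path, header_lines)
}
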