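#' Cosine distance between two profiles
#'
#' `1 - x.y / (|x| |y|)`, computed over the samples where both profiles are
#' non-missing; ranges from 0 (identical direction) through 1 (orthogonal)
#' to 2 (opposite direction). Invariant to positive rescaling of either
#' vector.
#'
#' @param x,y numeric vectors of equal length.
#' @return The distance, clamped into `[0, 2]` against floating-point
#'   round-off.
#' @export
cosine_distance <- function(x, y) {
  if (length(x) != length(y)) stop_validation("vectors differ in length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) == 0L) stop_validation("no shared non-missing samples")
  nx <- sqrt(sum(x * x)); ny <- sqrt(sum(y * y))
  if (nx == 0 || ny == 0)
    stop_validation("cosine distance undefined for a zero vector")
  min(max(1 - sum(x * y) / (nx * ny), 0), 2)
}

#' Cosine distances from a query gene to every normalized gene
#'
#' Genes whose orientation is `"excluded"` (all-missing rows) are omitted.
#'
#' @param query gene id (case-insensitive) present in `normalized`.
#' @param normalized a [normalize_dataset()] result.
#' @return Named numeric vector of distances (including the query itself,
#'   at distance 0).
#' @export
neighbor_distances <- function(query, normalized) {
  stopifnot(inherits(normalized, "NormalizedDataset"))
  query <- toupper(query)
  mat <- normalized$values
  keep <- rowSums(!is.na(mat)) > 0L
  mat <- mat[keep, , drop = FALSE]
  if (!query %in% rownames(mat))
    stop_validation(sprintf("query gene %s not in normalized dataset", query))
  q <- mat[query, ]
  if (!anyNA(mat)) {
    qn <- sqrt(sum(q * q))
    if (qn == 0) stop_validation("query profile is all zero")
    rn <- sqrt(rowSums(mat * mat))
    if (any(rn == 0)) {
      mat <- mat[rn > 0, , drop = FALSE]
      rn <- rn[rn > 0]
    }
    d <- 1 - as.vector(mat %*% q) / (rn * qn)
    return(stats::setNames(pmin(pmax(d, 0), 2), rownames(mat)))
  }
  vapply(rownames(mat), function(g) cosine_distance(q, mat[g, ]), numeric(1))
}

#' Find the "close neighbors" group around a query gene
#'
#' Looks for an isolated cluster of genes at near-zero cosine distance from
#' the query — genes synchronously expressed with it. With the default
#' `"gap"` strategy the distances are binned over `[0, 1]` with bins of
#' `bin_width`; the candidate group is everything strictly below the first
#' empty bin, accepted only if that empty bin lies below the median of the
#' distance distribution (so the cluster is genuinely separated from the
#' bulk, not just the lower tail of it). The `"fixed"` strategy simply
#' takes all genes with distance at most `fixed_threshold`.
#'
#' Absence of a group (only the query survives, or no separating gap
#' exists) is a valid outcome and returns `NULL`. Anti-correlated genes
#' (distance near 2) are not added; after control-based orientation,
#' co-regulated group members run in the same direction.
#'
#' @param query gene id.
#' @param normalized a [normalize_dataset()] result.
#' @param strategy `"gap"` (default) or `"fixed"`.
#' @param bin_width histogram bin width for the gap rule.
#' @param fixed_threshold distance cutoff for the fixed rule.
#' @param min_group minimum group size (including the query).
#' @return An object of class `GeneGroup` (list with `name`, `members`
#'   ordered by distance, `member_distances`, `profile` from
#'   [group_profile()]), or `NULL` if no group is found.
#' @export
find_close_group <- function(query, normalized,
                             strategy = c("gap", "fixed"),
                             bin_width = 0.05, fixed_threshold = 0.25,
                             min_group = 2L) {
  strategy <- match.arg(strategy)
  query <- toupper(query)
  d <- neighbor_distances(query, normalized)
  others <- d[names(d) != query]
  if (length(others) == 0L) return(NULL)
  if (strategy == "fixed") {
    members <- names(d)[d <= fixed_threshold]
  } else {
    breaks <- seq(0, 1, by = bin_width)
    if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
    counts <- graphics::hist(d[d <= 1], breaks = breaks, right = FALSE,
                             include.lowest = TRUE, plot = FALSE)$counts
    # the gap is the first empty bin that separates a non-trivial near-zero
    # cluster (query plus at least one other gene) from the rest; leading
    # empty bins right after the query's own zero bin do not count
    gap <- NA_integer_
    for (b in which(counts == 0L)) {
      if (sum(others < breaks[b]) >= 1L) { gap <- b; break }
    }
    if (is.na(gap)) return(NULL)
    if (breaks[gap] >= stats::median(others)) return(NULL)
    members <- names(d)[d < breaks[gap]]
  }
  if (!query %in% members) members <- c(query, members)
  if (length(members) < max(2L, min_group)) return(NULL)
  members <- members[order(d[members])]
  structure(list(name = query, members = members,
                 member_distances = unname(d[members]),
                 strategy = strategy,
                 profile = group_profile(members, normalized)),
            class = "GeneGroup")
}

#' @export
print.GeneGroup <- function(x, ...) {
  cat(sprintf("GeneGroup '%s': %d members\n", x$name, length(x$members)))
  cat(paste(sprintf("  %s (d=%.3f)", x$members, x$member_distances),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Per-sample average expression of a gene group
#'
#' The group's expression in a sample is the mean of its members'
#' normalized values there. Members absent from the dataset (e.g. a gene
#' not assayed on this platform) are skipped, so a group remains usable as
#' a descriptor with a member missing; it is an error if no member is
#' present at all.
#'
#' @param group a `GeneGroup` or character vector of member gene ids.
#' @param normalized a [normalize_dataset()] result.
#' @return Named numeric vector, one value per sample.
#' @export
group_profile <- function(group, normalized) {
  members <- if (inherits(group, "GeneGroup")) group$members
             else toupper(group)
  present <- intersect(members, rownames(normalized$values))
  if (length(present) == 0L)
    stop_validation("no group member present in the dataset")
  colMeans(normalized$values[present, , drop = FALSE], na.rm = TRUE)
}

#' Barcode samples by the expression mode of each group
#'
#' For every sample and group, the group's average normalized expression is
#' read as a binary mode: code 1 if below 0, code 2 otherwise (exact zero
#' maps to 2 by convention). The codes, joined with dashes in the given
#' group order (e.g. `"1-1-2-1-2"`), partition the cohort into at most
#' `2^G` clusters.
#'
#' @param groups list of `GeneGroup` objects (or character member vectors);
#'   names are used as column labels, defaulting to each group's query gene.
#' @param normalized a [normalize_dataset()] result.
#' @return Data frame with columns `sample`, `barcode`, and one numeric
#'   group-mean column per group.
#' @export
barcode_samples <- function(groups, normalized) {
  if (inherits(groups, "GeneGroup")) groups <- list(groups)
  if (length(groups) == 0L) stop_validation("at least one group is required")
  if (any(vapply(groups, is.null, logical(1))))
    stop_validation("NULL group supplied (no close group was found?)")
  labels <- names(groups)
  if (is.null(labels)) labels <- rep("", length(groups))
  fallback <- vapply(groups, function(g)
    if (inherits(g, "GeneGroup")) g$name else g[[1L]], character(1))
  labels <- ifelse(nzchar(labels), labels, fallback)
  profiles <- do.call(cbind, lapply(groups, group_profile,
                                    normalized = normalized))
  colnames(profiles) <- labels
  codes <- ifelse(profiles < 0, 1L, 2L)
  out <- data.frame(sample = colnames(normalized$values),
                    barcode = apply(codes, 1, paste, collapse = "-"),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(profiles, check.names = FALSE))
}
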