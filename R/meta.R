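#' One-sided hypergeometric (Fisher) enrichment
#'
#' Probability of drawing at least `overlap` annotated genes when
#' `list_size` genes are sampled without replacement from a universe of
#' `universe` genes of which `annotation_size` are annotated — the upper
#' tail `P(X >= overlap)`, i.e. the one-sided Fisher exact test for
#' over-representation. The tail is evaluated in log space
#' (`phyper(log.p = TRUE)`), so magnitudes like 1e-112 are exact rather
#' than underflowing.
#'
#' @param list_size size of the gene list of interest.
#' @param annotation_size size of the annotation set within the universe.
#' @param overlap observed intersection of the two.
#' @param universe total number of genes in the background.
#' @param alternative `"greater"` (enrichment; default) or `"two.sided"`
#'   (sum of all tables no more probable than the observed one).
#' @return An object of class `EnrichmentResult`: list with the four
#'   counts, `p_value` and `log10_p`.
#' @export
#' @examples
#' hypergeom_enrichment(866, 609, 69, 40599)  # p = 1.169e-29
hypergeom_enrichment <- function(list_size, annotation_size, overlap,
                                 universe,
                                 alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  counts <- c(list_size, annotation_size, overlap, universe)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop_validation("counts must be non-negative integers")
  if (overlap > min(list_size, annotation_size))
    stop_validation("overlap exceeds one of the set sizes")
  if (max(list_size, annotation_size) > universe)
    stop_validation("set sizes exceed the universe")
  if (list_size + annotation_size - overlap > universe)
    stop_validation("sets cannot fit in the universe with this overlap")
  if (alternative == "greater") {
    logp <- stats::phyper(overlap - 1, annotation_size,
                          universe - annotation_size, list_size,
                          lower.tail = FALSE, log.p = TRUE)
    p <- exp(logp)
    log10p <- logp / log(10)
  } else {
    tab <- matrix(c(overlap, annotation_size - overlap,
                    list_size - overlap,
                    universe - annotation_size - list_size + overlap), 2, 2)
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    log10p <- log10(p)
  }
  structure(list(list_size = list_size, annotation_size = annotation_size,
                 overlap = overlap, universe = universe,
                 p_value = p, log10_p = log10p,
                 alternative = alternative),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf(
    "Enrichment: %d/%d of list in annotation (%d of %d in universe)\n  one-sided p = %.4g (log10 p = %.2f)\n",
    x$overlap, x$list_size, x$annotation_size, x$universe,
    x$p_value, x$log10_p))
  invisible(x)
}

#' Enrichment of a gene list in an annotation set
#'
#' Convenience wrapper around [hypergeom_enrichment()] that computes the
#' overlap from the sets themselves (case-insensitive symbol match). The
#' universe defaults to a user-supplied constant (e.g. the genome-wide gene
#' count) rather than the platform size.
#'
#' @param gene_list character vector or `GeneSet` of genes of interest.
#' @param annotation character vector or `GeneSet` of annotated genes.
#' @param universe background size (integer).
#' @param ... passed to [hypergeom_enrichment()].
#' @return An `EnrichmentResult`.
#' @export
enrich_gene_sets <- function(gene_list, annotation, universe, ...) {
  a <- unique(toupper(if (inherits(gene_list, "GeneSet")) gene_list$members
                      else gene_list))
  b <- unique(toupper(if (inherits(annotation, "GeneSet")) annotation$members
                      else annotation))
  hypergeom_enrichment(length(a), length(b), length(intersect(a, b)),
                       universe, ...)
}

#' Pairwise intersections of bimodal gene sets across datasets
#'
#' For every unordered pair of datasets, restricts attention to the shared
#' universe (genes assayed on both platforms — genes absent from a platform
#' are "not assayed", not "not bimodal"), intersects the two bimodal sets
#' within it, and scores the overlap with the one-sided hypergeometric
#' tail. Pairs with an empty shared universe yield a row with `NA`
#' p-value and a warning.
#'
#' @param bimodal_sets named list: dataset label -> character vector of
#'   bimodal genes.
#' @param platform_genes named list (same names): dataset label ->
#'   character vector of all genes assayed on that platform.
#' @return Data frame with one row per pair: `set_a, set_b,
#'   shared_universe, bimodal_a, bimodal_b, overlap, p_value`.
#' @export
pairwise_intersections <- function(bimodal_sets, platform_genes) {
  labels <- names(bimodal_sets)
  if (is.null(labels) || length(labels) < 2L)
    stop_validation("need >= 2 named datasets")
  if (!setequal(labels, names(platform_genes)))
    stop_validation("bimodal_sets and platform_genes must share names")
  bimodal_sets <- lapply(bimodal_sets, function(x) unique(toupper(x)))
  platform_genes <- lapply(platform_genes, function(x) unique(toupper(x)))
  pairs <- utils::combn(labels, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    shared <- intersect(platform_genes[[pr[1]]], platform_genes[[pr[2]]])
    a <- intersect(bimodal_sets[[pr[1]]], shared)
    b <- intersect(bimodal_sets[[pr[2]]], shared)
    ov <- length(intersect(a, b))
    p <- NA_real_
    if (length(shared) == 0L) {
      warning(sprintf("empty shared universe for %s vs %s", pr[1], pr[2]))
    } else {
      p <- hypergeom_enrichment(length(a), length(b), ov,
                                length(shared))$p_value
    }
    data.frame(set_a = pr[1], set_b = pr[2],
               shared_universe = length(shared),
               bimodal_a = length(a), bimodal_b = length(b),
               overlap = ov, p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Genes bimodal in at least `min_datasets` datasets
#'
#' The "commonly bimodal" call: a gene qualifies when it appears in the
#' bimodal set of at least `min_datasets` of the supplied datasets
#' (`min_datasets = 1` degenerates to the plain union).
#'
#' @param bimodal_sets list of character vectors of bimodal genes.
#' @param min_datasets minimum number of supporting datasets (default 3).
#' @return Sorted character vector of commonly bimodal genes.
#' @export
commonly_bimodal <- function(bimodal_sets, min_datasets = 3L) {
  if (min_datasets < 1L) stop_validation("min_datasets must be >= 1")
  if (min_datasets > length(bimodal_sets))
    stop_validation("min_datasets exceeds the number of datasets")
  counts <- table(unlist(lapply(bimodal_sets,
                                function(x) unique(toupper(x)))))
  sort(names(counts)[counts >= min_datasets])
}
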