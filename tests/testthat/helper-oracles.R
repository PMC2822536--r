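# Independent oracles and small fixture builders shared across tests.

# Exhaustive-scan oracle for the two-way partition: evaluates every split of
# the sorted vector directly from the definition and returns the minimal
# within-subset SS plus the set of K values tied for it (within tolerance).
brute_partition <- function(x, tol = 1e-9) {
  xs <- sort(x[!is.na(x)])
  n <- length(xs)
  g <- vapply(seq_len(n - 1L), function(k) {
    L <- xs[seq_len(k)]
    U <- xs[(k + 1L):n]
    sum((L - mean(L))^2) + sum((U - mean(U))^2)
  }, numeric(1))
  gmin <- min(g)
  list(gamma = gmin, ties = which(g <= gmin + tol * max(1, abs(gmin))))
}

# Direct log-space summation of hypergeometric point masses for the upper
# tail P(X >= ov), independent of phyper.
brute_hyper_tail <- function(list_size, annotation_size, ov, universe) {
  ks <- ov:min(list_size, annotation_size)
  lp <- stats::dhyper(ks, annotation_size, universe - annotation_size,
                      list_size, log = TRUE)
  m <- max(lp)
  exp(m + log(sum(exp(lp - m))))
}

# Write a small expression TSV from a matrix-like spec.
write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# A tiny deterministic dataset: rows with known standard deviations.
make_dataset <- function(values, gene_ids = NULL, sample_ids = NULL, ...) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- sprintf("G%03d", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(ncol(values)))
  expression_dataset(values, gene_ids, sample_ids, ...)
}

# Normalized dataset straight from a matrix of already-normalized values
# (built directly so single-sample worked examples are allowed).
make_normalized <- function(values, gene_ids = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- sprintf("G%03d", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(ncol(values)))
  dimnames(values) <- list(toupper(gene_ids), sample_ids)
  structure(list(values = values,
                 orientation = stats::setNames(
                   rep("as-is", nrow(values)), rownames(values)),
                 nu = NULL, platform = NA_character_),
            class = "NormalizedDataset")
}
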