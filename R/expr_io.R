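#' Construct an expression dataset
#'
#' The basic container of the package: a genes-by-samples matrix of
#' continuous (log-scale-like) expression values with gene and sample
#' identifiers, an optional per-sample control flag (normal/reference
#' samples), and a free-text platform label.
#'
#' Gene identifiers are case-normalized to upper case so that symbols match
#' across datasets and platforms regardless of capitalisation; they must be
#' unique after normalization. Missing values are permitted in the matrix.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids character vector of gene identifiers (defaults to
#'   `rownames(values)`).
#' @param sample_ids character vector of sample identifiers (defaults to
#'   `colnames(values)`).
#' @param control_mask optional logical vector, one entry per sample;
#'   `TRUE` marks a control/normal sample.
#' @param platform free-text platform label.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values` (matrix with dimnames), `control_mask`, `platform`.
#' @export
expression_dataset <- function(values, gene_ids = rownames(values),
                               sample_ids = colnames(values),
                               control_mask = NULL,
                               platform = NA_character_) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids))
    stop_validation("gene_ids and sample_ids are required (or set dimnames)")
  gene_ids <- toupper(as.character(gene_ids))
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids))
    stop_validation("matrix dimensions do not match identifier lengths")
  if (anyDuplicated(gene_ids))
    stop_validation("gene identifiers are not unique after case normalization")
  if (anyDuplicated(sample_ids))
    stop_validation("sample identifiers are not unique")
  if (ncol(values) < 2)
    stop_validation("at least 2 samples are required")
  if (!is.null(control_mask)) {
    control_mask <- as.logical(control_mask)
    if (length(control_mask) != ncol(values) || anyNA(control_mask))
      stop_validation("control_mask must be a logical vector with one entry per sample")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, control_mask = control_mask,
                 platform = platform),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d samples", nrow(x$values),
              ncol(x$values)))
  if (!is.na(x$platform)) cat(sprintf(" [%s]", x$platform))
  cat("\n")
  if (!is.null(x$control_mask))
    cat(sprintf("  controls: %d of %d samples\n", sum(x$control_mask),
                ncol(x$values)))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

# Split lines on tabs, erroring on ragged rows with the offending 1-based
# file line number. Comment lines (leading '#', e.g. provenance headers
# written by the command-line tool) are skipped.
.parse_tsv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  list(fields = fields, lineno = lineno)
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a tab-separated file: first row is a header whose first cell is a
#' gene-id column label and remaining cells are sample identifiers; each
#' subsequent row is a gene identifier followed by numeric values. The
#' tokens `""`, `"NA"` and `"NaN"` (configurable) are read as missing.
#' Lines starting with `#` are skipped.
#'
#' Gene order in the file is preserved. Duplicate gene identifiers (after
#' case normalization, e.g. multiple probes per symbol) are collapsed
#' according to `duplicates`:
#' \describe{
#'   \item{`"max-variance"`}{keep the row with the largest variance
#'     (a proxy for the most informative probe; the default).}
#'   \item{`"mean"`}{average the duplicate rows per sample.}
#'   \item{`"error"`}{fail on any duplicate.}
#' }
#'
#' @param path path to the TSV file.
#' @param duplicates how to collapse duplicated gene ids (see Details).
#' @param missing_tokens character cell values treated as missing.
#' @param platform optional platform label stored on the dataset.
#' @param quiet suppress the message reporting collapsed rows.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path,
                            duplicates = c("max-variance", "mean", "error"),
                            missing_tokens = c("", "NA", "NaN"),
                            platform = NA_character_, quiet = FALSE) {
  duplicates <- match.arg(duplicates)
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  parsed <- .parse_tsv_lines(path)
  fields <- parsed$fields
  if (length(fields) < 2)
    stop_parse(sprintf("no data rows in %s", path))
  header <- fields[[1]]
  if (length(header) < 2)
    stop_parse(sprintf("zero data columns in %s", path))
  sample_ids <- header[-1]
  ncols <- length(header)
  widths <- lengths(fields)
  bad <- which(widths[-1] != ncols)
  if (length(bad))
    stop_parse(sprintf("ragged row at line %d of %s: %d fields, expected %d",
                       parsed$lineno[bad[1] + 1L], path,
                       widths[bad[1] + 1L], ncols))
  body <- fields[-1]
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  cells <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  cells[cells %in% missing_tokens] <- NA_character_
  vals <- suppressWarnings(as.numeric(cells))
  bad_cell <- which(is.na(vals) & !is.na(cells))
  if (length(bad_cell)) {
    row <- (bad_cell[1] - 1L) %/% (ncols - 1L) + 1L
    stop_parse(sprintf("non-numeric value '%s' at line %d of %s",
                       cells[bad_cell[1]], parsed$lineno[row + 1L], path))
  }
  mat <- matrix(vals, nrow = length(body), ncol = ncols - 1L, byrow = TRUE)
  rownames(mat) <- toupper(gene_ids)

  dup <- duplicated(rownames(mat))
  if (any(dup)) {
    if (duplicates == "error")
      stop_validation(sprintf("duplicated gene ids (e.g. %s)",
                              rownames(mat)[dup][1]))
    n_in <- nrow(mat)
    groups <- split(seq_len(n_in), factor(rownames(mat),
                                          levels = unique(rownames(mat))))
    pick <- lapply(groups, function(idx) {
      if (length(idx) == 1L) return(mat[idx, , drop = FALSE])
      block <- mat[idx, , drop = FALSE]
      if (duplicates == "mean") {
        matrix(colMeans(block, na.rm = TRUE), nrow = 1)
      } else {
        v <- apply(block, 1, stats::var, na.rm = TRUE)
        block[which.max(v), , drop = FALSE]
      }
    })
    mat <- do.call(rbind, pick)
    rownames(mat) <- names(groups)
    if (!quiet)
      message(sprintf("read_expression: collapsed %d duplicate rows (%s rule)",
                      n_in - nrow(mat), duplicates))
  }
  colnames(mat) <- sample_ids
  expression_dataset(mat, platform = platform)
}

#' Read a sample annotation file
#'
#' TSV with a header and two columns: sample identifier and `is_control`
#' (0/1). Returns a named logical vector usable with [set_controls()].
#'
#' @param path path to the annotation TSV.
#' @return Named logical vector (`TRUE` = control sample).
#' @export
read_sample_annotation <- function(path) {
  parsed <- .parse_tsv_lines(path)
  fields <- parsed$fields
  if (length(fields) < 2) stop_parse(sprintf("no data rows in %s", path))
  body <- fields[-1]
  ids <- vapply(body, `[[`, character(1), 1L)
  flag <- vapply(body, `[[`, character(1), 2L)
  mask <- as.integer(flag)
  if (anyNA(mask) || !all(mask %in% c(0L, 1L)))
    stop_parse("is_control column must be 0/1")
  stats::setNames(mask == 1L, ids)
}

#' Attach control flags to a dataset
#'
#' @param dataset an [expression_dataset()].
#' @param controls either a named logical vector as returned by
#'   [read_sample_annotation()] (names matched against sample ids; samples
#'   absent from the vector default to non-control) or a character vector of
#'   control sample ids.
#' @return The dataset with `control_mask` set.
#' @export
set_controls <- function(dataset, controls) {
  ids <- colnames(dataset$values)
  if (is.character(controls)) {
    mask <- ids %in% controls
  } else {
    mask <- rep(FALSE, length(ids))
    hit <- match(ids, names(controls))
    mask[!is.na(hit)] <- controls[hit[!is.na(hit)]]
  }
  dataset$control_mask <- mask
  dataset
}

#' Read a gene set (one symbol per line)
#'
#' Blank lines are ignored; identifiers are case-normalized and
#' de-duplicated. Errors on an empty file.
#'
#' @param path path to the gene list.
#' @param name optional set name (defaults to the file name).
#' @return A list of class `GeneSet` with elements `name` and `members`.
#' @export
read_gene_set <- function(path, name = NULL) {
  lines <- trimws(readLines(path, warn = FALSE))
  members <- unique(toupper(lines[nzchar(lines) & !grepl("^#", lines)]))
  if (length(members) == 0L)
    stop_parse(sprintf("gene set file is empty: %s", path))
  structure(list(name = if (is.null(name)) basename(path) else name,
                 members = members),
            class = "GeneSet")
}

#' Write a tabular result as TSV
#'
#' Plain tab-separated output (no quoting, no row names). Numeric columns
#' are written at full precision so that a round-trip read reproduces the
#' values exactly; infinite tau values are serialized as `"inf"` (see
#' [write_fits()]).
#'
#' @param x a data frame (or object coercible to one).
#' @param path output path.
#' @param header_lines optional character vector of `#`-prefixed comment
#'   lines written before the table (provenance).
#' @export
write_table <- function(x, path, header_lines = NULL) {
  x <- as.data.frame(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(header_lines, con)
  utils::write.table(format(x, digits = 17, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression (or normalized) matrix as TSV
#'
#' Inverse of [read_expression()]: first column `gene`, one column per
#' sample, full numeric precision.
#'
#' @param dataset an `ExpressionDataset` or `NormalizedDataset`.
#' @param path output path.
#' @param header_lines optional `#`-prefixed provenance lines.
#' @export
write_expression <- function(dataset, path, header_lines = NULL) {
  mat <- dataset$values
  df <- data.frame(gene = rownames(mat), check.names = FALSE,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(mat, check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(header_lines, con)
  writeLines(paste(c("gene", colnames(mat)), collapse = "\t"), con)
  body <- apply(mat, 1, function(r)
    paste(ifelse(is.na(r), "NA", sprintf("%.17g", r)), collapse = "\t"))
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

#' Write sample control annotation as TSV
#'
#' @param dataset an `ExpressionDataset` with a control mask.
#' @param path output path.
#' @export
write_sample_annotation <- function(dataset, path) {
  mask <- dataset$control_mask
  if (is.null(mask)) mask <- rep(FALSE, ncol(dataset$values))
  utils::write.table(
    data.frame(sample = colnames(dataset$values),
               is_control = as.integer(mask)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
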