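#' Construct an expression matrix
#'
#' The universal payload of the package: a samples x genes matrix of
#' finite, log-scale expression values with unique sample and gene IDs.
#' Stored as a plain numeric matrix with `rownames` = samples and
#' `colnames` = genes, plus an optional `sample_labels` attribute mapping
#' samples to tissue/condition strings.
#'
#' @param values numeric matrix, samples in rows, genes in columns.
#' @param sample_ids,gene_ids character vectors of unique IDs; default to
#'   the dimnames of `values`.
#' @param sample_labels optional named character vector (names = sample
#'   IDs) of tissue/condition labels.
#' @return a validated samples x genes numeric matrix.
#' @export
expression_matrix <- function(values, sample_ids = rownames(values),
                              gene_ids = colnames(values),
                              sample_labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids) || is.null(gene_ids)) {
    gex_abort("expression matrix requires sample and gene IDs")
  }
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (length(sample_ids) != nrow(values) || length(gene_ids) != ncol(values)) {
    gex_abort("ID lengths inconsistent with matrix shape")
  }
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s)) {
    gex_abort(sprintf("duplicate sample ID(s): %s",
                      paste(unique(dup_s), collapse = ", ")))
  }
  dup_g <- gene_ids[duplicated(gene_ids)]
  if (length(dup_g)) {
    gex_abort(sprintf("duplicate gene ID(s): %s",
                      paste(unique(dup_g), collapse = ", ")))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    gex_abort(sprintf(
      "non-finite expression value at sample '%s', gene '%s'",
      sample_ids[bad[1]], gene_ids[bad[2]]))
  }
  dimnames(values) <- list(sample_ids, gene_ids)
  if (!is.null(sample_labels)) {
    sample_labels <- sample_labels[sample_ids]
    attr(values, "sample_labels") <- sample_labels
  }
  values
}

#' Sample labels of an expression matrix
#' @param expr expression matrix as built by [expression_matrix()].
#' @return named character vector or `NULL`.
#' @export
sample_labels <- function(expr) attr(expr, "sample_labels")

#' Read a delimited expression matrix
#'
#' Reads a TSV/CSV with a header row and an ID column and returns a
#' samples x genes matrix regardless of the on-disk orientation.  IDs are
#' preserved verbatim; duplicate IDs and non-numeric or missing cells are
#' fatal.  Expression is assumed already normalized/log-scaled; an
#' optional `log2p1` switch applies log2(x + 1) on load (default off).
#'
#' @param path file path; `.csv` implies comma separation, anything else
#'   tab separation (override with `sep`).
#' @param orientation `"genes_in_rows"` (default, the common expression
#'   layout) or `"samples_in_rows"`.
#' @param sep field separator override.
#' @param log2p1 apply log2(x + 1) after loading.
#' @return samples x genes expression matrix.
#' @export
read_expression <- function(path,
                            orientation = c("genes_in_rows", "samples_in_rows"),
                            sep = NULL, log2p1 = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) gex_io_abort(sprintf("file not found: %s", path))
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(
    read.delim(path, sep = sep, check.names = FALSE,
               stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) gex_io_abort(sprintf("cannot parse %s: %s",
                                             path, conditionMessage(e))))
  if (nrow(df) == 0 || ncol(df) < 2) {
    gex_io_abort(sprintf("empty or ID-only expression file: %s", path))
  }
  row_ids <- as.character(df[[1]])
  col_ids <- colnames(df)[-1]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    gex_io_abort(sprintf(
      "non-numeric cell '%s' at row %d (ID '%s'), column '%s' in %s",
      vals[bad[1], bad[2]], bad[1], row_ids[bad[1]], col_ids[bad[2]], path))
  }
  dup <- c(row_ids[duplicated(row_ids)], col_ids[duplicated(col_ids)])
  if (length(dup)) {
    gex_io_abort(sprintf("duplicate ID(s) in %s: %s", path,
                         paste(unique(dup), collapse = ", ")))
  }
  if (log2p1) num <- log2(num + 1)
  if (orientation == "genes_in_rows") {
    expression_matrix(t(num), sample_ids = col_ids, gene_ids = row_ids)
  } else {
    expression_matrix(num, sample_ids = row_ids, gene_ids = col_ids)
  }
}

#' Write an expression matrix
#'
#' Values are serialized with 17 significant digits so a write/read
#' round-trip reproduces every double exactly.
#'
#' @param expr samples x genes expression matrix.
#' @param path output path (`.csv` switches to comma separation).
#' @param orientation on-disk layout, default `"genes_in_rows"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path,
                             orientation = c("genes_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  m <- if (orientation == "genes_in_rows") t(expr) else expr
  chr <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
  out <- data.frame(id = rownames(m), chr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out) <- c(if (orientation == "genes_in_rows") "gene_id" else "sample_id",
                     colnames(m))
  ok <- tryCatch({
    write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) gex_io_abort(sprintf("cannot write %s", path))
  invisible(path)
}

#' Read / write a landmark gene list (one ID per line)
#'
#' @param path file path.
#' @return character vector of unique landmark gene IDs.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) gex_io_abort(sprintf("file not found: %s", path))
  ids <- readLines(path, warn = FALSE)
  ids <- ids[nzchar(trimws(ids))]
  ids <- trimws(ids)
  if (!length(ids)) gex_io_abort(sprintf("empty landmark list: %s", path))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    gex_io_abort(sprintf("duplicate landmark ID(s): %s",
                         paste(unique(dup), collapse = ", ")))
  }
  ids
}

#' @rdname read_landmarks
#' @param ids character vector of landmark gene IDs.
#' @export
write_landmarks <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

# report IDs present in one vector but not the other (pre-join utility;
# gene identity is matched by exact string, no symbol mapping layer)
#' Report unmatched gene IDs between two ID vectors
#' @param ids_a,ids_b character vectors.
#' @return list with `only_a`, `only_b`, `shared`.
#' @export
match_report <- function(ids_a, ids_b) {
  list(only_a = setdiff(ids_a, ids_b),
       only_b = setdiff(ids_b, ids_a),
       shared = intersect(ids_a, ids_b))
}
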