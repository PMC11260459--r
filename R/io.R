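#' Read gene annotations from a GTF file
#'
#' Parses the 9-column GTF format (1-based, inclusive coordinates; never
#' shifted) into a per-gene table of chromosome, start, end and strand.
#' Attribute parsing is permissive: `key "value"`, `key value` and
#' `key=value` all resolve; only the requested `id_attribute` is
#' required.  Records missing it are skipped with a warning count.
#'
#' @param path GTF file path.
#' @param feature feature type to keep (column 3), default `"gene"`.
#' @param id_attribute attribute naming the gene ID, default `"gene_id"`.
#' @return data.frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand` (`+`, `-` or `unknown`), class `gene_annotation`.
#' @export
read_gene_annotation <- function(path, feature = "gene",
                                 id_attribute = "gene_id") {
  if (!file.exists(path)) gex_io_abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9)) {
    gex_io_abort(sprintf("GTF line %d has %d column(s), expected 9",
                         which(nf != 9)[1], nf[nf != 9][1]))
  }
  keep <- vapply(fields, function(f) f[3] == feature, logical(1))
  if (!any(keep)) {
    warning(sprintf("no '%s' features in %s", feature, path))
    out <- data.frame(gene_id = character(), chromosome = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
    class(out) <- c("gene_annotation", "data.frame")
    return(out)
  }
  fields <- fields[keep]
  pat <- sprintf('(?:^|;)\\s*%s[ =]+"?([^";]+)"?', id_attribute)
  ids <- vapply(fields, function(f) {
    m <- regmatches(f[9], regexec(pat, f[9]))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }, character(1))
  n_missing <- sum(is.na(ids))
  if (n_missing > 0) {
    warning(sprintf("skipped %d record(s) missing attribute '%s'",
                    n_missing, id_attribute))
    fields <- fields[!is.na(ids)]
    ids <- ids[!is.na(ids)]
  }
  start <- as.integer(vapply(fields, `[`, character(1), 4))
  end <- as.integer(vapply(fields, `[`, character(1), 5))
  if (anyNA(start) || anyNA(end)) {
    gex_io_abort("non-integer GTF coordinate")
  }
  bad <- which(start > end)
  if (length(bad)) {
    gex_io_abort(sprintf("gene '%s' has start %d > end %d",
                         ids[bad[1]], start[bad[1]], end[bad[1]]))
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    gex_io_abort(sprintf("duplicate gene record(s): %s",
                         paste(unique(dup), collapse = ", ")))
  }
  strand <- vapply(fields, `[`, character(1), 7)
  strand[!strand %in% c("+", "-")] <- "unknown"
  out <- data.frame(
    gene_id = ids,
    chromosome = vapply(fields, `[`, character(1), 1),
    start = start, end = end, strand = strand,
    stringsAsFactors = FALSE, row.names = NULL)
  if (any(!nzchar(out$chromosome))) gex_io_abort("empty chromosome field")
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' Read pathway gene sets from a GMT file
#'
#' GMT standard: set name, description, then member gene IDs, all
#' tab-separated.  The description is discarded and duplicate genes
#' within a set are collapsed.
#'
#' @param path GMT file path.
#' @return named list of character vectors (one per pathway), class
#'   `pathway_collection`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) gex_io_abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      gex_io_abort(sprintf("GMT line %d has %d field(s), expected >= 3",
                           i, length(f)))
    }
    sets[[f[1]]] <- unique(f[-(1:2)])
  }
  class(sets) <- c("pathway_collection", class(sets))
  sets
}

#' Read a scored gene-pair list (STRING-style PPI or regulon TSV)
#'
#' The first two columns are taken as the pair endpoints; `score_column`
#' (and optionally `grade_column`) are resolved by header name.
#' Self-pairs are dropped with a reported count.
#'
#' @param path TSV path with a header row.
#' @param score_column header name of the numeric score column.
#' @param grade_column optional header name of a confidence-grade column
#'   (values A--E, as in regulon databases).
#' @param directed `TRUE` for TF->target lists, `FALSE` for PPI.
#' @return data.frame with columns `gene_a`, `gene_b`, `score` and
#'   optionally `grade`; attribute `directed`; class `scored_pair_list`.
#' @export
read_scored_pairs <- function(path, score_column = "score",
                              grade_column = NULL, directed = FALSE) {
  if (!file.exists(path)) gex_io_abort(sprintf("file not found: %s", path))
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 3) gex_io_abort(sprintf("expected >= 3 columns in %s", path))
  if (!score_column %in% colnames(df)) {
    gex_io_abort(sprintf("score column '%s' not found in %s (have: %s)",
                         score_column, path,
                         paste(colnames(df), collapse = ", ")))
  }
  score <- suppressWarnings(as.numeric(df[[score_column]]))
  if (anyNA(score)) {
    bad <- which(is.na(score))[1]
    gex_io_abort(sprintf("non-numeric score '%s' at row %d of %s",
                         df[[score_column]][bad], bad, path))
  }
  out <- data.frame(gene_a = as.character(df[[1]]),
                    gene_b = as.character(df[[2]]),
                    score = score, stringsAsFactors = FALSE)
  if (!is.null(grade_column)) {
    if (!grade_column %in% colnames(df)) {
      gex_io_abort(sprintf("grade column '%s' not found in %s",
                           grade_column, path))
    }
    grade <- as.character(df[[grade_column]])
    bad <- which(!grade %in% c("A", "B", "C", "D", "E", "", NA))
    if (length(bad)) {
      gex_io_abort(sprintf("invalid grade '%s' at row %d (expected A-E)",
                           grade[bad[1]], bad[1]))
    }
    out$grade <- grade
  }
  n_self <- sum(out$gene_a == out$gene_b)
  if (n_self > 0) {
    message(sprintf("read_scored_pairs: dropped %d self-pair(s)", n_self))
    out <- out[out$gene_a != out$gene_b, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "directed") <- isTRUE(directed)
  class(out) <- c("scored_pair_list", "data.frame")
  out
}

#' Read Hi-C contacts from a BEDPE-like TSV
#'
#' Expected header columns: `chrom_a`, `pos_a`, `chrom_b`, `pos_b`,
#' `score` (or any 5 columns in that order).  Positions are 1-based;
#' scores must be finite and non-negative.  Intra- vs inter-chromosomal
#' status is derivable from chromosome equality; row order is preserved.
#'
#' @param path TSV path.
#' @return data.frame with the five columns above, class `contact_list`.
#' @export
read_contacts <- function(path) {
  if (!file.exists(path)) gex_io_abort(sprintf("file not found: %s", path))
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 5) gex_io_abort(sprintf("expected >= 5 columns in %s", path))
  out <- data.frame(chrom_a = as.character(df[[1]]),
                    pos_a = suppressWarnings(as.numeric(df[[2]])),
                    chrom_b = as.character(df[[3]]),
                    pos_b = suppressWarnings(as.numeric(df[[4]])),
                    score = suppressWarnings(as.numeric(df[[5]])),
                    stringsAsFactors = FALSE)
  if (nrow(out)) {
    if (anyNA(out$pos_a) || anyNA(out$pos_b) || anyNA(out$score)) {
      gex_io_abort(sprintf("non-numeric position or score in %s", path))
    }
    if (any(out$pos_a < 1) || any(out$pos_b < 1)) {
      bad <- which(out$pos_a < 1 | out$pos_b < 1)[1]
      gex_io_abort(sprintf("contact position < 1 at row %d of %s", bad, path))
    }
    if (any(!is.finite(out$score)) || any(out$score < 0)) {
      gex_io_abort(sprintf("negative or non-finite contact score in %s", path))
    }
  }
  class(out) <- c("contact_list", "data.frame")
  out
}

#' Write edge sets or a merged gene graph to a canonical edge-list TSV
#'
#' Columns `gene_a`, `gene_b`, `edge_type`, `weight`, one row per
#' (edge, type); undirected edges are written with
#' `gene_a < gene_b` lexicographically.  The file is loadable by
#' [read_scored_pairs()] (score column `weight`) and by [read_edges()].
#'
#' @param x an `edge_set`, a list of edge sets, or a `gene_graph` (its
#'   typed sets are written).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(x, path) {
  sets <- if (inherits(x, "gene_graph")) {
    x$edge_sets
  } else if (inherits(x, "edge_set")) {
    list(x)
  } else {
    x
  }
  rows <- lapply(sets, function(es) {
    if (!nrow(es)) return(NULL)
    w <- if ("weight" %in% colnames(es)) es$weight else rep(1, nrow(es))
    data.frame(gene_a = es$gene_a, gene_b = es$gene_b,
               edge_type = attr(es, "edge_type") %||% "edge",
               weight = sprintf("%.17g", w), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_a = character(), gene_b = character(),
                      edge_type = character(), weight = character())
  }
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) gex_io_abort(sprintf("cannot write %s", path))
  invisible(path)
}

#' Read a canonical edge-list TSV back into typed edge sets
#'
#' @param path TSV written by [write_edges()].
#' @return named list of `edge_set` objects, one per `edge_type` present
#'   (type `tf` is flagged directed).
#' @export
read_edges <- function(path) {
  if (!file.exists(path)) gex_io_abort(sprintf("file not found: %s", path))
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b", "edge_type", "weight") %in% colnames(df))) {
    gex_io_abort(sprintf("%s is not a canonical edge-list TSV", path))
  }
  types <- unique(df$edge_type)
  sets <- lapply(types, function(ty) {
    sub <- df[df$edge_type == ty, , drop = FALSE]
    edge_set(sub$gene_a, sub$gene_b, weight = as.numeric(sub$weight),
             type = ty, directed = identical(ty, "tf"))
  })
  names(sets) <- types
  sets
}
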