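#' Construct a typed edge set
#'
#' A typed set of gene-gene edges.  Undirected sets store each pair once
#' in canonical (`gene_a < gene_b`) order; self-loops are forbidden;
#' weights, when present, must be finite (they become the e_{j,i} of the
#' graph-convolution propagation when a weighted merge is requested).
#'
#' @param gene_a,gene_b character endpoint vectors.
#' @param weight optional numeric weights.
#' @param type edge-type label; the builders use `correlation`,
#'   `pathway`, `ppi`, `tf`, `chrom_distance`, `hic_intra`, `hic_inter`.
#' @param directed only transcription-factor edge sets are directed.
#' @param dedup collapse duplicate pairs, keeping the maximum weight.
#' @return data.frame with columns `gene_a`, `gene_b`, `weight`;
#'   attributes `edge_type`, `directed`; class `edge_set`.
#' @export
edge_set <- function(gene_a = character(), gene_b = character(),
                     weight = NULL, type = "edge", directed = FALSE,
                     dedup = TRUE) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  if (length(gene_a) != length(gene_b)) gex_abort("endpoint length mismatch")
  if (any(gene_a == gene_b)) gex_abort("self-loop in edge set")
  if (is.null(weight)) weight <- rep(1, length(gene_a))
  if (any(!is.finite(weight))) gex_abort("non-finite edge weight")
  if (!directed && length(gene_a)) {
    cp <- canonicalize_pairs(gene_a, gene_b)
    gene_a <- cp$gene_a
    gene_b <- cp$gene_b
  }
  df <- data.frame(gene_a = gene_a, gene_b = gene_b, weight = weight,
                   stringsAsFactors = FALSE)
  if (dedup && nrow(df)) {
    key <- paste(df$gene_a, df$gene_b, sep = "\r")
    if (anyDuplicated(key)) {
      w <- tapply(df$weight, key, max)
      df <- df[!duplicated(key), , drop = FALSE]
      df$weight <- as.numeric(w[paste(df$gene_a, df$gene_b, sep = "\r")])
    }
  }
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "edge_type") <- type
  attr(df, "directed") <- isTRUE(directed)
  class(df) <- c("edge_set", "data.frame")
  df
}

#' @export
print.edge_set <- function(x, ...) {
  cat(sprintf("<edge_set '%s'%s: %d edge(s)>\n", attr(x, "edge_type"),
              if (attr(x, "directed")) ", directed" else "", nrow(x)))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

edge_keys <- function(es) paste(es$gene_a, es$gene_b, sep = "\r")

#' Co-expression edges by Pearson correlation threshold
#'
#' Connects gene pairs whose Pearson correlation across samples exceeds
#' `r_min` (strictly).  The threshold is applied to signed r by default,
#' following the convention of connecting positively co-expressed pairs;
#' `use_absolute = TRUE` also admits strong anti-correlation.
#' Zero-variance genes are excluded with a warning.
#'
#' @param expr samples x genes expression matrix.
#' @param r_min correlation threshold, default 0.9.
#' @param use_absolute threshold |r| instead of r.
#' @return `edge_set` of type `correlation`, weights = r.
#' @export
correlation_edges <- function(expr, r_min = 0.9, use_absolute = FALSE) {
  if (nrow(expr) < 3) gex_abort("need >= 3 samples for correlation edges")
  v <- apply(expr, 2, stats::sd)
  if (any(v == 0)) {
    warning(sprintf("excluding %d zero-variance gene(s)", sum(v == 0)))
    expr <- expr[, v > 0, drop = FALSE]
  }
  if (ncol(expr) < 2) {
    return(edge_set(type = "correlation"))
  }
  r <- stats::cor(expr)
  ut <- upper.tri(r)
  hit <- if (use_absolute) abs(r) > r_min else r > r_min
  idx <- which(ut & hit, arr.ind = TRUE)
  edge_set(colnames(expr)[idx[, 1]], colnames(expr)[idx[, 2]],
           weight = r[idx], type = "correlation")
}

#' Chromosomal distance between two genes
#'
#' Distance between gene center points: D = |(m1 + n1)/2 - (m2 + n2)/2|
#' with start/end midpoints kept fractional.  Both genes must lie on the
#' same chromosome; callers pre-filter cross-chromosome pairs.
#'
#' @param a,b single annotation records (one-row data.frames or lists
#'   with `chromosome`, `start`, `end`).
#' @return distance in base pairs (real-valued).
#' @export
chromosomal_distance <- function(a, b) {
  if (as.character(a$chromosome) != as.character(b$chromosome)) {
    gex_abort(sprintf("genes on different chromosomes (%s vs %s)",
                      a$chromosome, b$chromosome),
              class = "gexgraph_chromosome_error")
  }
  abs((a$start + a$end) / 2 - (b$start + b$end) / 2)
}

#' Genomic-proximity edges from the closest intra-chromosomal pairs
#'
#' All intra-chromosomal gene pairs are pooled genome-wide and ranked by
#' center-to-center distance; the `quantile` fraction with smallest
#' distance (the closest pairs) become edges.  Ties at the cutoff are
#' broken by canonical pair order.
#'
#' @param annot gene annotation table ([read_gene_annotation()]).
#' @param quantile fraction of intra-chromosomal pairs to keep, in
#'   (0, 1]; default 0.10.
#' @return `edge_set` of type `chrom_distance`, weights = distance in bp.
#' @export
proximity_edges <- function(annot, quantile = 0.10) {
  if (!(quantile > 0 && quantile <= 1)) gex_abort("quantile must be in (0, 1]")
  mids <- (annot$start + annot$end) / 2
  pieces <- lapply(split(seq_len(nrow(annot)), annot$chromosome), function(ix) {
    if (length(ix) < 2) return(NULL)
    pr <- unrank_pairs(seq_len(choose(length(ix), 2)), length(ix))
    i <- ix[pr[, 1]]
    j <- ix[pr[, 2]]
    data.frame(gene_a = annot$gene_id[i], gene_b = annot$gene_id[j],
               d = abs(mids[i] - mids[j]), stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pieces)
  if (is.null(pairs) || !nrow(pairs)) {
    warning("no intra-chromosomal gene pair; empty proximity edge set")
    return(edge_set(type = "chrom_distance"))
  }
  cp <- canonicalize_pairs(pairs$gene_a, pairs$gene_b)
  pairs$gene_a <- cp$gene_a
  pairs$gene_b <- cp$gene_b
  m <- ceiling(quantile * nrow(pairs))
  ord <- order(pairs$d, pairs$gene_a, pairs$gene_b)
  sel <- pairs[ord[seq_len(m)], , drop = FALSE]
  edge_set(sel$gene_a, sel$gene_b, weight = sel$d, type = "chrom_distance")
}

#' Pathway edges: 2N random within-set edges per pathway
#'
#' For a pathway of N genes, min(2N, N(N-1)/2) distinct unordered pairs
#' are sampled uniformly without replacement (small pathways thus get
#' the complete graph).  Each pathway draws from its own sub-stream,
#' indexed by pathway order, so the topology is reproducible per seed
#' and fixed at graph-build time.  Singleton pathways are skipped with a
#' warning; the union across pathways is deduplicated.
#'
#' @param pathways `pathway_collection` (named list of gene-ID vectors).
#' @param seed integer seed.
#' @param edges_per_gene edges sampled per member gene, default 2.
#' @return `edge_set` of type `pathway`.
#' @export
pathway_edges <- function(pathways, seed, edges_per_gene = 2) {
  skipped <- 0L
  parts <- vector("list", length(pathways))
  for (p in seq_along(pathways)) {
    genes <- unique(as.character(pathways[[p]]))
    n <- length(genes)
    if (n < 2) {
      skipped <- skipped + 1L
      next
    }
    n_pairs <- choose(n, 2)
    m <- min(edges_per_gene * n, n_pairs)
    idx <- with_seed(derive_seed(seed, sprintf("pathway-%d", p)),
                     sample.int(n_pairs, m))
    pr <- unrank_pairs(sort(idx), n)
    parts[[p]] <- data.frame(gene_a = genes[pr[, 1]], gene_b = genes[pr[, 2]],
                             stringsAsFactors = FALSE)
  }
  if (skipped > 0) {
    warning(sprintf("skipped %d singleton pathway(s)", skipped))
  }
  all <- do.call(rbind, parts)
  if (is.null(all)) return(edge_set(type = "pathway"))
  edge_set(all$gene_a, all$gene_b, type = "pathway")
}

#' Top-k scored edges (PPI / TF regulon selection)
#'
#' Applies an optional confidence-grade filter, then keeps the `k`
#' pairs with highest score; ties at the boundary are broken by
#' canonical pair order.  Directedness is inherited from the input.
#'
#' @param pairs `scored_pair_list` from [read_scored_pairs()].
#' @param k number of edges to keep (`Inf` or k > available keeps all).
#' @param grade_filter optional character set of grades to retain, e.g.
#'   `c("A", "B")` for high-confidence regulon pairs.
#' @param type edge-type label, default `"ppi"` (use `"tf"` for regulons).
#' @return `edge_set` with weights = scores.
#' @export
top_scored_edges <- function(pairs, k = Inf, grade_filter = NULL,
                             type = if (isTRUE(attr(pairs, "directed"))) "tf" else "ppi") {
  if (!(is.numeric(k) && length(k) == 1 && k >= 1)) gex_abort("k must be >= 1")
  directed <- isTRUE(attr(pairs, "directed"))
  df <- as.data.frame(pairs)
  if (!is.null(grade_filter)) {
    if (!"grade" %in% colnames(df)) {
      gex_abort("grade filter requested but pair list has no grades")
    }
    df <- df[df$grade %in% grade_filter, , drop = FALSE]
  }
  if (!nrow(df)) return(edge_set(type = type, directed = directed))
  if (!directed) {
    cp <- canonicalize_pairs(df$gene_a, df$gene_b)
    df$gene_a <- cp$gene_a
    df$gene_b <- cp$gene_b
  }
  ord <- order(-df$score, df$gene_a, df$gene_b)
  df <- df[ord[seq_len(min(k, nrow(df)))], , drop = FALSE]
  edge_set(df$gene_a, df$gene_b, weight = df$score, type = type,
           directed = directed)
}

#' Hi-C contact edges (intra- and inter-chromosomal)
#'
#' Each contact endpoint is assigned to every gene whose center lies
#' within `assign_window` bp of the endpoint position (on the endpoint's
#' chromosome).  The resulting gene pairs are ranked by descending
#' contact score -- stronger contact meaning closer in 3D -- separately
#' for intra- and inter-chromosomal contacts, and the top `k` of each
#' class are kept.  A pair reached by several contacts takes the
#' maximum score.
#'
#' @param contacts `contact_list` from [read_contacts()].
#' @param annot gene annotation table.
#' @param k_intra,k_inter edges kept per class, default 100000.
#' @param assign_window endpoint-to-gene-center assignment window in bp,
#'   default 500000 (Hi-C bin scale).
#' @return list with `edge_set`s `hic_intra` and `hic_inter`.
#' @export
hic_edges <- function(contacts, annot, k_intra = 100000, k_inter = 100000,
                      assign_window = 500000) {
  mids <- (annot$start + annot$end) / 2
  by_chrom <- split(seq_len(nrow(annot)), annot$chromosome)
  assign_genes <- function(chrom, pos) {
    ix <- by_chrom[[chrom]]
    if (is.null(ix)) return(character(0))
    annot$gene_id[ix[abs(mids[ix] - pos) <= assign_window]]
  }
  intra <- list()
  inter <- list()
  n_unmapped <- 0L
  for (r in seq_len(nrow(contacts))) {
    ga <- assign_genes(contacts$chrom_a[r], contacts$pos_a[r])
    gb <- assign_genes(contacts$chrom_b[r], contacts$pos_b[r])
    if (!length(ga) || !length(gb)) {
      n_unmapped <- n_unmapped + 1L
      next
    }
    pairs <- expand.grid(gene_a = ga, gene_b = gb,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$gene_a != pairs$gene_b, , drop = FALSE]
    if (!nrow(pairs)) next
    pairs$score <- contacts$score[r]
    slot <- if (contacts$chrom_a[r] == contacts$chrom_b[r]) "intra" else "inter"
    if (slot == "intra") intra[[length(intra) + 1L]] <- pairs
    else inter[[length(inter) + 1L]] <- pairs
  }
  if (!length(intra) && !length(inter)) {
    warning(sprintf("no contact could be assigned to genes (%d unmapped)",
                    n_unmapped))
  }
  pick <- function(parts, k, type) {
    if (!length(parts)) return(edge_set(type = type))
    df <- do.call(rbind, parts)
    cp <- canonicalize_pairs(df$gene_a, df$gene_b)
    df$gene_a <- cp$gene_a
    df$gene_b <- cp$gene_b
    key <- paste(df$gene_a, df$gene_b, sep = "\r")
    w <- tapply(df$score, key, max)
    df <- df[!duplicated(key), , drop = FALSE]
    df$score <- as.numeric(w[paste(df$gene_a, df$gene_b, sep = "\r")])
    ord <- order(-df$score, df$gene_a, df$gene_b)
    df <- df[ord[seq_len(min(k, nrow(df)))], , drop = FALSE]
    edge_set(df$gene_a, df$gene_b, weight = df$score, type = type)
  }
  list(hic_intra = pick(intra, k_intra, "hic_intra"),
       hic_inter = pick(inter, k_inter, "hic_inter"))
}
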