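#' Merge typed edge sets into a gene graph
#'
#' Produces one merged undirected adjacency over the given node set.
#' Directed (TF) edges are symmetrized for message passing, with their
#' direction retained as metadata; parallel typed edges collapse to a
#' single merged edge carrying the set of contributing types; edges with
#' endpoints outside `node_ids` are dropped with a reported count.
#'
#' The merged edge weight e_{j,i} is controlled by `weight_reducer`:
#' `"unit"` (default) sets every merged weight to 1 (unweighted
#' propagation), `"max"`/`"sum"` reduce the typed weights.
#'
#' @param node_ids ordered gene IDs (graph nodes).
#' @param edge_sets list of `edge_set` objects.
#' @param weight_reducer `"unit"`, `"max"` or `"sum"`.
#' @return object of class `gene_graph`: list with `nodes`, merged
#'   `edges` (gene_a, gene_b, types, weight), the retained typed
#'   `edge_sets`, and `directed_edges` metadata.
#' @export
merge_graph <- function(node_ids, edge_sets,
                        weight_reducer = c("unit", "max", "sum")) {
  weight_reducer <- match.arg(weight_reducer)
  node_ids <- as.character(node_ids)
  if (!length(node_ids)) gex_abort("empty node list")
  if (anyDuplicated(node_ids)) gex_abort("duplicate node IDs")
  if (inherits(edge_sets, "edge_set")) edge_sets <- list(edge_sets)
  n_dropped <- 0L
  directed_edges <- list()
  kept <- list()
  for (es in edge_sets) {
    ty <- attr(es, "edge_type") %||% "edge"
    ok <- es$gene_a %in% node_ids & es$gene_b %in% node_ids
    n_dropped <- n_dropped + sum(!ok)
    es2 <- es[ok, , drop = FALSE]
    if (isTRUE(attr(es, "directed")) && nrow(es2)) {
      directed_edges[[length(directed_edges) + 1L]] <-
        data.frame(from = es2$gene_a, to = es2$gene_b, type = ty,
                   stringsAsFactors = FALSE)
      cp <- canonicalize_pairs(es2$gene_a, es2$gene_b)
      es2 <- edge_set(cp$gene_a, cp$gene_b, weight = es2$weight,
                      type = ty, directed = FALSE)
    } else {
      es2 <- edge_set(es2$gene_a, es2$gene_b, weight = es2$weight,
                      type = ty, directed = FALSE)
    }
    kept[[length(kept) + 1L]] <- es2
  }
  if (n_dropped > 0) {
    message(sprintf("merge_graph: dropped %d edge(s) with endpoints outside the node set",
                    n_dropped))
  }
  names(kept) <- vapply(kept, function(e) attr(e, "edge_type"), character(1))
  all <- do.call(rbind, lapply(kept, function(es) {
    if (!nrow(es)) return(NULL)
    data.frame(gene_a = es$gene_a, gene_b = es$gene_b,
               type = attr(es, "edge_type"), weight = es$weight,
               stringsAsFactors = FALSE)
  }))
  if (is.null(all)) {
    merged <- data.frame(gene_a = character(), gene_b = character(),
                         types = character(), weight = numeric(),
                         stringsAsFactors = FALSE)
  } else {
    key <- paste(all$gene_a, all$gene_b, sep = "\r")
    types <- vapply(split(all$type, key),
                    function(t) paste(sort(unique(t)), collapse = ","),
                    character(1))
    wred <- switch(weight_reducer,
                   unit = vapply(split(all$weight, key), function(w) 1.0, 1.0),
                   max = vapply(split(all$weight, key), max, 1.0),
                   sum = vapply(split(all$weight, key), sum, 1.0))
    first <- !duplicated(key)
    merged <- data.frame(gene_a = all$gene_a[first], gene_b = all$gene_b[first],
                         types = types[key[first]],
                         weight = as.numeric(wred[key[first]]),
                         stringsAsFactors = FALSE)
    merged <- merged[order(merged$gene_a, merged$gene_b), , drop = FALSE]
    rownames(merged) <- NULL
  }
  structure(list(nodes = node_ids, edges = merged, edge_sets = kept,
                 directed_edges = if (length(directed_edges))
                   do.call(rbind, directed_edges) else NULL,
                 weight_reducer = weight_reducer),
            class = "gene_graph")
}

#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf("<gene_graph: %d nodes, %d merged edges (%s)>\n",
              length(x$nodes), nrow(x$edges),
              paste(sprintf("%s: %d", names(x$edge_sets),
                            vapply(x$edge_sets, nrow, 1L)), collapse = ", ")))
  invisible(x)
}

#' Sparse merged adjacency of a gene graph
#'
#' @param graph `gene_graph`.
#' @return symmetric sparse matrix of merged edge weights e_{j,i}
#'   (no self-loops).
#' @export
graph_adjacency <- function(graph) {
  n <- length(graph$nodes)
  idx <- stats::setNames(seq_len(n), graph$nodes)
  e <- graph$edges
  if (!nrow(e)) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n),
                                dimnames = list(graph$nodes, graph$nodes)))
  }
  i <- idx[e$gene_a]
  j <- idx[e$gene_b]
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = rep(e$weight, 2),
                       dims = c(n, n),
                       dimnames = list(graph$nodes, graph$nodes))
}

#' Node degrees of the merged graph
#'
#' @param graph `gene_graph`.
#' @return list with `degree` (neighbor counts |N(i)|) and `dhat`
#'   (1 + sum of incident edge weights, the normalization degree of the
#'   graph-convolution propagation; >= 1 everywhere).
#' @export
graph_degrees <- function(graph) {
  A <- graph_adjacency(graph)
  list(degree = as.integer(Matrix::rowSums(A != 0)),
       dhat = 1 + as.numeric(Matrix::rowSums(A)))
}

#' Symmetric-normalized propagation matrix of a gene graph
#'
#' S = Dhat^(-1/2) (A + I) Dhat^(-1/2) with dhat_i = 1 + sum_j e_{j,i}
#' and unit self-loops: one application of S performs the
#' graph-convolution message-passing step.
#'
#' @param graph `gene_graph`.
#' @return sparse n x n matrix.
#' @export
gcn_propagation_matrix <- function(graph) {
  A <- graph_adjacency(graph)
  n <- nrow(A)
  dhat <- 1 + as.numeric(Matrix::rowSums(A))
  Dinv <- Matrix::Diagonal(n, x = 1 / sqrt(dhat))
  Dinv %*% (A + Matrix::Diagonal(n)) %*% Dinv
}

#' Overlap proportion between two undirected edge sets
#'
#' @param set_a,set_b undirected `edge_set`s.
#' @return list with `proportion` = |A intersect B| / |A| (fraction of
#'   A's pairs also in B; `NA` with a warning when A is empty) and the
#'   symmetric `jaccard` = |A intersect B| / |A union B|.
#' @export
overlap_proportion <- function(set_a, set_b) {
  if (isTRUE(attr(set_a, "directed")) || isTRUE(attr(set_b, "directed"))) {
    gex_abort("overlap_proportion expects undirected edge sets")
  }
  ka <- edge_keys(set_a)
  kb <- edge_keys(set_b)
  inter <- length(intersect(ka, kb))
  uni <- length(union(ka, kb))
  if (!length(ka)) {
    warning("empty reference edge set; overlap proportion undefined")
    return(list(proportion = NA_real_,
                jaccard = if (uni) inter / uni else NA_real_))
  }
  list(proportion = inter / length(ka),
       jaccard = if (uni) inter / uni else NA_real_)
}

#' Random-edge connectivity simulation
#'
#' For each node count N, draws `iterations` uniform random graphs with
#' m = min(round(factor * N), N(N-1)/2) distinct edges and records the
#' fraction of the N nodes inside the largest connected component.
#' This quantifies how reliably ~2N random edges connect a pathway of N
#' genes: the per-N summaries report the mean and median coverage and
#' the fraction of draws that were fully connected.
#'
#' @param n_values integer node counts.
#' @param edges_per_node_factor edges drawn per node, default 2.
#' @param iterations draws per node count, default 1000.
#' @param seed integer seed.
#' @return object of class `coverage_table`: list with `per_iteration`
#'   (n, factor, iteration, coverage) and `summary` (n, factor,
#'   mean_coverage, median_coverage, frac_fully_connected).
#' @export
connectivity_simulation <- function(n_values, edges_per_node_factor = 2.0,
                                    iterations = 1000, seed = 1) {
  if (any(n_values < 2)) gex_abort("node counts must be >= 2")
  if (!is_count(iterations)) gex_abort("iterations must be a positive integer")
  rows <- list()
  for (n in n_values) {
    n_pairs <- choose(n, 2)
    m <- min(round(edges_per_node_factor * n), n_pairs)
    cov <- with_seed(derive_seed(seed, sprintf("conn-%d", n)), {
      vapply(seq_len(iterations), function(it) {
        if (m == 0) return(1 / n)
        idx <- sample.int(n_pairs, m)
        pr <- unrank_pairs(idx, n)
        g <- igraph::make_graph(as.vector(t(pr)), n = n, directed = FALSE)
        max(igraph::components(g)$csize) / n
      }, numeric(1))
    })
    rows[[length(rows) + 1L]] <- data.frame(
      n = n, factor = edges_per_node_factor,
      iteration = seq_len(iterations), coverage = cov)
  }
  per_it <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per_it, per_it$n), function(d) {
    data.frame(n = d$n[1], factor = d$factor[1],
               mean_coverage = mean(d$coverage),
               median_coverage = stats::median(d$coverage),
               frac_fully_connected = mean(d$coverage == 1))
  }))
  rownames(summ) <- NULL
  structure(list(per_iteration = per_it, summary = summ),
            class = "coverage_table")
}

#' @export
print.coverage_table <- function(x, ...) {
  cat("<coverage_table>\n")
  print(x$summary)
  invisible(x)
}
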