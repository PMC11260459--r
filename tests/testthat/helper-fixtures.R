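# fixtures are built in code at test time; nothing is stored on disk

# small expression matrix with named samples/genes
tiny_expr <- function(samples = 10, genes = 5, seed = 1) {
  set.seed(seed)
  expression_matrix(matrix(rnorm(samples * genes), samples, genes),
                    sample_ids = sprintf("s%02d", seq_len(samples)),
                    gene_ids = sprintf("g%02d", seq_len(genes)))
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# uniform random gene graph with optional random weights
random_gene_graph <- function(n, m, seed = 1, weighted = TRUE) {
  set.seed(seed)
  ids <- sprintf("n%03d", seq_len(n))
  n_pairs <- choose(n, 2)
  m <- min(m, n_pairs)
  idx <- sample.int(n_pairs, m)
  pr <- gexgraph:::unrank_pairs(idx, n)
  w <- if (weighted) runif(m, 0.2, 2) else rep(1, m)
  es <- edge_set(ids[pr[, 1]], ids[pr[, 2]], weight = w, type = "correlation")
  merge_graph(ids, list(es), weight_reducer = if (weighted) "max" else "unit")
}

# independent dense formula for the normalized propagation: the oracle
# against which the sparse implementation is checked
dense_gcn_oracle <- function(graph, X, theta) {
  ids <- graph$nodes
  n <- length(ids)
  A <- matrix(0, n, n)
  for (k in seq_len(nrow(graph$edges))) {
    i <- match(graph$edges$gene_a[k], ids)
    j <- match(graph$edges$gene_b[k], ids)
    A[i, j] <- A[j, i] <- graph$edges$weight[k]
  }
  dhat <- 1 + rowSums(A)
  S <- diag(1 / sqrt(dhat)) %*% (A + diag(n)) %*% diag(1 / sqrt(dhat))
  S %*% X %*% theta
}

# brute-force all-pairs correlation thresholding (independent of
# correlation_edges' vectorized path)
brute_correlation_pairs <- function(expr, r_min) {
  g <- colnames(expr)
  out <- character(0)
  for (i in seq_along(g)) {
    for (j in seq_along(g)) {
      if (i < j && cor(expr[, i], expr[, j]) > r_min) {
        out <- c(out, paste(sort(c(g[i], g[j])), collapse = "|"))
      }
    }
  }
  sort(out)
}

edge_pair_ids <- function(es) {
  sort(paste(es$gene_a, es$gene_b, sep = "|"))
}
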