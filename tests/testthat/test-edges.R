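test_that("correlation edges follow the signed threshold and the brute-force oracle", {
  set.seed(3)
  base <- rnorm(30)
  expr <- expression_matrix(cbind(a = base, b = 2 * base, c = -base,
                                  d = rnorm(30)),
                            sample_ids = sprintf("s%02d", 1:30),
                            gene_ids = c("a", "b", "c", "d"))
  es <- correlation_edges(expr, r_min = 0.9)
  expect_equal(edge_pair_ids(es), "a|b")        # colinear pair only
  # anti-correlated pair excluded by default, admitted with |r|
  es_abs <- correlation_edges(expr, r_min = 0.9, use_absolute = TRUE)
  expect_true("a|c" %in% edge_pair_ids(es_abs))

  # 20 genes x 50 samples against the direct all-pairs loop
  big <- tiny_expr(samples = 50, genes = 20, seed = 11)
  for (r_min in c(0.1, 0.3)) {
    es <- correlation_edges(big, r_min = r_min)
    expect_identical(edge_pair_ids(es), brute_correlation_pairs(big, r_min))
  }

  expect_error(correlation_edges(big[1:2, ]), "3 samples",
               class = "gexgraph_validation_error")
  const <- expression_matrix(cbind(a = rep(1, 10), b = rnorm(10),
                                   c = rnorm(10)),
                             sample_ids = paste0("s", 1:10),
                             gene_ids = c("a", "b", "c"))
  expect_warning(correlation_edges(const, r_min = 0.99), "zero-variance")
})

test_that("correlation threshold extremes behave as the definition implies", {
  big <- tiny_expr(samples = 20, genes = 8, seed = 5)
  expect_equal(nrow(correlation_edges(big, r_min = -1)), choose(8, 2))
  exact <- correlation_edges(big, r_min = 1)        # strict >: nothing
  expect_equal(nrow(exact), 0L)
  # permutation invariance up to canonical ordering
  perm <- big[, sample(ncol(big))]
  expect_identical(edge_pair_ids(correlation_edges(big, 0.2)),
                   edge_pair_ids(correlation_edges(perm, 0.2)))
})

test_that("chromosomal distance is the midpoint separation, kept fractional", {
  rec <- function(chrom, s, e) list(chromosome = chrom, start = s, end = e)
  expect_equal(chromosomal_distance(rec("chr1", 100, 200),
                                    rec("chr1", 400, 500)), 300)
  expect_equal(chromosomal_distance(rec("chr1", 100, 200),
                                    rec("chr1", 100, 200)), 0)
  expect_equal(chromosomal_distance(rec("chr1", 0, 3), rec("chr1", 3, 4)), 2)
  expect_error(chromosomal_distance(rec("chr1", 1, 2), rec("chr2", 1, 2)),
               class = "gexgraph_chromosome_error")
})

test_that("proximity edges select the closest intra-chromosomal pairs", {
  annot <- data.frame(gene_id = c("g1", "g2", "g3"),
                      chromosome = "chr1",
                      start = c(50, 150, 950), end = c(150, 250, 1050),
                      strand = "+")
  es <- proximity_edges(annot, quantile = 1 / 3)
  expect_equal(edge_pair_ids(es), "g1|g2")          # closest of the 3 pairs
  expect_equal(es$weight, 100)
  expect_equal(nrow(proximity_edges(annot, quantile = 1)), 3L)

  split_chrom <- annot
  split_chrom$chromosome <- c("chr1", "chr2", "chr3")
  expect_warning(empty <- proximity_edges(split_chrom, 0.1),
                 "no intra-chromosomal")
  expect_equal(nrow(empty), 0L)

  # output size equals ceil(quantile * n_pairs)
  set.seed(8)
  big <- data.frame(gene_id = sprintf("g%02d", 1:20),
                    chromosome = rep(c("chr1", "chr2"), each = 10),
                    start = sample.int(1e6, 20), strand = "+")
  big$end <- big$start + 1000
  n_pairs <- 2 * choose(10, 2)
  for (q in c(0.1, 0.25, 0.8)) {
    expect_equal(nrow(proximity_edges(big, q)), ceiling(q * n_pairs))
  }
})

test_that("pathway sets contribute 2N random within-set edges", {
  p5 <- list(P1 = letters[1:5])
  class(p5) <- c("pathway_collection", "list")
  es5 <- pathway_edges(p5, seed = 1)
  expect_equal(nrow(es5), 10L)                 # 2N = C(5,2): complete graph
  expect_equal(edge_pair_ids(es5),
               sort(apply(combn(letters[1:5], 2), 2, paste, collapse = "|")))

  p10 <- list(P1 = sprintf("g%02d", 1:10))
  class(p10) <- c("pathway_collection", "list")
  es10 <- pathway_edges(p10, seed = 4)
  expect_equal(nrow(es10), 20L)                # exactly 2N distinct edges
  expect_true(all(c(es10$gene_a, es10$gene_b) %in% p10$P1))
  expect_true(all(es10$gene_a != es10$gene_b))
  expect_false(anyDuplicated(edge_pair_ids(es10)) > 0)

  # determinism contract
  expect_identical(pathway_edges(p10, seed = 4), es10)
  expect_false(identical(edge_pair_ids(pathway_edges(p10, seed = 5)),
                         edge_pair_ids(es10)))

  singleton <- list(P1 = "a", P2 = c("x", "y"))
  class(singleton) <- c("pathway_collection", "list")
  expect_warning(es <- pathway_edges(singleton, seed = 1), "singleton")
  expect_equal(edge_pair_ids(es), "x|y")
})

test_that("top-scored selection honors grade filters and descending-score top-k", {
  pairs <- data.frame(gene_a = c("a", "b", "c", "d", "e"),
                      gene_b = c("x", "y", "z", "w", "v"),
                      score = c(0.5, 0.9, 0.7, 0.9, 0.1),
                      grade = c("A", "B", "C", "A", "B"))
  attr(pairs, "directed") <- FALSE
  class(pairs) <- c("scored_pair_list", "data.frame")

  top2 <- top_scored_edges(pairs, k = 2)
  expect_setequal(top2$weight, c(0.9, 0.9))
  # tie at the boundary broken by canonical pair order
  expect_equal(edge_pair_ids(top_scored_edges(pairs, k = 1))[1], "b|y")

  ab <- top_scored_edges(pairs, k = Inf, grade_filter = c("A", "B"))
  expect_equal(nrow(ab), 4L)
  expect_false("c|z" %in% edge_pair_ids(ab))

  expect_equal(nrow(top_scored_edges(pairs, k = 100)), 5L)
  expect_error(top_scored_edges(pairs, k = 0), "k must be")
})

test_that("Hi-C edges map contacts to nearby gene centers, max-scored and top-k", {
  annot <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                      chromosome = c("chr1", "chr1", "chr1", "chr2"),
                      start = c(1000, 21000, 61000, 1000),
                      end = c(2000, 22000, 62000, 2000), strand = "+")
  mk <- function(...) {
    df <- as.data.frame(rbind(...), stringsAsFactors = FALSE)
    colnames(df) <- c("chrom_a", "pos_a", "chrom_b", "pos_b", "score")
    df$pos_a <- as.numeric(df$pos_a); df$pos_b <- as.numeric(df$pos_b)
    df$score <- as.numeric(df$score)
    class(df) <- c("contact_list", "data.frame")
    df
  }
  single <- mk(c("chr1", 1500, "chr1", 21500, 5))
  res <- hic_edges(single, annot, assign_window = 2000)
  expect_equal(edge_pair_ids(res$hic_intra), "g1|g2")
  expect_equal(nrow(res$hic_inter), 0L)

  dup <- mk(c("chr1", 1500, "chr1", 21500, 3),
            c("chr1", 1600, "chr1", 21400, 7))
  res <- hic_edges(dup, annot, assign_window = 2000)
  expect_equal(nrow(res$hic_intra), 1L)
  expect_equal(res$hic_intra$weight, 7)        # max over repeated contacts

  # toy list against exhaustive enumeration with k_intra = 2
  toy <- mk(c("chr1", 1500, "chr1", 21500, 3),
            c("chr1", 1500, "chr1", 61500, 9),
            c("chr1", 21500, "chr1", 61500, 6),
            c("chr1", 1600, "chr1", 21600, 1),
            c("chr1", 1500, "chr2", 1500, 4),
            c("chr2", 1500, "chr1", 61500, 2))
  res <- hic_edges(toy, annot, k_intra = 2, k_inter = 100,
                   assign_window = 2000)
  # brute force: per-pair max scores are g1-g2: 3, g1-g3: 9, g2-g3: 6
  expect_equal(edge_pair_ids(res$hic_intra), c("g1|g3", "g2|g3"))
  expect_setequal(res$hic_inter$weight, c(4, 2))

  nowhere <- mk(c("chr9", 100, "chr9", 200, 1))
  expect_warning(res <- hic_edges(nowhere, annot), "unmapped")
  expect_equal(nrow(res$hic_intra), 0L)
})
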