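#' Synthetic-data configuration
#'
#' Parameters of the block-correlated synthetic world used for
#' desk-scale validation.  Expression follows a one-latent-factor-per-
#' block model: gene g in block b takes value sqrt(within_block_r) *
#' f_b(s) + noise_sd * eps with f and eps standard normal, so the
#' expected within-block Pearson correlation is within_block_r (with
#' the default noise_sd = sqrt(1 - within_block_r), marginal variance
#' is 1) and between-block correlation is ~0.  Pathways coincide with
#' blocks, co-located blocks sit contiguously on a chromosome, and the
#' PPI/TF/contact lists are enriched for within-block pairs, so every
#' edge rule has recoverable structure.
#'
#' @param n_genes total genes, default 500.
#' @param n_samples_train,n_samples_test sample counts, defaults 300 /
#'   100.
#' @param n_blocks co-expression blocks, default 10.
#' @param within_block_r expected within-block Pearson correlation,
#'   default 0.81.
#' @param noise_sd per-gene noise standard deviation, default
#'   sqrt(1 - within_block_r).
#' @param landmark_fraction fraction of genes in the landmark panel
#'   (stratified over blocks, >= 1 per block), default 0.1.
#' @param genes_per_chromosome default 50.
#' @param block_colocation_prob probability a block's genes are placed
#'   contiguously on one chromosome, default 0.8.
#' @param edge_enrichment odds multiplier that a sampled PPI/TF/contact
#'   pair falls within a block, default 8.
#' @param seed integer seed.
#' @return `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 500, n_samples_train = 300,
                             n_samples_test = 100, n_blocks = 10,
                             within_block_r = 0.81,
                             noise_sd = sqrt(1 - within_block_r),
                             landmark_fraction = 0.1,
                             genes_per_chromosome = 50,
                             block_colocation_prob = 0.8,
                             edge_enrichment = 8, seed = 1) {
  if (n_blocks > n_genes) gex_abort("n_blocks must be <= n_genes")
  if (!(within_block_r > 0 && within_block_r < 1)) {
    gex_abort("within_block_r must be in (0, 1)")
  }
  if (!(noise_sd > 0)) gex_abort("noise_sd must be > 0")
  if (!(landmark_fraction > 0 && landmark_fraction <= 1)) {
    gex_abort("landmark_fraction must be in (0, 1]")
  }
  if (!(block_colocation_prob >= 0 && block_colocation_prob <= 1)) {
    gex_abort("block_colocation_prob must be in [0, 1]")
  }
  if (edge_enrichment < 1) gex_abort("edge_enrichment must be >= 1")
  n_landmarks <- max(n_blocks, round(landmark_fraction * n_genes))
  if (n_landmarks > n_genes) {
    gex_abort("infeasible config: fewer genes than required landmarks")
  }
  structure(as.list(environment()), class = "synthetic_config")
}

sample_block_factor_expr <- function(samples, block_of, lambda, noise_sd,
                                     genes, prefix) {
  S <- samples
  G <- length(block_of)
  Fb <- matrix(stats::rnorm(S * max(block_of)), S, max(block_of))
  E <- matrix(stats::rnorm(S * G), S, G)
  vals <- lambda * Fb[, block_of, drop = FALSE] + noise_sd * E
  expression_matrix(vals, sample_ids = sprintf("%s%03d", prefix, seq_len(S)),
                    gene_ids = genes)
}

# sample `n_pairs` gene pairs with within-block odds multiplied by
# `enrichment`; returns canonical unique pairs with a within-block flag
sample_enriched_pairs <- function(block_of, genes, n_pairs, enrichment) {
  base <- sum(vapply(table(block_of), function(k) choose(k, 2), 1.0)) /
    choose(length(genes), 2)
  p_within <- enrichment * base / (enrichment * base + (1 - base))
  blocks <- split(seq_along(genes), block_of)
  blocks <- blocks[lengths(blocks) >= 2]
  if (!length(blocks)) p_within <- 0
  out <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    if (stats::runif(1) < p_within) {
      b <- blocks[[sample.int(length(blocks), 1)]]
      pr <- sample(b, 2)
      out[[k]] <- c(pr, 1L)
    } else {
      pr <- sample.int(length(genes), 2)
      out[[k]] <- c(pr, as.integer(block_of[pr[1]] == block_of[pr[2]]))
    }
  }
  m <- do.call(rbind, out)
  cp <- canonicalize_pairs(genes[m[, 1]], genes[m[, 2]])
  df <- data.frame(gene_a = cp$gene_a, gene_b = cp$gene_b,
                   within = m[, 3] == 1L, stringsAsFactors = FALSE)
  df[!duplicated(paste(df$gene_a, df$gene_b)), , drop = FALSE]
}

#' Generate a self-consistent synthetic bundle
#'
#' Produces expression (train/test), gene annotations, pathways,
#' PPI and TF pair lists, Hi-C contacts, a stratified landmark panel
#' and the true block assignment, all mutually consistent and
#' deterministic per seed.
#'
#' @param config a [synthetic_config()].
#' @return object of class `synthetic_bundle`: list with `expr_train`,
#'   `expr_test`, `annot`, `pathways`, `ppi`, `tf`, `contacts`,
#'   `landmarks`, `truth` (named block vector) and `config`.
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  cf <- config
  with_seed(cf$seed, {
    G <- cf$n_genes
    genes <- sprintf("g%04d", seq_len(G))
    block_of <- sort(rep_len(seq_len(cf$n_blocks), G))
    lambda <- sqrt(cf$within_block_r)

    expr_train <- sample_block_factor_expr(cf$n_samples_train, block_of,
                                           lambda, cf$noise_sd, genes, "tr")
    expr_test <- sample_block_factor_expr(cf$n_samples_test, block_of,
                                          lambda, cf$noise_sd, genes, "te")

    # genomic placement: co-located blocks keep their genes contiguous,
    # the rest are shuffled among themselves; ~10 kb gene spacing
    blocks <- split(seq_len(G), block_of)
    coloc <- stats::runif(cf$n_blocks) < cf$block_colocation_prob
    scattered <- unlist(blocks[!coloc], use.names = FALSE)
    order_slots <- c(unlist(blocks[coloc], use.names = FALSE),
                     if (length(scattered) > 1) sample(scattered)
                     else scattered)
    slot_of <- integer(G)
    slot_of[order_slots] <- seq_len(G)
    chrom_of <- paste0("chr", (slot_of - 1) %/% cf$genes_per_chromosome + 1)
    within_chrom <- (slot_of - 1) %% cf$genes_per_chromosome
    start <- within_chrom * 10000L + 1L
    annot <- data.frame(gene_id = genes, chromosome = chrom_of,
                        start = start, end = start + 999L,
                        strand = "+", stringsAsFactors = FALSE)
    class(annot) <- c("gene_annotation", "data.frame")

    pathways <- lapply(blocks, function(ix) genes[ix])
    names(pathways) <- sprintf("P%02d", seq_len(cf$n_blocks))
    class(pathways) <- c("pathway_collection", "list")

    # landmarks: stratified across blocks, >= 1 each
    quota <- rep(cf$n_landmarks %/% cf$n_blocks, cf$n_blocks)
    extra <- cf$n_landmarks %% cf$n_blocks
    if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
    landmarks <- sort(unlist(mapply(function(ix, q) {
      genes[sample(ix, min(q, length(ix)))]
    }, blocks, quota, SIMPLIFY = FALSE), use.names = FALSE))

    # scored PPI list, score higher within blocks
    ppi_pairs <- sample_enriched_pairs(block_of, genes, 4L * G,
                                       cf$edge_enrichment)
    ppi <- data.frame(
      gene_a = ppi_pairs$gene_a, gene_b = ppi_pairs$gene_b,
      score = pmin(0.999, pmax(0.15, ifelse(
        ppi_pairs$within,
        stats::rnorm(nrow(ppi_pairs), 0.85, 0.05),
        stats::rnorm(nrow(ppi_pairs), 0.45, 0.10)))),
      stringsAsFactors = FALSE)
    attr(ppi, "directed") <- FALSE
    class(ppi) <- c("scored_pair_list", "data.frame")

    # regulon list: one TF per block targets its block mates (grades
    # A/B), plus cross-block noise pairs graded C
    tf_rows <- do.call(rbind, lapply(seq_len(cf$n_blocks), function(b) {
      ix <- blocks[[b]]
      tf <- genes[ix[1]]
      targets <- genes[ix[-1]]
      if (!length(targets)) return(NULL)
      data.frame(gene_a = tf, gene_b = targets,
                 score = pmin(0.999, stats::rnorm(length(targets), 0.9, 0.03)),
                 grade = sample(c("A", "B"), length(targets), replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    noise_n <- cf$n_blocks
    cross <- sample_enriched_pairs(block_of, genes, noise_n, 1)
    tf_rows <- rbind(tf_rows, data.frame(
      gene_a = cross$gene_a, gene_b = cross$gene_b,
      score = pmax(0.05, stats::rnorm(nrow(cross), 0.3, 0.05)),
      grade = "C", stringsAsFactors = FALSE))
    attr(tf_rows, "directed") <- TRUE
    class(tf_rows) <- c("scored_pair_list", "data.frame")

    # Hi-C contacts at gene midpoints +/- <= 5 kb jitter: intra within
    # co-located blocks (strong), inter across chromosomes (weak)
    mids <- (annot$start + annot$end) / 2
    intra <- do.call(rbind, lapply(which(coloc), function(b) {
      ix <- blocks[[b]]
      if (length(ix) < 2) return(NULL)
      k <- min(3L * length(ix), choose(length(ix), 2))
      pr <- unrank_pairs(sample.int(choose(length(ix), 2), k), length(ix))
      i <- ix[pr[, 1]]
      j <- ix[pr[, 2]]
      data.frame(chrom_a = annot$chromosome[i],
                 pos_a = pmax(1, round(mids[i] + stats::runif(k, -5000, 5000))),
                 chrom_b = annot$chromosome[j],
                 pos_b = pmax(1, round(mids[j] + stats::runif(k, -5000, 5000))),
                 score = pmax(1, stats::rnorm(k, 15, 3)),
                 stringsAsFactors = FALSE)
    }))
    n_inter <- max(4L, G %/% 2L)
    ij <- replicate(n_inter, sample.int(G, 2))
    keep <- annot$chromosome[ij[1, ]] != annot$chromosome[ij[2, ]]
    ij <- ij[, keep, drop = FALSE]
    inter <- if (ncol(ij)) data.frame(
      chrom_a = annot$chromosome[ij[1, ]],
      pos_a = pmax(1, round(mids[ij[1, ]] +
                              stats::runif(ncol(ij), -5000, 5000))),
      chrom_b = annot$chromosome[ij[2, ]],
      pos_b = pmax(1, round(mids[ij[2, ]] +
                              stats::runif(ncol(ij), -5000, 5000))),
      score = pmax(0.1, stats::rnorm(ncol(ij), 3, 1)),
      stringsAsFactors = FALSE) else NULL
    contacts <- rbind(intra, inter)
    if (is.null(contacts)) {
      contacts <- data.frame(chrom_a = character(), pos_a = numeric(),
                             chrom_b = character(), pos_b = numeric(),
                             score = numeric(), stringsAsFactors = FALSE)
    }
    rownames(contacts) <- NULL
    class(contacts) <- c("contact_list", "data.frame")

    truth <- stats::setNames(block_of, genes)
    structure(list(expr_train = expr_train, expr_test = expr_test,
                   annot = annot, pathways = pathways, ppi = ppi,
                   tf = tf_rows, contacts = contacts,
                   landmarks = landmarks, truth = truth, config = cf),
              class = "synthetic_bundle")
  })
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_bundle: %d genes in %d blocks, ",
                     "%d/%d train/test samples, %d landmarks>\n"),
              x$config$n_genes, x$config$n_blocks,
              x$config$n_samples_train, x$config$n_samples_test,
              length(x$landmarks)))
  invisible(x)
}

#' Ground-truth gene graph of a synthetic bundle
#'
#' Edges connect every within-block gene pair; used as the oracle graph
#' in recovery benchmarks.
#'
#' @param bundle `synthetic_bundle`.
#' @return `gene_graph` over all bundle genes.
#' @export
truth_graph <- function(bundle) {
  blocks <- split(names(bundle$truth), bundle$truth)
  parts <- lapply(blocks, function(g) {
    if (length(g) < 2) return(NULL)
    pr <- unrank_pairs(seq_len(choose(length(g), 2)), length(g))
    data.frame(gene_a = g[pr[, 1]], gene_b = g[pr[, 2]],
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, parts)
  es <- edge_set(all$gene_a, all$gene_b, type = "truth")
  merge_graph(names(bundle$truth), list(es))
}

#' Write a synthetic bundle to disk in the standard formats
#'
#' Emits `expr_train.tsv`, `expr_test.tsv`, `genes.gtf`,
#' `pathways.gmt`, `ppi.tsv`, `tf.tsv`, `hic.tsv`, `landmarks.txt` and
#' `truth.json`, all readable by the package's own readers.
#'
#' @param bundle `synthetic_bundle`.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_expression(bundle$expr_train, p("expr_train.tsv"))
  write_expression(bundle$expr_test, p("expr_test.tsv"))
  gtf <- sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
                 bundle$annot$chromosome, bundle$annot$start,
                 bundle$annot$end,
                 ifelse(bundle$annot$strand == "unknown", ".",
                        bundle$annot$strand),
                 bundle$annot$gene_id)
  writeLines(gtf, p("genes.gtf"))
  gmt <- vapply(seq_along(bundle$pathways), function(i) {
    paste(c(names(bundle$pathways)[i], "synthetic_block",
            bundle$pathways[[i]]), collapse = "\t")
  }, character(1))
  writeLines(gmt, p("pathways.gmt"))
  write.table(as.data.frame(bundle$ppi), p("ppi.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(bundle$tf), p("tf.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(bundle$contacts), p("hic.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_landmarks(bundle$landmarks, p("landmarks.txt"))
  jsonlite::write_json(as.list(bundle$truth), p("truth.json"),
                       auto_unbox = TRUE)
  files <- c(expr_train = p("expr_train.tsv"), expr_test = p("expr_test.tsv"),
             gtf = p("genes.gtf"), gmt = p("pathways.gmt"),
             ppi = p("ppi.tsv"), tf = p("tf.tsv"), hic = p("hic.tsv"),
             landmarks = p("landmarks.txt"), truth = p("truth.json"))
  invisible(files)
}
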