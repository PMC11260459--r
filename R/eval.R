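#' Transformed mean squared error
#'
#' tMSE = 2 - exp(MSE), with the MSE pooled over every (gene, sample)
#' entry of the predicted matrix.  Bounded above by 1 (perfect
#' prediction), strictly decreasing in MSE, and negative once
#' MSE > ln 2; higher is better.
#'
#' @param actual,predicted matrices of identical shape.
#' @return scalar tMSE.
#' @export
tmse <- function(actual, predicted) {
  if (!identical(dim(actual), dim(predicted))) {
    gex_abort("shape mismatch between actual and predicted")
  }
  2 - exp(mean((actual - predicted)^2))
}

#' Per-gene Pearson correlation between actual and predicted expression
#'
#' One correlation per gene (column), computed across samples.  Genes
#' whose actual or predicted vector has zero variance have undefined
#' correlation; they are dropped from the result and counted in the
#' `n_excluded` attribute rather than imputed.
#'
#' @param actual,predicted samples x genes matrices with matching gene
#'   columns.
#' @return named numeric vector of correlations (attribute `n_excluded`).
#' @export
per_gene_correlation <- function(actual, predicted) {
  if (nrow(actual) < 3) gex_abort("need >= 3 samples")
  if (!identical(dim(actual), dim(predicted))) {
    gex_abort("shape mismatch between actual and predicted")
  }
  va <- apply(actual, 2, stats::sd)
  vp <- apply(predicted, 2, stats::sd)
  ok <- va > 0 & vp > 0
  rho <- rep(NA_real_, ncol(actual))
  if (any(ok)) {
    rho[ok] <- vapply(which(ok), function(j) {
      stats::cor(actual[, j], predicted[, j])
    }, numeric(1))
  }
  names(rho) <- colnames(actual)
  out <- rho[ok]
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Per-gene background recall
#'
#' R_i = |Z < rho_i| / |Z|: the fraction of the background correlation
#' set Z strictly below the gene's actual-vs-predicted correlation.
#'
#' @param rho_i per-gene correlation (scalar or vector).
#' @param Z background correlation values.
#' @return recall in \[0, 1\] (vectorized over `rho_i`).
#' @export
gene_recall <- function(rho_i, Z) {
  if (!length(Z)) gex_abort("empty background set")
  vapply(rho_i, function(r) mean(Z < r), numeric(1))
}

#' Model recall
#'
#' Fraction of per-gene recalls strictly greater than the threshold; the
#' default 0.66 is the 95th percentile of the L1000 background set.
#'
#' @param R vector of per-gene recalls R_i.
#' @param threshold default 0.66.
#' @return recall fraction in \[0, 1\].
#' @export
model_recall <- function(R, threshold = 0.66) {
  if (!length(R)) gex_abort("empty recall vector")
  mean(R > threshold)
}

#' Permutation-null background correlation set
#'
#' Draws the background Z empirically: for each permutation the sample
#' order of the actual matrix is shuffled and per-gene correlations
#' between predicted and permuted-actual vectors are pooled across
#' genes, giving n_perm * n_genes null correlations.  The fitted mean
#' and variance are attached as attributes.
#'
#' @param actual,predicted samples x genes matrices.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return numeric vector Z with attributes `mu`, `sigma`.
#' @export
permutation_null <- function(actual, predicted, n_perm = 10, seed = 1) {
  if (!is_count(n_perm)) gex_abort("n_perm must be >= 1")
  if (nrow(actual) < 3) gex_abort("need >= 3 samples")
  va <- apply(actual, 2, stats::sd)
  vp <- apply(predicted, 2, stats::sd)
  ok <- which(va > 0 & vp > 0)
  Z <- with_seed(seed, {
    unlist(lapply(seq_len(n_perm), function(p) {
      prm <- sample.int(nrow(actual))
      vapply(ok, function(j) {
        stats::cor(actual[prm, j], predicted[, j])
      }, numeric(1))
    }), use.names = FALSE)
  })
  attr(Z, "mu") <- mean(Z)
  attr(Z, "sigma") <- stats::sd(Z)
  Z
}

#' Full evaluation report
#'
#' Computes the three headline metrics -- per-gene correlations rho_i,
#' per-gene recalls R_i with the model recall R_j, and the tMSE -- for a
#' prediction against held-out expression.
#'
#' @param actual,predicted samples x genes matrices over the inferred
#'   genes.
#' @param background background set Z (numeric vector), or `NULL` to
#'   draw a permutation null with `n_perm` permutations, or a list
#'   `list(mu =, sigma =, n =)` for a parametric normal background.
#' @param threshold model-recall threshold, default 0.66.
#' @param n_perm permutations for the default background.
#' @param seed seed for background generation.
#' @return object of class `eval_report`: list with `rho` (per-gene),
#'   `recall_per_gene`, `model_recall`, `tmse`, `mean_rho`,
#'   `n_evaluated`, `n_excluded`, `threshold`.
#' @export
evaluate_predictions <- function(actual, predicted, background = NULL,
                                 threshold = 0.66, n_perm = 20, seed = 1) {
  shared <- intersect(colnames(actual), colnames(predicted))
  if (!length(shared)) gex_abort("no shared genes between actual and predicted")
  actual <- actual[, shared, drop = FALSE]
  predicted <- predicted[rownames(actual), shared, drop = FALSE]
  rho <- per_gene_correlation(actual, predicted)
  if (!length(rho)) {
    # every gene excluded (e.g. constant predictions): report the
    # degenerate case rather than failing
    return(structure(list(rho = rho, recall_per_gene = numeric(0),
                          model_recall = NA_real_,
                          tmse = tmse(actual, predicted),
                          mean_rho = NA_real_, n_evaluated = 0L,
                          n_excluded = attr(rho, "n_excluded"),
                          threshold = threshold),
                     class = "eval_report"))
  }
  Z <- if (is.null(background)) {
    permutation_null(actual, predicted, n_perm = n_perm, seed = seed)
  } else if (is.list(background)) {
    with_seed(seed, stats::rnorm(background$n %||% 1000,
                                 background$mu, background$sigma))
  } else {
    as.numeric(background)
  }
  R <- gene_recall(rho, Z)
  structure(list(rho = rho, recall_per_gene = R,
                 model_recall = model_recall(R, threshold),
                 tmse = tmse(actual, predicted),
                 mean_rho = mean(rho),
                 n_evaluated = length(rho),
                 n_excluded = attr(rho, "n_excluded"),
                 threshold = threshold),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report: %d genes (%d excluded)>\n",
                     "  mean rho     %.4f\n",
                     "  model recall %.4f (threshold %.2f)\n",
                     "  tMSE         %.4f\n"),
              x$n_evaluated, x$n_excluded, x$mean_rho, x$model_recall,
              x$threshold, x$tmse))
  invisible(x)
}

#' Cross-dataset generalizability of pairwise gene correlations
#'
#' Computes pairwise Pearson correlations between genes within each
#' dataset, then over the shared gene pairs reports (i) the correlation
#' of correlations, (ii) the fraction of pairs preserved (r >
#' `preserve_r` in both datasets), and (iii) the fraction with
#' |r_a - r_b| < `delta_r`.
#'
#' @param expr_a,expr_b samples x genes expression matrices sharing
#'   gene IDs.
#' @param preserve_r preserved-pair threshold, default 0.6.
#' @param delta_r correlation-difference threshold, default 0.2.
#' @return list with `correlation_of_correlations`,
#'   `preserved_fraction`, `delta_fraction`, `n_genes`, `n_pairs`.
#' @export
correlation_generalizability <- function(expr_a, expr_b, preserve_r = 0.6,
                                         delta_r = 0.2) {
  shared <- intersect(colnames(expr_a), colnames(expr_b))
  va <- apply(expr_a[, shared, drop = FALSE], 2, stats::sd)
  vb <- apply(expr_b[, shared, drop = FALSE], 2, stats::sd)
  shared <- shared[va > 0 & vb > 0]
  if (length(shared) < 2) {
    gex_abort("need >= 2 shared genes with nonzero variance in both datasets")
  }
  ra <- stats::cor(expr_a[, shared, drop = FALSE])
  rb <- stats::cor(expr_b[, shared, drop = FALSE])
  ut <- upper.tri(ra)
  va <- ra[ut]
  vb <- rb[ut]
  list(correlation_of_correlations = stats::cor(va, vb),
       preserved_fraction = mean(va > preserve_r & vb > preserve_r),
       delta_fraction = mean(abs(va - vb) < delta_r),
       n_genes = length(shared), n_pairs = sum(ut))
}

#' Tissue-specific genes
#'
#' A gene is specific to tissue t iff its mean expression in t is at
#' least `fold` times its mean in every other tissue (inclusive
#' boundary).  Zero means in a comparison tissue count as satisfied
#' whenever the candidate tissue's mean is positive.  Intended for
#' non-negative expression scales.
#'
#' @param expr samples x genes expression matrix.
#' @param tissues per-sample tissue labels; defaults to
#'   [sample_labels()] of `expr`.
#' @param fold fold-change requirement, default 3.
#' @return named list (one element per tissue) of specific gene IDs.
#' @export
tissue_specific_genes <- function(expr, tissues = sample_labels(expr),
                                  fold = 3) {
  if (is.null(tissues)) gex_abort("no tissue labels supplied")
  tissues <- as.character(tissues)
  levs <- unique(tissues)
  if (length(levs) < 2) gex_abort("need >= 2 tissues")
  means <- do.call(rbind, lapply(levs, function(t) {
    colMeans(expr[tissues == t, , drop = FALSE])
  }))
  rownames(means) <- levs
  out <- lapply(levs, function(t) {
    others <- means[setdiff(levs, t), , drop = FALSE]
    ok <- vapply(seq_len(ncol(means)), function(j) {
      mt <- means[t, j]
      all(ifelse(others[, j] == 0, mt > 0, mt >= fold * others[, j]))
    }, logical(1))
    colnames(expr)[ok]
  })
  names(out) <- levs
  out
}

#' Fold-change gene selection between two datasets
#'
#' Returns the genes whose mean expression differs by at least `fold`
#' between the two datasets, in either direction (so the selection is
#' symmetric in its arguments).
#'
#' @param expr_a,expr_b samples x genes expression matrices sharing
#'   gene IDs.
#' @param fold fold-change requirement, default 3.
#' @return character vector of gene IDs.
#' @export
fold_change_genes <- function(expr_a, expr_b, fold = 3) {
  shared <- intersect(colnames(expr_a), colnames(expr_b))
  ma <- colMeans(expr_a[, shared, drop = FALSE])
  mb <- colMeans(expr_b[, shared, drop = FALSE])
  shared[ma >= fold * mb | mb >= fold * ma]
}
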