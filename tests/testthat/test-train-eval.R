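test_that("masking arithmetic matches the landmark-panel convention", {
  panel <- sprintf("L%03d", 1:955)
  plan <- make_mask(panel, 0.7, seed = 5)
  expect_length(plan$masked_ids, 669)
  expect_length(plan$observed_ids, 286)
  expect_setequal(c(plan$masked_ids, plan$observed_ids), panel)
  expect_length(intersect(plan$masked_ids, plan$observed_ids), 0)

  none <- make_mask(panel, 0, seed = 1)
  expect_length(none$masked_ids, 0)

  expect_identical(make_mask(panel, 0.7, seed = 5)$masked_ids,
                   plan$masked_ids)
  expect_false(identical(make_mask(panel, 0.7, seed = 6)$masked_ids,
                         plan$masked_ids))
  expect_error(make_mask(panel, 1), "\\[0, 1\\)")
})

test_that("least squares is exact on noiseless linear data", {
  set.seed(2)
  X <- matrix(rnorm(200), 40, 5)
  B <- matrix(rnorm(5 * 7), 5, 7)
  Y <- X %*% B + 1
  expr <- expression_matrix(cbind(X, Y),
                            sample_ids = sprintf("s%02d", 1:40),
                            gene_ids = c(sprintf("x%d", 1:5),
                                         sprintf("y%d", 1:7)))
  m <- train_model(model_config("lr"), expr, sprintf("x%d", 1:5))
  expect_lt(m$history$train_loss, 1e-10)
  pred <- predict(m, expr[, 1:5])
  expect_lt(max(abs(pred - Y)), 1e-6)
})

test_that("neural training reduces the loss and is deterministic per seed", {
  expr <- tiny_expr(samples = 60, genes = 20, seed = 3)
  lmk <- colnames(expr)[1:8]
  fit <- function() {
    train_model(model_config("mlp", hidden_dim = 16, seed = 4), expr, lmk,
                opts = list(epochs = 15, seed = 9))
  }
  m1 <- fit()
  expect_lt(tail(m1$history$train_loss, 1), m1$history$train_loss[1])
  m2 <- fit()
  expect_identical(m1$params, m2$params)
})

test_that("tMSE follows its closed forms", {
  A <- matrix(rnorm(50), 10, 5)
  expect_equal(tmse(A, A), 1)
  expect_equal(tmse(A, A + sqrt(log(2))), 0)
  expect_equal(tmse(A, A + 1), 2 - exp(1))     # negative values allowed
  expect_error(tmse(A, A[, 1:2]), "shape mismatch")
  # strictly decreasing in MSE, bounded above by 1
  expect_true(all(diff(vapply(c(0, 0.1, 0.5, 2),
                              function(s) tmse(A, A + s), 1)) < 0))
})

test_that("per-gene correlation matches the brute-force loop", {
  set.seed(14)
  A <- matrix(rnorm(600), 30, 20,
              dimnames = list(NULL, sprintf("g%02d", 1:20)))
  P <- A + matrix(rnorm(600, sd = 0.8), 30, 20)
  colnames(P) <- colnames(A)
  rho <- per_gene_correlation(A, P)
  brute <- vapply(1:20, function(j) cor(A[, j], P[, j]), 1)
  expect_equal(unname(rho), brute, ignore_attr = TRUE)
  expect_equal(unname(per_gene_correlation(A, A)), rep(1, 20),
               ignore_attr = TRUE)
  expect_equal(unname(per_gene_correlation(A, -A)), rep(-1, 20),
               ignore_attr = TRUE)
  # zero-variance genes are excluded and counted, not imputed
  P2 <- P
  P2[, 3] <- 5
  rho2 <- per_gene_correlation(A, P2)
  expect_length(rho2, 19)
  expect_equal(attr(rho2, "n_excluded"), 1L)
  expect_error(per_gene_correlation(A[1:2, ], P[1:2, ]), "3 samples")
})

test_that("recall definitions use strict inequalities", {
  Z <- c(-0.5, 0, 0.5, 1)
  expect_equal(gene_recall(0.6, Z), 0.75)
  expect_equal(gene_recall(-1, Z), 0)
  expect_equal(gene_recall(2, Z), 1)
  expect_equal(gene_recall(0.5, Z), 0.5)        # strict <
  expect_error(gene_recall(0.5, numeric(0)), "empty background")

  expect_equal(model_recall(c(0.7, 0.5, 0.9), 0.66), 2 / 3)
  expect_equal(model_recall(rep(0.66, 5), 0.66), 0)   # strict >
  expect_equal(model_recall(rep(1, 4), 0.66), 1)
  expect_error(model_recall(numeric(0)), "empty recall")

  # monotone non-decreasing when any rho_i increases
  set.seed(10)
  rho <- runif(30, -1, 1)
  Zbg <- rnorm(200, 0, 0.3)
  base <- model_recall(gene_recall(rho, Zbg))
  for (i in c(1, 15, 30)) {
    up <- rho
    up[i] <- up[i] + 0.5
    expect_gte(model_recall(gene_recall(up, Zbg)), base)
  }
})

test_that("the permutation null is centered, sized and reproducible", {
  set.seed(8)
  A <- matrix(rnorm(25 * 20), 25, 20,
              dimnames = list(NULL, sprintf("g%02d", 1:20)))
  P <- matrix(rnorm(25 * 20), 25, 20, dimnames = dimnames(A))
  Z <- permutation_null(A, P, n_perm = 10, seed = 2)
  expect_length(Z, 200)                        # n_perm * genes
  se <- sd(Z) / sqrt(length(Z))
  expect_lt(abs(mean(Z)), 3 * se + 3 / sqrt(25))
  expect_identical(Z, permutation_null(A, P, n_perm = 10, seed = 2))
  expect_error(permutation_null(A, P, n_perm = 0), "n_perm")
})

test_that("evaluation is invariant to gene and sample ordering", {
  set.seed(44)
  A <- matrix(rnorm(300), 20, 15,
              dimnames = list(sprintf("s%02d", 1:20), sprintf("g%02d", 1:15)))
  P <- A + matrix(rnorm(300, sd = 0.5), 20, 15)
  dimnames(P) <- dimnames(A)
  Zbg <- rnorm(300, 0, 0.2)
  r1 <- evaluate_predictions(A, P, background = Zbg)
  r2 <- evaluate_predictions(A[rev(1:20), rev(1:15)], P, background = Zbg)
  expect_equal(r1$tmse, r2$tmse)
  expect_equal(r1$model_recall, r2$model_recall)
  expect_equal(sort(r1$rho), sort(r2$rho))
})

test_that("cross-dataset correlation generalizability summaries are exact on identities", {
  expr <- tiny_expr(samples = 30, genes = 10, seed = 17)
  same <- correlation_generalizability(expr, expr)
  expect_equal(same$correlation_of_correlations, 1)
  expect_equal(same$delta_fraction, 1)
  expect_equal(same$n_pairs, choose(10, 2))

  # independent data: correlation of correlations near 0
  a <- tiny_expr(samples = 200, genes = 50, seed = 18)
  b <- tiny_expr(samples = 200, genes = 50, seed = 19)
  ind <- correlation_generalizability(a, b)
  expect_lt(abs(ind$correlation_of_correlations), 0.15)

  # one strongly preserved pair, hand-computable fraction
  set.seed(20)
  base <- rnorm(50)
  mk <- function(seed) {
    set.seed(seed)
    expression_matrix(cbind(p = base + rnorm(50, sd = 0.1),
                            q = base + rnorm(50, sd = 0.1),
                            r = rnorm(50)),
                      sample_ids = sprintf("s%02d", 1:50),
                      gene_ids = c("p", "q", "r"))
  }
  toy <- correlation_generalizability(mk(1), mk(2), preserve_r = 0.6)
  expect_equal(toy$preserved_fraction, 1 / 3)   # only the p-q pair

  expect_error(correlation_generalizability(mk(1)[, 1, drop = FALSE],
                                            mk(2)[, 2, drop = FALSE]),
               "shared genes")
})

test_that("tissue-specific and fold-change rules use inclusive boundaries", {
  mk_expr <- function(means) {
    vals <- do.call(rbind, lapply(means, function(m) {
      matrix(rep(m, each = 4), 4, length(m))
    }))
    expression_matrix(vals,
                      sample_ids = sprintf("s%02d", seq_len(nrow(vals))),
                      gene_ids = sprintf("g%d", seq_along(means[[1]])),
                      sample_labels = stats::setNames(
                        rep(names(means), each = 4),
                        sprintf("s%02d", seq_len(nrow(vals)))))
  }
  expr <- mk_expr(list(t1 = c(9, 8.9, 6), t2 = c(3, 3, 0), t3 = c(1, 1, 0)))
  ts <- tissue_specific_genes(expr, fold = 3)
  expect_setequal(ts$t1, c("g1", "g3"))        # 9 >= 3*3 inclusive; zero rule
  expect_false("g2" %in% ts$t1)                # 8.9 < 9 fails
  one_tissue <- mk_expr(list(t1 = c(1, 2, 3)))
  expect_error(tissue_specific_genes(one_tissue), ">= 2 tissues")

  ea <- mk_expr(list(t1 = c(6, 5, 2)))
  eb <- mk_expr(list(t1 = c(2, 2, 6)))
  expect_setequal(fold_change_genes(ea, eb, fold = 3), c("g1", "g3"))
  expect_setequal(fold_change_genes(eb, ea, fold = 3),
                  fold_change_genes(ea, eb, fold = 3))  # symmetric
})
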