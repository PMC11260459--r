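test_that("the graph-convolution layer matches hand computations", {
  # isolated node: dhat = 1, self term only -> identity
  g1 <- merge_graph(c("a", "b"), list())
  X <- matrix(c(1, 3), 2, 1)
  expect_equal(gcn_layer_forward(X, g1, matrix(1, 1, 1)), X,
               ignore_attr = TRUE)
  # one unit-weight edge, scalar features (1, 3): both outputs 2
  g2 <- merge_graph(c("a", "b"), list(edge_set("a", "b", type = "x")))
  out <- gcn_layer_forward(X, g2, matrix(1, 1, 1))
  expect_equal(as.vector(out), c(2, 2))
  expect_error(gcn_layer_forward(matrix(1, 2, 3), g2, matrix(1, 1, 1)),
               "dimension mismatch")
})

test_that("the sparse propagation equals the dense closed form on random graphs", {
  for (rep in 1:10) {
    set.seed(rep)
    n <- sample(4:20, 1)
    g <- random_gene_graph(n, sample.int(choose(n, 2), 1), seed = rep)
    X <- matrix(rnorm(n * 3), n, 3)
    theta <- matrix(rnorm(3 * 2), 3, 2)
    expect_lt(max(abs(gcn_layer_forward(X, g, theta) -
                        dense_gcn_oracle(g, X, theta))), 1e-6)
  }
})

test_that("the GCN layer is linear and node-relabelling equivariant", {
  g <- random_gene_graph(12, 20, seed = 2)
  theta <- matrix(rnorm(6), 3, 2)
  X <- matrix(rnorm(36), 12, 3)
  Z <- matrix(rnorm(36), 12, 3)
  lhs <- gcn_layer_forward(2 * X - 3 * Z, g, theta)
  rhs <- 2 * gcn_layer_forward(X, g, theta) -
    3 * gcn_layer_forward(Z, g, theta)
  expect_lt(max(abs(lhs - rhs)), 1e-9)

  set.seed(9)
  perm <- sample(12)
  ids <- g$nodes
  es <- g$edge_sets[[1]]
  g_perm <- merge_graph(ids[perm], list(es), weight_reducer = "max")
  out <- gcn_layer_forward(X, g, theta)
  out_perm <- gcn_layer_forward(X[match(ids[perm], ids), , drop = FALSE],
                                g_perm, theta)
  expect_lt(max(abs(out_perm - out[match(ids[perm], ids), ])), 1e-9)
})

test_that("PNA aggregation matches brute-force evaluation", {
  v <- pna_aggregate(0, rbind(1, 3), degree = 2, delta = 1,
                     aggregators = c("mean", "max", "min", "std"),
                     scalers = "identity")
  expect_equal(unname(v), c(2, 3, 1, 1))        # population std of {1,3} is 1

  # degenerate-input rule: no neighbors -> zero vector
  z <- pna_aggregate(c(1, 2), matrix(numeric(0), 0, 2), degree = 0,
                     delta = 0.7)
  expect_true(all(z == 0))
  expect_length(z, 2 * 4 * 4)

  # amplification scaler with delta from a stated 4-node path graph
  # (degrees 1,2,2,1 -> dhat = 2,3,3,2; delta = mean(log(dhat+1)))
  delta <- mean(log(c(2, 3, 3, 2) + 1))
  set.seed(4)
  M <- matrix(rnorm(10), 5, 2)
  got <- pna_aggregate(c(0, 0), M, degree = 5, delta = delta,
                       aggregators = c("mean", "std"),
                       scalers = "amplification")
  sc <- log(5 + 1) / delta
  want <- c(sc * colMeans(M),
            sc * sqrt(colMeans(M^2) - colMeans(M)^2))
  expect_equal(unname(got), want)

  expect_error(pna_aggregate(0, rbind(1), 1, 1, aggregators = character(0)),
               "empty aggregator")
})

test_that("PNA aggregates obey ordering identities", {
  set.seed(12)
  for (k in c(1, 2, 7)) {
    M <- matrix(rnorm(k * 3), k, 3)
    v <- pna_aggregate(numeric(3), M, degree = k, delta = 1,
                       scalers = "identity")
    mean_v <- v[1:3]; max_v <- v[4:6]; min_v <- v[7:9]; std_v <- v[10:12]
    expect_true(all(min_v <= mean_v + 1e-12 & mean_v <= max_v + 1e-12))
    expect_true(all(std_v >= 0))
    if (k == 1) {
      expect_equal(unname(mean_v), unname(max_v))
      expect_equal(unname(mean_v), unname(min_v))
      expect_true(all(std_v == 0))
    }
  }
})

test_that("the two-term auto-encoder loss is the sum of two MSEs", {
  expect_equal(ae_loss(1:3, 1:3, 4:5, 4:5), 0)
  expect_equal(ae_loss(0, 1, c(0, 0), c(1, 1)), 2)
  set.seed(6)
  Y <- rnorm(7); Yh <- rnorm(7); X <- rnorm(4); Xh <- rnorm(4)
  mse <- function(u, v) mean((u - v)^2)       # independent routine
  expect_equal(ae_loss(Y, Yh, X, Xh), mse(Y, Yh) + mse(X, Xh))
  expect_gte(ae_loss(Y, Yh, X, Xh), 0)
  expect_error(ae_loss(1:2, 1:3, 1, 1), "length mismatch")
})

test_that("model construction honors the architecture contracts", {
  lr <- build_model(model_config("lr", input_dim = 3, output_dim = 2))
  expect_equal(n_parameters(lr), 2 * (3 + 1))   # intercept per target
  expect_equal(model_config("mlp")$hidden_dim, 2048)
  expect_equal(model_config("ae")$hidden_dim, 256)
  mlp <- build_model(model_config("mlp", input_dim = 10, output_dim = 20,
                                  hidden_dim = 8))
  expect_equal(dim(mlp$params$W1), c(10L, 8L))
  expect_equal(dim(mlp$params$W2), c(8L, 20L))
  ae <- build_model(model_config("ae", input_dim = 10, output_dim = 20,
                                 hidden_dim = 4))
  expect_equal(dim(ae$params$Wd), c(4L, 10L))   # reconstruction layer
  expect_error(build_model(model_config("pna")), "requires a gene graph")
  expect_error(build_model(model_config("gcn")), "requires a gene graph")
})

test_that("predictions are finite, batch-invariant and row-stable", {
  set.seed(31)
  expr <- tiny_expr(samples = 40, genes = 12, seed = 31)
  lmk <- colnames(expr)[1:4]
  g <- random_gene_graph(12, 30, seed = 31)
  g <- merge_graph(colnames(expr), g$edge_sets)  # nodes = gene ids
  for (kind in c("lr", "mlp", "ae", "gcn", "pna")) {
    cfg <- model_config(kind, hidden_dim = if (kind == "lr") NULL else 6,
                        seed = 2)
    m <- train_model(cfg, expr, lmk, graph = g,
                     opts = list(epochs = 3, batch_size = 16))
    obs <- expr[, lmk, drop = FALSE]
    p <- predict(m, obs)
    expect_true(all(is.finite(p)))
    expect_identical(colnames(p), m$inferred_ids)
    # one batch vs sample-by-sample
    rows <- do.call(rbind, lapply(seq_len(6), function(i) {
      predict(m, obs[i, , drop = FALSE])
    }))
    expect_equal(rows, p[1:6, , drop = FALSE], tolerance = 1e-6)
    # permuting samples permutes predictions identically
    prm <- c(5, 2, 9, 1)
    expect_equal(predict(m, obs[prm, , drop = FALSE]), p[prm, ],
                 tolerance = 1e-12)
    # unknown genes are fatal and named
    bad <- obs
    colnames(bad)[1] <- "mystery"
    expect_error(predict(m, bad), "mystery")
  }
})

test_that("GNNs on an edgeless graph reduce to per-node functions", {
  expr <- tiny_expr(samples = 30, genes = 8, seed = 13)
  lmk <- colnames(expr)[1:3]
  g0 <- merge_graph(colnames(expr), list())
  m <- train_model(model_config("gcn", hidden_dim = 4, seed = 1), expr, lmk,
                   g0, opts = list(epochs = 2))
  p <- predict(m, expr[, lmk, drop = FALSE])
  # inferred nodes carry constant (0, 0) features -> constant output
  expect_true(all(apply(p, 2, function(col) max(col) - min(col)) < 1e-12))
})
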