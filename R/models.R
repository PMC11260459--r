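#' Predictor configuration
#'
#' Describes one of the five predictors: `lr` (per-gene least squares,
#' the L1000-style baseline), `mlp` (input / 2048 / output), `ae`
#' (auto-encoder with a 256-unit bottleneck, an input-sized
#' reconstruction layer and the two-term loss), `gcn` (graph
#' convolution) and `pna` (principal neighborhood aggregation).
#'
#' @param kind one of `"lr"`, `"mlp"`, `"ae"`, `"gcn"`, `"pna"`.
#' @param input_dim observed landmark count (may be `NULL` and filled at
#'   training time).
#' @param output_dim number of genes to infer (may be `NULL`).
#' @param hidden_dim hidden width; defaults: 2048 (mlp), 256 (ae
#'   bottleneck), 64 (GNN hidden/message width).
#' @param n_message_layers message-passing layers for GNNs, default 2.
#' @param aggregators PNA aggregators, subset of
#'   `c("mean", "max", "min", "std")` (std is the population standard
#'   deviation).
#' @param scalers PNA degree scalers, subset of `c("identity",
#'   "amplification", "attenuation", "linear")`: identity = 1,
#'   amplification = log(d + 1) / delta, attenuation = delta /
#'   log(d + 1), linear = d / exp(delta), with delta the mean of
#'   log(dhat + 1) over graph nodes.
#' @param node_feature_dim per-node input channels for GNNs: expression
#'   value + observed flag (+ optional static covariates), default 2.
#' @param seed integer seed controlling parameter initialization.
#' @return a `model_config` list.
#' @export
model_config <- function(kind = c("lr", "mlp", "ae", "gcn", "pna"),
                         input_dim = NULL, output_dim = NULL,
                         hidden_dim = NULL, n_message_layers = 2,
                         aggregators = c("mean", "max", "min", "std"),
                         scalers = c("identity", "amplification",
                                     "attenuation", "linear"),
                         node_feature_dim = 2, seed = 1) {
  kind <- match.arg(kind)
  if (is.null(hidden_dim)) {
    hidden_dim <- switch(kind, mlp = 2048, ae = 256, gcn = 64, pna = 64,
                         lr = NULL)
  }
  for (d in list(input_dim, output_dim, hidden_dim)) {
    if (!is.null(d) && !is_count(d)) gex_abort("dimensions must be >= 1")
  }
  if (!is_count(n_message_layers)) gex_abort("n_message_layers must be >= 1")
  if (kind == "pna") {
    aggregators <- match.arg(aggregators, several.ok = TRUE)
    scalers <- match.arg(scalers, several.ok = TRUE)
    if (!length(aggregators)) gex_abort("pna needs >= 1 aggregator")
    if (!length(scalers)) gex_abort("pna needs >= 1 scaler")
  }
  structure(list(kind = kind, input_dim = input_dim,
                 output_dim = output_dim, hidden_dim = hidden_dim,
                 n_message_layers = n_message_layers,
                 aggregators = aggregators, scalers = scalers,
                 node_feature_dim = node_feature_dim,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Build an (untrained) predictor model
#'
#' Allocates and seeds the model parameters.  GNN kinds require the gene
#' graph they will message-pass over; graph node order fixes the node
#' feature layout.
#'
#' @param config a [model_config()].
#' @param graph `gene_graph`, required iff `config$kind` is `gcn`/`pna`.
#' @return object of class `predictor_model`.
#' @export
build_model <- function(config, graph = NULL) {
  kind <- config$kind
  if (kind %in% c("gcn", "pna") && is.null(graph)) {
    gex_abort(sprintf("model kind '%s' requires a gene graph", kind))
  }
  m <- config$input_dim
  n <- config$output_dim
  h <- config$hidden_dim
  d <- config$node_feature_dim
  L <- config$n_message_layers
  params <- with_seed(config$seed, switch(
    kind,
    lr = if (!is.null(m) && !is.null(n)) {
      list(coef = matrix(0, m + 1, n))
    } else list(),
    mlp = list(W1 = glorot(m, h), b1 = numeric(h),
               W2 = glorot(h, n), b2 = numeric(n)),
    ae = list(We = glorot(m, h), be = numeric(h),
              Wd = glorot(h, m), bd = numeric(m),
              Wo = glorot(m, n), bo = numeric(n)),
    gcn = {
      p <- list()
      din <- d
      for (l in seq_len(L)) {
        p[[sprintf("W%d", l)]] <- glorot(din, h)
        p[[sprintf("b%d", l)]] <- numeric(h)
        din <- h
      }
      p$Whead <- glorot(h, 1)
      p$bhead <- 0
      p
    },
    pna = {
      nblk <- length(config$aggregators) * length(config$scalers)
      p <- list()
      din <- d
      for (l in seq_len(L)) {
        p[[sprintf("Wh%d", l)]] <- glorot(2 * din, h)
        p[[sprintf("bh%d", l)]] <- numeric(h)
        p[[sprintf("Wg%d", l)]] <- glorot(din + h * nblk, h)
        p[[sprintf("bg%d", l)]] <- numeric(h)
        din <- h
      }
      p$Whead <- glorot(h, 1)
      p$bhead <- 0
      p
    }))
  internals <- list()
  if (kind == "gcn") internals$S <- gcn_propagation_matrix(graph)
  if (kind == "pna") {
    internals$ein <- pna_edge_index(graph, config$aggregators,
                                    config$scalers)
  }
  structure(list(config = config, params = params, graph = graph,
                 internals = internals, landmark_ids = NULL,
                 inferred_ids = NULL, history = NULL, trained = FALSE),
            class = "predictor_model")
}

#' @export
print.predictor_model <- function(x, ...) {
  cat(sprintf("<predictor_model '%s'%s: %s parameters%s>\n",
              x$config$kind,
              if (x$trained) ", trained" else "",
              format(n_parameters(x), big.mark = ","),
              if (!is.null(x$graph))
                sprintf(", graph of %d nodes", length(x$graph$nodes)) else ""))
  invisible(x)
}

#' Number of learnable parameters in a model
#' @param model `predictor_model`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, 1L))
}

#' One graph-convolution layer (no nonlinearity)
#'
#' Computes X' = Dhat^(-1/2) (A + I) Dhat^(-1/2) X theta, i.e. per node
#' the weighted normalized sum over N(i) and the node itself, with
#' dhat_i = 1 + sum_j e_{j,i} and unit self-loop weight.  Activation
#' functions are applied by the model assembly, not here.
#'
#' @param features nodes x d matrix, rows aligned with graph node order.
#' @param graph `gene_graph`.
#' @param theta d x d' weight matrix.
#' @return nodes x d' matrix.
#' @export
gcn_layer_forward <- function(features, graph, theta) {
  features <- as.matrix(features)
  theta <- as.matrix(theta)
  if (nrow(features) != length(graph$nodes)) {
    gex_abort("feature rows must align with graph nodes")
  }
  if (ncol(features) != nrow(theta)) {
    gex_abort("feature/theta dimension mismatch")
  }
  S <- gcn_propagation_matrix(graph)
  as.matrix(S %*% (features %*% theta))
}

#' Principal-neighborhood aggregation of one node's messages
#'
#' For every aggregator a (mean, max, min, population std) and every
#' degree scaler s, emits s(degree) * a(messages), concatenated
#' scaler-major.  Degree-0 nodes receive the zero vector for all
#' aggregates.
#'
#' @param self_feature the node's own d-vector (carried for signature
#'   symmetry with the layer transform; not aggregated).
#' @param neighbor_features matrix (neighbors x d) or list of d-vectors
#'   of incoming messages.
#' @param degree neighbor count used by the scalers.
#' @param delta mean of log(dhat + 1) over training-graph nodes; must be
#'   positive.
#' @param aggregators,scalers see [model_config()].
#' @return named numeric vector of length d * |aggregators| * |scalers|.
#' @export
pna_aggregate <- function(self_feature, neighbor_features, degree, delta,
                          aggregators = c("mean", "max", "min", "std"),
                          scalers = c("identity", "amplification",
                                      "attenuation", "linear")) {
  if (!length(aggregators)) gex_abort("empty aggregator list")
  if (!length(scalers)) gex_abort("empty scaler list")
  if (!(is.numeric(delta) && delta > 0)) gex_abort("delta must be > 0")
  if (is.list(neighbor_features)) {
    neighbor_features <- do.call(rbind, lapply(neighbor_features, rbind))
  }
  d <- length(self_feature)
  if (is.null(neighbor_features) || !nrow(neighbor_features)) {
    M <- matrix(numeric(0), 0, d)
  } else {
    M <- as.matrix(neighbor_features)
  }
  aggs <- list(
    mean = if (nrow(M)) colMeans(M) else numeric(d),
    max = if (nrow(M)) apply(M, 2, max) else numeric(d),
    min = if (nrow(M)) apply(M, 2, min) else numeric(d),
    std = if (nrow(M)) {
      sqrt(pmax(colMeans(M^2) - colMeans(M)^2, 0))
    } else numeric(d))
  scale_of <- function(s) {
    switch(s,
           identity = 1,
           amplification = log(degree + 1) / delta,
           attenuation = if (degree > 0) delta / log(degree + 1) else 0,
           linear = degree / exp(delta),
           gex_abort(sprintf("unknown scaler '%s'", s)))
  }
  out <- numeric(0)
  for (s in scalers) {
    sc <- scale_of(s)
    for (a in aggregators) {
      if (!a %in% names(aggs)) gex_abort(sprintf("unknown aggregator '%s'", a))
      v <- if (nrow(M)) sc * aggs[[a]] else numeric(d)
      names(v) <- paste(s, a, seq_len(d), sep = ".")
      out <- c(out, v)
    }
  }
  out
}

#' Two-term auto-encoder loss
#'
#' L = mean((Y - Yhat)^2) + mean((X - Xhat)^2): the prediction MSE over
#' the n inferred genes plus the reconstruction MSE over the m landmark
#' genes, enforcing reconstruction of the predictor genes before
#' inferring the rest.
#'
#' @param Y,Y_hat actual / predicted values for the inferred genes.
#' @param X,X_hat input / reconstructed landmark values.
#' @return non-negative scalar; 0 iff both terms are exact.
#' @export
ae_loss <- function(Y, Y_hat, X, X_hat) {
  if (length(Y) != length(Y_hat) || length(X) != length(X_hat)) {
    gex_abort("length mismatch in ae_loss")
  }
  if (!length(Y) || !length(X)) gex_abort("ae_loss needs n >= 1 and m >= 1")
  mean((Y - Y_hat)^2) + mean((X - X_hat)^2)
}
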