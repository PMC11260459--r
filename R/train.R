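#' Random masking plan over a landmark panel
#'
#' Masks a uniform random subset of ceil(fraction * |landmarks|)
#' landmark genes; with the 955-gene L1000 panel and fraction 0.7 this
#' leaves 286 observed genes.  Deterministic per seed.
#'
#' @param landmarks character vector of landmark gene IDs.
#' @param fraction fraction to mask, in \[0, 1).
#' @param seed integer seed.
#' @return object of class `mask_plan`: list with `landmark_ids`,
#'   `masked_ids`, `observed_ids`, `fraction`, `seed`.
#' @export
make_mask <- function(landmarks, fraction, seed = 1) {
  landmarks <- as.character(landmarks)
  if (!length(landmarks)) gex_abort("empty landmark set")
  if (anyDuplicated(landmarks)) gex_abort("duplicate landmark IDs")
  if (!(is.numeric(fraction) && fraction >= 0 && fraction < 1)) {
    gex_abort("mask fraction must be in [0, 1): masking everything leaves no input")
  }
  n_masked <- ceiling(fraction * length(landmarks))
  masked <- if (n_masked > 0) {
    with_seed(seed, sort(sample(landmarks, n_masked)))
  } else character(0)
  structure(list(landmark_ids = landmarks, masked_ids = masked,
                 observed_ids = setdiff(landmarks, masked),
                 fraction = fraction, seed = as.integer(seed)),
            class = "mask_plan")
}

#' @export
print.mask_plan <- function(x, ...) {
  cat(sprintf("<mask_plan: %d landmarks, %d masked (%.0f%%), %d observed>\n",
              length(x$landmark_ids), length(x$masked_ids),
              100 * x$fraction, length(x$observed_ids)))
  invisible(x)
}

default_train_opts <- function() {
  list(epochs = 200, batch_size = 32, learning_rate = 1e-3,
       mask_fraction = 0, val_fraction = 0.1, patience = 20,
       seed = NULL, verbose = FALSE, covariates = NULL)
}

#' Train a predictor
#'
#' Fits one of the five predictors to map landmark-gene expression to
#' the remaining genes of `expr_train`.  LR is solved in closed form
#' (ordinary least squares with intercept, ridge-stabilized at 1e-8 for
#' rank-deficient toy inputs); the neural models are trained with Adam
#' on mini-batches of 32 samples, minimizing the MSE over inferred
#' genes (the auto-encoder adds its landmark-reconstruction term), with
#' early stopping on a held-out validation split.
#'
#' When `opts$mask_fraction > 0`, a fresh random subset of landmarks is
#' zeroed (value and, for GNNs, observed flag) in every mini-batch, so
#' the model learns to predict from partial landmark panels -- the
#' regime in which it is evaluated under test-time masking.
#'
#' @param config a [model_config()]; `input_dim`/`output_dim` are filled
#'   from the data when `NULL`.
#' @param expr_train samples x genes expression matrix.
#' @param landmarks landmark gene IDs (must be columns of `expr_train`).
#' @param graph `gene_graph` whose nodes cover all expression genes;
#'   required for GNN kinds.
#' @param opts list of training options: `epochs` (default 200),
#'   `batch_size` (32), `learning_rate` (1e-3), `mask_fraction` (0),
#'   `val_fraction` (0.1), `patience` (20), `seed` (defaults to the
#'   config seed), `verbose`, `covariates` (optional genes x k numeric
#'   matrix of static node covariates for GNNs).
#' @return trained `predictor_model`; `$history` holds per-epoch train
#'   and validation losses.
#' @export
train_model <- function(config, expr_train, landmarks, graph = NULL,
                        opts = list()) {
  o <- utils::modifyList(default_train_opts(), opts)
  if (is.null(o$seed)) o$seed <- derive_seed(config$seed, "train")
  landmarks <- as.character(landmarks)
  missing_lm <- setdiff(landmarks, colnames(expr_train))
  if (length(missing_lm)) {
    gex_abort(sprintf("landmark(s) absent from expression matrix: %s",
                      paste(utils::head(missing_lm, 5), collapse = ", ")))
  }
  inferred <- setdiff(colnames(expr_train), landmarks)
  if (!length(inferred)) gex_abort("no genes left to infer")
  if (is.null(config$input_dim)) config$input_dim <- length(landmarks)
  if (is.null(config$output_dim)) config$output_dim <- length(inferred)
  if (config$input_dim != length(landmarks) ||
      config$output_dim != length(inferred)) {
    gex_abort("config dimensions disagree with landmark/inferred gene counts")
  }
  if (config$kind %in% c("gcn", "pna")) {
    if (is.null(graph)) gex_abort("GNN training requires a gene graph")
    outside <- setdiff(colnames(expr_train), graph$nodes)
    if (length(outside)) {
      gex_abort(sprintf("graph nodes must cover all expression genes; missing: %s",
                        paste(utils::head(outside, 5), collapse = ", ")))
    }
    ncov <- if (is.null(o$covariates)) 0L else ncol(o$covariates)
    config$node_feature_dim <- 2L + ncov
  }
  model <- build_model(config, graph)
  if (config$kind %in% c("gcn", "pna")) {
    model$internals$covariates <- o$covariates
  }
  model$landmark_ids <- landmarks
  model$inferred_ids <- inferred
  X <- expr_train[, landmarks, drop = FALSE]
  Y <- expr_train[, inferred, drop = FALSE]
  model <- switch(config$kind,
                  lr = fit_lr(model, X, Y),
                  mlp = ,
                  ae = fit_dense(model, X, Y, o),
                  gcn = ,
                  pna = fit_gnn(model, X, Y, o))
  model$trained <- TRUE
  model
}

fit_lr <- function(model, X, Y, ridge = 1e-8) {
  Xi <- cbind(1, X)
  G <- crossprod(Xi) + ridge * diag(ncol(Xi))
  coef <- solve(G, crossprod(Xi, Y))
  model$params$coef <- coef
  mse <- mean((Xi %*% coef - Y)^2)
  model$history <- data.frame(epoch = 1L, train_loss = mse,
                              val_loss = NA_real_)
  model
}

# shared training-loop skeleton: batching, per-batch landmark masking,
# Adam, early stopping on validation loss
run_epochs <- function(model, X, Y, o, step_fn, eval_fn) {
  n <- nrow(X)
  m <- ncol(X)
  with_seed(o$seed, {
    n_val <- if (n >= 20) max(1, floor(o$val_fraction * n)) else 0
    idx <- sample.int(n)
    val_idx <- if (n_val > 0) idx[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(idx, val_idx)
    val_mask <- if (o$mask_fraction > 0) {
      sample.int(m, ceiling(o$mask_fraction * m))
    } else integer(0)
    state <- adam_init(model$params)
    best <- list(params = model$params, val = Inf, epoch = 0L)
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric())
    stale <- 0L
    for (ep in seq_len(o$epochs)) {
      ord <- sample(tr_idx)
      batches <- split(ord, ceiling(seq_along(ord) / o$batch_size))
      tl <- 0
      for (b in batches) {
        bmask <- if (o$mask_fraction > 0) {
          sample.int(m, ceiling(o$mask_fraction * m))
        } else integer(0)
        res <- step_fn(model$params, X[b, , drop = FALSE],
                       Y[b, , drop = FALSE], bmask)
        if (!is.finite(res$loss)) {
          gex_abort(sprintf("non-finite training loss at epoch %d", ep))
        }
        upd <- adam_step(model$params, res$grads, state, lr = o$learning_rate)
        model$params <- upd$params
        state <- upd$state
        tl <- tl + res$loss * length(b)
      }
      tl <- tl / length(tr_idx)
      vl <- if (n_val > 0) {
        eval_fn(model$params, X[val_idx, , drop = FALSE],
                Y[val_idx, , drop = FALSE], val_mask)
      } else NA_real_
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = tl,
                                     val_loss = vl))
      if (isTRUE(o$verbose)) {
        message(sprintf("epoch %3d  train %.5f  val %s", ep, tl,
                        if (is.na(vl)) "-" else sprintf("%.5f", vl)))
      }
      monitor <- if (n_val > 0) vl else tl
      if (monitor < best$val - 1e-9) {
        best <- list(params = model$params, val = monitor, epoch = ep)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= o$patience) break
      }
    }
    model$params <- best$params
    model$history <- hist
    model
  })
}

fit_dense <- function(model, X, Y, o) {
  kind <- model$config$kind
  n_out <- ncol(Y)
  m <- ncol(X)
  step_fn <- function(params, Xb, Yb, bmask) {
    Xin <- Xb
    if (length(bmask)) Xin[, bmask] <- 0
    B <- nrow(Xb)
    if (kind == "mlp") {
      fwd <- mlp_forward(params, Xin)
      dY <- 2 * (fwd$Y - Yb) / (B * n_out)
      list(loss = mean((fwd$Y - Yb)^2),
           grads = mlp_backward(params, Xin, fwd, dY))
    } else {
      fwd <- ae_forward(params, Xin)
      # reconstruction targets the true (unmasked) landmark values
      dY <- 2 * (fwd$Y - Yb) / (B * n_out)
      dXh <- 2 * (fwd$Xhat - Xb) / (B * m)
      list(loss = mean((fwd$Y - Yb)^2) + mean((fwd$Xhat - Xb)^2),
           grads = ae_backward(params, Xin, fwd, dY, dXh))
    }
  }
  eval_fn <- function(params, Xb, Yb, bmask) {
    Xin <- Xb
    if (length(bmask)) Xin[, bmask] <- 0
    if (kind == "mlp") {
      mean((mlp_forward(params, Xin)$Y - Yb)^2)
    } else {
      fwd <- ae_forward(params, Xin)
      mean((fwd$Y - Yb)^2) + mean((fwd$Xhat - Xb)^2)
    }
  }
  run_epochs(model, X, Y, o, step_fn, eval_fn)
}

# assemble GNN node-feature arrays: channel 1 = expression value of
# observed landmarks (0 elsewhere), channel 2 = observed flag, optional
# further channels = static per-gene covariates
gnn_features <- function(nodes, landmark_ids, Xb, masked_cols, covariates) {
  N <- length(nodes)
  B <- nrow(Xb)
  ncov <- if (is.null(covariates)) 0L else ncol(covariates)
  F0 <- array(0, c(N, B, 2L + ncov))
  li <- match(landmark_ids, nodes)
  obs <- setdiff(seq_along(landmark_ids), masked_cols)
  if (length(obs)) {
    F0[li[obs], , 1] <- t(Xb[, obs, drop = FALSE])
    F0[li[obs], , 2] <- 1
  }
  if (ncov > 0) {
    ci <- match(rownames(covariates), nodes)
    for (k in seq_len(ncov)) {
      F0[ci, , 2L + k] <- covariates[, k]
    }
  }
  F0
}

fit_gnn <- function(model, X, Y, o) {
  kind <- model$config$kind
  L <- model$config$n_message_layers
  nodes <- model$graph$nodes
  ii <- match(colnames(Y), nodes)
  n_out <- ncol(Y)
  lmk <- model$landmark_ids
  cov <- o$covariates
  forward <- function(params, F0) {
    if (kind == "gcn") gcn_forward(params, model$internals$S, F0, L)
    else pna_forward(params, model$internals$ein, F0, L)
  }
  step_fn <- function(params, Xb, Yb, bmask) {
    F0 <- gnn_features(nodes, lmk, Xb, bmask, cov)
    fwd <- forward(params, F0)
    pred <- fwd$out[ii, , drop = FALSE]
    resid <- pred - t(Yb)
    dOut <- matrix(0, dim(F0)[1], dim(F0)[2])
    dOut[ii, ] <- 2 * resid / (n_out * nrow(Xb))
    grads <- if (kind == "gcn") {
      gcn_backward(params, model$internals$S, F0, fwd, dOut, L)
    } else {
      pna_backward(params, model$internals$ein, F0, fwd, dOut, L)
    }
    list(loss = mean(resid^2), grads = grads)
  }
  eval_fn <- function(params, Xb, Yb, bmask) {
    F0 <- gnn_features(nodes, lmk, Xb, bmask, cov)
    fwd <- forward(params, F0)
    mean((fwd$out[ii, , drop = FALSE] - t(Yb))^2)
  }
  run_epochs(model, X, Y, o, step_fn, eval_fn)
}

#' Predict a transcriptome from (possibly masked) landmark expression
#'
#' Masked and never-observed landmark nodes enter the models with value
#' 0 (and observed-flag 0 for GNNs).  Predictions cover exactly the
#' model's inferred-gene list, in stable order, and are finite for every
#' gene and sample; results do not depend on how samples are batched.
#'
#' @param object trained `predictor_model`.
#' @param observed samples x genes expression matrix restricted to
#'   (a subset of) the model's landmark genes.
#' @param mask optional character vector of landmark IDs to treat as
#'   masked even if present in `observed`.
#' @param ... unused.
#' @return samples x inferred-genes expression matrix.
#' @export
predict.predictor_model <- function(object, observed, mask = NULL, ...) {
  if (!object$trained) gex_abort("model is not trained")
  if (is.null(dim(observed))) {
    gex_abort("observed must be a samples x genes matrix (use drop = FALSE when subsetting)")
  }
  lmk <- object$landmark_ids
  unknown <- setdiff(colnames(observed), lmk)
  if (length(unknown)) {
    gex_abort(sprintf("observed gene(s) unknown to the model: %s",
                      paste(unknown, collapse = ", ")))
  }
  use <- setdiff(colnames(observed), mask)
  B <- nrow(observed)
  X <- matrix(0, B, length(lmk), dimnames = list(rownames(observed), lmk))
  X[, use] <- observed[, use, drop = FALSE]
  kind <- object$config$kind
  out <- if (kind == "lr") {
    cbind(1, X) %*% object$params$coef
  } else if (kind == "mlp") {
    mlp_forward(object$params, X)$Y
  } else if (kind == "ae") {
    ae_forward(object$params, X)$Y
  } else {
    masked_cols <- which(!lmk %in% use)
    F0 <- gnn_features(object$graph$nodes, lmk, X, masked_cols,
                       object$internals$covariates)
    fwd <- if (kind == "gcn") {
      gcn_forward(object$params, object$internals$S, F0,
                  object$config$n_message_layers)
    } else {
      pna_forward(object$params, object$internals$ein, F0,
                  object$config$n_message_layers)
    }
    t(fwd$out[match(object$inferred_ids, object$graph$nodes), ,
              drop = FALSE])
  }
  dimnames(out) <- list(rownames(observed), object$inferred_ids)
  if (any(!is.finite(out))) gex_abort("non-finite prediction")
  out
}
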