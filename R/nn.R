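# internal neural-network machinery: parameter init, Adam, dense and
# graph forward/backward passes.  All models are trained with explicit
# reverse-mode gradients; no autodiff dependency.

glorot <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / (fan_in + fan_out))),
         fan_in, fan_out)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# row-broadcast bias add without sweep()'s aperm overhead
addb <- function(M, b) M + rep(b, each = nrow(M))

adam_init <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# ---- dense models -------------------------------------------------------

mlp_forward <- function(params, X) {
  H <- relu(addb(X %*% params$W1, params$b1))
  Y <- addb(H %*% params$W2, params$b2)
  list(Y = Y, H = H)
}

mlp_backward <- function(params, X, fwd, dY) {
  dW2 <- crossprod(fwd$H, dY)
  db2 <- colSums(dY)
  dH <- dY %*% t(params$W2)
  dH[fwd$H <= 0] <- 0
  list(W1 = crossprod(X, dH), b1 = colSums(dH), W2 = dW2, b2 = db2)
}

ae_forward <- function(params, X) {
  Z <- relu(addb(X %*% params$We, params$be))
  Xhat <- addb(Z %*% params$Wd, params$bd)
  Y <- addb(Xhat %*% params$Wo, params$bo)
  list(Y = Y, Xhat = Xhat, Z = Z)
}

# dY: gradient wrt predicted output; dXhat_loss: gradient of the
# reconstruction term wrt the reconstruction layer
ae_backward <- function(params, X, fwd, dY, dXhat_loss) {
  dWo <- crossprod(fwd$Xhat, dY)
  dbo <- colSums(dY)
  dXhat <- dXhat_loss + dY %*% t(params$Wo)
  dWd <- crossprod(fwd$Z, dXhat)
  dbd <- colSums(dXhat)
  dZ <- dXhat %*% t(params$Wd)
  dZ[fwd$Z <= 0] <- 0
  list(We = crossprod(X, dZ), be = colSums(dZ),
       Wd = dWd, bd = dbd, Wo = dWo, bo = dbo)
}

# ---- GCN ---------------------------------------------------------------
# Node features are carried as arrays (N nodes, B samples, d channels).
# Because the layout is column-major with nodes fastest, the reshapes
# (N, B, d) <-> (N, B*d) (for the sparse node-dimension propagation) and
# (N, B, d) <-> (N*B, d) (for the dense channel transform) are pure
# dim-changes on contiguous data -- no transposition, no copy.

arr_nodes_mat <- function(F) {
  dim(F) <- c(dim(F)[1], dim(F)[2] * dim(F)[3])
  F
}

arr_chan_mat <- function(F) {
  dim(F) <- c(dim(F)[1] * dim(F)[2], dim(F)[3])
  F
}

gcn_forward <- function(params, S, F0, n_layers) {
  N <- dim(F0)[1]
  B <- dim(F0)[2]
  F <- F0
  cache <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    d <- dim(F)[3]
    dim(F) <- c(N, B * d)
    P <- as.matrix(S %*% F)              # N x (B*d)
    dim(P) <- c(N * B, d)
    W <- params[[sprintf("W%d", l)]]
    H <- relu(addb(P %*% W, params[[sprintf("b%d", l)]]))   # (N*B) x h
    cache[[l]] <- list(P = P, H = H)
    F <- H
    dim(F) <- c(N, B, ncol(W))
  }
  dim(F) <- c(N * B, dim(F)[3])
  out <- addb(F %*% params$Whead, params$bhead)
  dim(out) <- c(N, B)
  list(out = out, F_last = F, cache = cache)
}

gcn_backward <- function(params, S, F0, fwd, dOut, n_layers) {
  N <- dim(dOut)[1]
  B <- dim(dOut)[2]
  grads <- list()
  dOutv <- dOut
  dim(dOutv) <- c(N * B, 1)
  grads$Whead <- crossprod(fwd$F_last, dOutv)
  grads$bhead <- sum(dOutv)
  dF <- dOutv %*% t(params$Whead)        # (N*B) x h
  for (l in rev(seq_len(n_layers))) {
    W <- params[[sprintf("W%d", l)]]
    cl <- fwd$cache[[l]]
    dH <- dF
    dH[cl$H <= 0] <- 0
    grads[[sprintf("W%d", l)]] <- crossprod(cl$P, dH)
    grads[[sprintf("b%d", l)]] <- colSums(dH)
    dP <- dH %*% t(W)                    # (N*B) x d
    d <- ncol(dP)
    dim(dP) <- c(N, B * d)
    # S is symmetric, so the adjoint of the propagation is S itself
    dF <- as.matrix(S %*% dP)
    dim(dF) <- c(N * B, d)
  }
  grads
}

# ---- PNA ---------------------------------------------------------------
# Directed incidence: every merged undirected edge (i, j) yields the two
# messages j->i and i->j.  `ein` caches src/dst vectors, per-node
# incoming-edge index lists, degrees and the degree scalers.

pna_edge_index <- function(graph, aggregators, scalers) {
  n <- length(graph$nodes)
  idx <- stats::setNames(seq_len(n), graph$nodes)
  e <- graph$edges
  src <- c(idx[e$gene_b], idx[e$gene_a])
  dst <- c(idx[e$gene_a], idx[e$gene_b])
  deg <- tabulate(dst, nbins = n)
  dhat <- graph_degrees(graph)$dhat
  delta <- mean(log(dhat + 1))
  scale_of <- function(s, d) {
    switch(s,
           identity = rep(1, length(d)),
           amplification = log(d + 1) / delta,
           attenuation = ifelse(d > 0, delta / log(d + 1), 0),
           linear = d / exp(delta),
           gex_abort(sprintf("unknown scaler '%s'", s)))
  }
  scale_mat <- vapply(scalers, scale_of, numeric(n), d = deg)
  list(src = unname(src), dst = unname(dst), deg = deg, delta = delta,
       by_dst = split(seq_along(dst), factor(dst, levels = seq_len(n))),
       scale_mat = matrix(scale_mat, nrow = n,
                          dimnames = list(NULL, scalers)),
       aggregators = aggregators, scalers = scalers)
}

# rowsum() drops empty groups; degree-0 nodes must keep zero rows
full_rowsum <- function(M, group, n) {
  rs <- rowsum(M, group)
  out <- matrix(0, n, ncol(M))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# messages M: matrix E2 x (B*w); returns per-aggregator node matrices
# N x (B*w) plus argmax/argmin bookkeeping for the backward pass
pna_aggregate_nodes <- function(M, ein, n, B, w) {
  cols <- B * w
  agg <- list()
  store <- list()
  deg <- ein$deg
  sums <- full_rowsum(M, ein$dst, n)
  means <- sums / pmax(deg, 1)
  means[deg == 0, ] <- 0
  if ("mean" %in% ein$aggregators) agg$mean <- means
  if ("std" %in% ein$aggregators) {
    sq <- full_rowsum(M * M, ein$dst, n) / pmax(deg, 1)
    v <- sq - means^2
    v[v < 0] <- 0
    s <- sqrt(v)
    s[deg == 0, ] <- 0
    agg$std <- s
    store$std <- s
  }
  store$mean <- means
  if (any(c("max", "min") %in% ein$aggregators)) {
    mx <- matrix(0, n, cols)
    mn <- matrix(0, n, cols)
    amax <- matrix(NA_integer_, n, cols)
    amin <- matrix(NA_integer_, n, cols)
    for (i in which(deg > 0)) {
      ix <- ein$by_dst[[i]]
      sub <- M[ix, , drop = FALSE]
      ax <- max.col(t(sub), ties.method = "first")
      an <- max.col(t(-sub), ties.method = "first")
      mx[i, ] <- sub[cbind(ax, seq_len(cols))]
      mn[i, ] <- sub[cbind(an, seq_len(cols))]
      amax[i, ] <- ix[ax]
      amin[i, ] <- ix[an]
    }
    if ("max" %in% ein$aggregators) agg$max <- mx
    if ("min" %in% ein$aggregators) agg$min <- mn
    store$amax <- amax
    store$amin <- amin
  }
  list(agg = agg[ein$aggregators], store = store)
}

pna_layer_forward <- function(Wh, bh, Wg, bg, F, ein) {
  N <- dim(F)[1]
  B <- dim(F)[2]
  d <- dim(F)[3]
  w <- ncol(Wh)
  Fd <- F[ein$dst, , , drop = FALSE]
  Fs <- F[ein$src, , , drop = FALSE]
  E2 <- length(ein$dst)
  msg_in <- cbind(arr_chan_mat(Fd), arr_chan_mat(Fs))       # (E2*B) x 2d
  M <- relu(addb(msg_in %*% Wh, bh))
  Mmat <- M
  dim(Mmat) <- c(E2, B * w)
  ag <- pna_aggregate_nodes(Mmat, ein, N, B, w)
  blocks <- list()
  for (s in ein$scalers) {
    sc <- ein$scale_mat[, s]
    for (a in ein$aggregators) {
      blocks[[paste(s, a)]] <- ag$agg[[a]] * sc    # scaler broadcasts by node
    }
  }
  G <- do.call(cbind, blocks)                                 # N x (B*w*S*A)
  nblk <- length(blocks)
  Garr <- array(G, c(N, B, w * nblk))
  gin <- cbind(arr_chan_mat(F), arr_chan_mat(Garr))           # (N*B) x (d + w*S*A)
  H <- relu(addb(gin %*% Wg, bg))
  list(F_out = array(H, c(N, B, ncol(Wg))),
       cache = list(msg_in = msg_in, M = M, Mmat = Mmat, ag = ag,
                    gin = gin, H = H, d = d, w = w, nblk = nblk,
                    E2 = E2, N = N, B = B))
}

pna_layer_backward <- function(Wh, Wg, ein, cache, dF_out) {
  N <- cache$N; B <- cache$B; d <- cache$d; w <- cache$w
  E2 <- cache$E2
  dH <- arr_chan_mat(dF_out)
  dH[cache$H <= 0] <- 0
  dWg <- crossprod(cache$gin, dH)
  dbg <- colSums(dH)
  dgin <- dH %*% t(Wg)
  dF_self <- array(dgin[, seq_len(d), drop = FALSE], c(N, B, d))
  dGarr <- array(dgin[, d + seq_len(w * cache$nblk), drop = FALSE],
                 c(N, B, w * cache$nblk))
  dG <- matrix(dGarr, N, B * w * cache$nblk)
  deg <- ein$deg
  dMmat <- matrix(0, E2, B * w)
  blk <- 0L
  for (s in ein$scalers) {
    sc <- ein$scale_mat[, s]
    for (a in ein$aggregators) {
      dA <- dG[, blk * B * w + seq_len(B * w), drop = FALSE] * sc
      blk <- blk + 1L
      if (a == "mean") {
        dMmat <- dMmat + dA[ein$dst, , drop = FALSE] / pmax(deg, 1)[ein$dst]
      } else if (a == "max" || a == "min") {
        am <- if (a == "max") cache$ag$store$amax else cache$ag$store$amin
        live <- which(deg > 0)
        if (length(live)) {
          rows <- as.vector(am[live, , drop = FALSE])
          cols <- rep(seq_len(B * w), each = length(live))
          vals <- as.vector(dA[live, , drop = FALSE])
          # each (edge, column) cell belongs to exactly one target node
          dMmat[cbind(rows, cols)] <- dMmat[cbind(rows, cols)] + vals
        }
      } else if (a == "std") {
        sd_n <- cache$ag$store$std
        mean_n <- cache$ag$store$mean
        denom <- pmax(deg, 1)[ein$dst] * sd_n[ein$dst, , drop = FALSE]
        term <- dA[ein$dst, , drop = FALSE] *
          (cache$Mmat - mean_n[ein$dst, , drop = FALSE])
        term[denom < 1e-12] <- 0
        denom[denom < 1e-12] <- 1
        dMmat <- dMmat + term / denom
      }
    }
  }
  dM <- arr_chan_mat(array(dMmat, c(E2, B, w)))
  dM[cache$M <= 0] <- 0
  dWh <- crossprod(cache$msg_in, dM)
  dbh <- colSums(dM)
  dmsg_in <- dM %*% t(Wh)
  d_dst <- array(dmsg_in[, seq_len(d), drop = FALSE], c(E2, B, d))
  d_src <- array(dmsg_in[, d + seq_len(d), drop = FALSE], c(E2, B, d))
  add_by <- function(acc, arr, group) {
    gm <- full_rowsum(matrix(arr, E2, B * d), group, N)
    acc + array(gm, c(N, B, d))
  }
  dF <- dF_self
  dF <- add_by(dF, d_dst, ein$dst)
  dF <- add_by(dF, d_src, ein$src)
  list(grads = list(Wh = dWh, bh = dbh, Wg = dWg, bg = dbg), dF = dF)
}

pna_forward <- function(params, ein, F0, n_layers) {
  F <- F0
  caches <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    res <- pna_layer_forward(params[[sprintf("Wh%d", l)]],
                             params[[sprintf("bh%d", l)]],
                             params[[sprintf("Wg%d", l)]],
                             params[[sprintf("bg%d", l)]], F, ein)
    caches[[l]] <- res$cache
    F <- res$F_out
  }
  N <- dim(F)[1]
  B <- dim(F)[2]
  out <- addb(arr_chan_mat(F) %*% params$Whead, params$bhead)
  dim(out) <- c(N, B)
  list(out = out, F_last = F, caches = caches)
}

pna_backward <- function(params, ein, F0, fwd, dOut, n_layers) {
  N <- dim(F0)[1]
  B <- dim(F0)[2]
  grads <- list()
  Fl <- arr_chan_mat(fwd$F_last)
  dOutv <- matrix(dOut, N * B, 1)
  grads$Whead <- crossprod(Fl, dOutv)
  grads$bhead <- sum(dOutv)
  dF <- array(dOutv %*% t(params$Whead), dim(fwd$F_last))
  for (l in rev(seq_len(n_layers))) {
    res <- pna_layer_backward(params[[sprintf("Wh%d", l)]],
                              params[[sprintf("Wg%d", l)]],
                              ein, fwd$caches[[l]], dF)
    grads[[sprintf("Wh%d", l)]] <- res$grads$Wh
    grads[[sprintf("bh%d", l)]] <- res$grads$bh
    grads[[sprintf("Wg%d", l)]] <- res$grads$Wg
    grads[[sprintf("bg%d", l)]] <- res$grads$bg
    dF <- res$dF
  }
  grads
}
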