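# Graph attention network that predicts the heteropolymer interaction
# parameters U = L + T directly from a contact map.
#
# The network operates on the 100 kb coarsening of a 50 kb map: nodes are
# 100 kb bins, node features are the top-10 eigenvectors of the
# observed/expected map, edge features are [log H_ij, diagonal mean].
# Message passing is dynamic (GATv2-style) attention with edge features
# mixed into the attention score, interleaved with residual MLPs. Two
# heads decode the latent node embedding Z: a bilinear head
# L100 = Z W Z^T upsampled 2x to 50 kb, and an MLP on the flattened Z
# emitting the m Toeplitz diagonal values of T. Eigenvector sign ambiguity
# is removed by running the network on +X and -X and summing.
#
# No autodiff framework is available in this stack, so forward and
# backward passes are written out explicitly; the backward pass is checked
# against finite differences in the test suite.

#' Graph network configuration
#'
#' @param n_message_layers Number of attention + MLP blocks.
#' @param hidden_dim Node embedding width (also total attention width;
#'   must be divisible by `n_attention_heads`).
#' @param n_attention_heads Attention heads per layer.
#' @param mlp_hidden_dim Width of the residual MLPs between message-passing
#'   layers.
#' @param t_hidden_dim Width of the genomic-distance head MLP.
#' @param k_node_eigvecs Number of eigenvector node features (10).
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param n_epochs Training epochs.
#' @param patience Early-stopping patience on validation loss (epochs);
#'   `Inf` disables early stopping.
#' @param leaky_slope Negative slope of the leaky ReLU.
#' @param seed Integer seed controlling initialization and batching.
#' @return A `GNNConfig` list.
#' @export
gnn_config <- function(n_message_layers = 2L, hidden_dim = 32L,
                       n_attention_heads = 2L, mlp_hidden_dim = 64L,
                       t_hidden_dim = 64L, k_node_eigvecs = 10L,
                       learning_rate = 1e-3, batch_size = 8L,
                       n_epochs = 100L, patience = Inf,
                       leaky_slope = 0.01, seed = 1L) {
  stopifnot(n_message_layers >= 1, hidden_dim >= 1, n_attention_heads >= 1,
            hidden_dim %% n_attention_heads == 0, mlp_hidden_dim >= 1,
            t_hidden_dim >= 1, k_node_eigvecs >= 1, learning_rate > 0,
            batch_size >= 1, n_epochs >= 1)
  structure(list(n_message_layers = as.integer(n_message_layers),
                 hidden_dim = as.integer(hidden_dim),
                 n_attention_heads = as.integer(n_attention_heads),
                 mlp_hidden_dim = as.integer(mlp_hidden_dim),
                 t_hidden_dim = as.integer(t_hidden_dim),
                 k_node_eigvecs = as.integer(k_node_eigvecs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 n_epochs = as.integer(n_epochs),
                 patience = patience,
                 leaky_slope = leaky_slope,
                 seed = as.integer(seed)), class = "GNNConfig")
}

#' Build the graph representation of a 100 kb contact map
#'
#' The map is first normalized by the mean of its main diagonal, and the
#' diagonal is then overwritten with 1. The adjacency is `A_ij = 1` iff the
#' normalized entry is positive (a strictly positive map gives a complete
#' graph). Node features are the top `k_node_eigvecs` eigenvectors (by
#' eigenvalue magnitude, deterministic sign) of the observed/expected map;
#' edge features are the entry's log and the mean of its diagonal.
#'
#' @param H100 A [contact_map()] at 100 kb resolution.
#' @return A `GraphInput`: list with `A` (n x n 0/1), `X` (n x k), `E1`
#'   (log entries, 0 where `A == 0`), `E2` (diagonal means), `n`.
#' @export
build_graph <- function(H100) {
  stopifnot(inherits(H100, "ContactMap"))
  V <- H100$values
  n <- nrow(V)
  dmean <- mean(diag(V))
  if (dmean <= 0) stop("all-zero main diagonal; cannot build graph")
  V <- V / dmean
  diag(V) <- 1
  A <- (V > 0) * 1
  Hn <- distance_normalize(V)$values
  e <- eigen(Hn, symmetric = TRUE)
  k <- 10L
  if (n < k) stop("need at least 10 nodes for eigenvector features, got ", n)
  ord <- order(abs(e$values), decreasing = TRUE)[seq_len(k)]
  X <- e$vectors[, ord, drop = FALSE]
  for (j in seq_len(k)) {
    if (X[which.max(abs(X[, j])), j] < 0) X[, j] <- -X[, j]
  }
  E1 <- matrix(0, n, n)
  E1[A == 1] <- log(V[A == 1])
  dm <- diag_means(V)
  E2 <- matrix(dm[abs(row(V) - col(V)) + 1], n, n)
  structure(list(A = A, X = X, E1 = E1, E2 = E2, n = n),
            class = "GraphInput")
}

#' Signed logarithm transform and its inverse
#'
#' `signed_log_transform(U) = sign(U) * log(|U| + 1)` compresses the
#' dynamic range of interaction parameters symmetrically about zero; the
#' training loss is computed in this representation. The transform is odd
#' and invertible: `signed_log_inverse(x) = sign(x) * (exp(|x|) - 1)`.
#'
#' @param U Numeric matrix or vector.
#' @return Transformed object of the same shape.
#' @export
signed_log_transform <- function(U) {
  if (!all(is.finite(U))) stop("non-finite input")
  sign(U) * log(abs(U) + 1)
}

#' @rdname signed_log_transform
#' @param x Transformed values.
#' @export
signed_log_inverse <- function(x) {
  if (!all(is.finite(x))) stop("non-finite input")
  sign(x) * (exp(abs(x)) - 1)
}

.glorot <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

#' Initialize network weights
#'
#' @param config A [gnn_config()].
#' @param n_nodes Number of graph nodes (m/2); the flattened-Z distance
#'   head fixes this at training time.
#' @param m_out Output side length at 50 kb (2 * n_nodes).
#' @return Nested weight list (class `gnn_weights`).
#' @export
init_gnn_weights <- function(config, n_nodes, m_out = 2L * n_nodes) {
  set.seed(config$seed)
  h <- config$hidden_dim
  nh <- config$n_attention_heads
  da <- h %/% nh   # per-head attention and value width
  layers <- lapply(seq_len(config$n_message_layers), function(l) {
    heads <- lapply(seq_len(nh), function(a) {
      list(Wl = .glorot(h, da), Wr = .glorot(h, da),
           We = .glorot(2L, da), av = stats::rnorm(da, sd = 1 / sqrt(da)),
           Wv = .glorot(h, da), Wev = .glorot(2L, da))
    })
    list(heads = heads, W_o = .glorot(h, h), b_o = rep(0, h),
         W1 = .glorot(h, config$mlp_hidden_dim),
         b1 = rep(0, config$mlp_hidden_dim),
         W2 = .glorot(config$mlp_hidden_dim, h), b2 = rep(0, h))
  })
  w <- list(W_in = .glorot(config$k_node_eigvecs, h), b_in = rep(0, h),
            layers = layers,
            W_bilin = .glorot(h, h),
            Wt1 = .glorot(n_nodes * h, config$t_hidden_dim),
            bt1 = rep(0, config$t_hidden_dim),
            Wt2 = .glorot(config$t_hidden_dim, m_out),
            bt2 = rep(0, m_out))
  attr(w, "n_nodes") <- as.integer(n_nodes)
  attr(w, "m_out") <- as.integer(m_out)
  class(w) <- "gnn_weights"
  w
}

.lrelu <- function(x, slope) ifelse(x > 0, x, slope * x)
.lrelu_grad <- function(x, slope) ifelse(x > 0, 1, slope)

.row_softmax_masked <- function(score, A) {
  score[A == 0] <- -Inf
  mx <- apply(score, 1, max)
  mx[!is.finite(mx)] <- 0          # isolated node: all-zero attention row
  ex <- exp(score - mx)
  ex[A == 0] <- 0
  rs <- rowSums(ex)
  rs[rs == 0] <- 1
  ex / rs
}

# upsample 100 kb -> 50 kb: replicate each entry into a 2x2 block
.upsample2 <- function(M) {
  idx <- rep(seq_len(nrow(M)), each = 2L)
  M[idx, idx, drop = FALSE]
}

# adjoint of .upsample2: sum each 2x2 block
.downsample2_sum <- function(M) {
  idx <- rep(seq_len(nrow(M) %/% 2L), each = 2L)
  t(rowsum(t(rowsum(M, idx)), idx))
}

#' Single forward pass of the network (one eigenvector sign)
#'
#' Most callers want [sign_invariant_forward()]; this single-sign pass is
#' exposed for testing and gradient checking.
#'
#' @param graph A `GraphInput` from [build_graph()].
#' @param weights From [init_gnn_weights()] or [train_gnn()].
#' @param config The matching [gnn_config()].
#' @param keep_cache Keep intermediates for the backward pass.
#' @return A `PredictionOutput`: list with `L_hat`, `T_hat`,
#'   `U_hat = L_hat + T_hat` (all m x m at 50 kb), `t_vals`, `Z`, and
#'   (optionally) `cache`.
#' @export
gnn_forward <- function(graph, weights, config, keep_cache = FALSE) {
  n <- graph$n
  stopifnot(n == attr(weights, "n_nodes"))
  slope <- config$leaky_slope
  h <- config$hidden_dim
  nh <- config$n_attention_heads
  da <- h %/% nh
  X <- graph$X
  A <- graph$A
  E1 <- graph$E1
  E2 <- graph$E2

  cache <- list(layers = list())
  X0 <- X %*% weights$W_in + matrix(weights$b_in, n, h, byrow = TRUE)
  cache$X_in <- X

  for (l in seq_len(config$n_message_layers)) {
    lw <- weights$layers[[l]]
    lc <- list(Xin = X0, heads = list())
    M <- matrix(0, n, h)
    for (a in seq_len(nh)) {
      hw <- lw$heads[[a]]
      Pl <- X0 %*% hw$Wl
      Pr <- X0 %*% hw$Wr
      S <- array(0, c(n, n, da))
      G <- array(0, c(n, n, da))
      score <- matrix(0, n, n)
      for (cc in seq_len(da)) {
        Sc <- matrix(Pl[, cc], n, n) + matrix(Pr[, cc], n, n, byrow = TRUE) +
          E1 * hw$We[1, cc] + E2 * hw$We[2, cc]
        Gc <- .lrelu(Sc, slope)
        S[, , cc] <- Sc
        G[, , cc] <- Gc
        score <- score + Gc * hw$av[cc]
      }
      alpha <- .row_softmax_masked(score, A)
      V <- X0 %*% hw$Wv
      # edge features enter the aggregated message as well as the
      # attention logits, so edge magnitudes can reach the embedding
      C1 <- rowSums(alpha * E1)
      C2 <- rowSums(alpha * E2)
      out_a <- alpha %*% V + outer(C1, hw$Wev[1, ]) + outer(C2, hw$Wev[2, ])
      M[, ((a - 1) * da + 1):(a * da)] <- out_a
      lc$heads[[a]] <- list(Pl = Pl, Pr = Pr, S = S, G = G, alpha = alpha,
                            V = V, C1 = C1, C2 = C2)
    }
    att <- M %*% lw$W_o + matrix(lw$b_o, n, h, byrow = TRUE)
    X1 <- X0 + att
    pre <- X1 %*% lw$W1 + matrix(lw$b1, n, config$mlp_hidden_dim,
                                 byrow = TRUE)
    H1 <- .lrelu(pre, slope)
    X2 <- X1 + H1 %*% lw$W2 + matrix(lw$b2, n, h, byrow = TRUE)
    lc$M <- M; lc$X1 <- X1; lc$pre <- pre; lc$H1 <- H1
    cache$layers[[l]] <- lc
    X0 <- X2
  }

  Z <- X0
  Ws <- (weights$W_bilin + t(weights$W_bilin)) / 2
  L100 <- Z %*% Ws %*% t(Z)
  L_hat <- .upsample2(L100)

  zf <- matrix(as.vector(Z), 1)
  pre_t <- zf %*% weights$Wt1 + matrix(weights$bt1, 1)
  h1 <- .lrelu(pre_t, slope)
  t_vals <- drop(h1 %*% weights$Wt2 + matrix(weights$bt2, 1))
  T_hat <- stats::toeplitz(t_vals)
  out <- list(L_hat = L_hat, T_hat = T_hat, U_hat = L_hat + T_hat,
              t_vals = t_vals, Z = Z)
  if (keep_cache) {
    cache$Z <- Z; cache$Ws <- Ws; cache$L100 <- L100
    cache$zf <- zf; cache$pre_t <- pre_t; cache$h1 <- h1
    out$cache <- cache
  }
  class(out) <- "PredictionOutput"
  out
}

# Backward pass for one gnn_forward() call. dU is the loss gradient with
# respect to U_hat (m x m). Returns gradients in the same nested shape as
# the weights. graph supplies A/E1/E2 (constants of the pass).
gnn_backward <- function(cache, dU, graph, weights, config) {
  n <- graph$n
  slope <- config$leaky_slope
  h <- config$hidden_dim
  nh <- config$n_attention_heads
  da <- h %/% nh
  m_out <- attr(weights, "m_out")

  g <- list()

  # Toeplitz head: T_ij = t[|i - j| + 1]
  dmat <- abs(row(dU) - col(dU))
  dt_vals <- vapply(0:(m_out - 1), function(d) sum(dU[dmat == d]),
                    numeric(1))
  g$bt2 <- dt_vals
  g$Wt2 <- t(cache$h1) %*% matrix(dt_vals, 1)
  dh1 <- matrix(dt_vals, 1) %*% t(weights$Wt2)
  dpre_t <- dh1 * .lrelu_grad(cache$pre_t, slope)
  g$Wt1 <- t(cache$zf) %*% dpre_t
  g$bt1 <- drop(dpre_t)
  dzf <- dpre_t %*% t(weights$Wt1)
  dZ <- matrix(as.vector(dzf), n, h)

  # bilinear head (upsample adjoint = 2x2 block sum)
  dL100 <- .downsample2_sum(dU)
  Z <- cache$Z; Ws <- cache$Ws
  dWs <- t(Z) %*% dL100 %*% Z
  g$W_bilin <- (dWs + t(dWs)) / 2
  dZ <- dZ + dL100 %*% Z %*% t(Ws) + t(dL100) %*% Z %*% Ws

  dX2 <- dZ
  g$layers <- vector("list", config$n_message_layers)
  for (l in rev(seq_len(config$n_message_layers))) {
    lw <- weights$layers[[l]]
    lc <- cache$layers[[l]]
    lg <- list()
    # MLP sublayer
    dX1 <- dX2
    dH1 <- dX2 %*% t(lw$W2)
    lg$W2 <- t(lc$H1) %*% dX2
    lg$b2 <- colSums(dX2)
    dpre <- dH1 * .lrelu_grad(lc$pre, slope)
    lg$W1 <- t(lc$X1) %*% dpre
    lg$b1 <- colSums(dpre)
    dX1 <- dX1 + dpre %*% t(lw$W1)
    # attention sublayer
    dX0 <- dX1
    dM <- dX1 %*% t(lw$W_o)
    lg$W_o <- t(lc$M) %*% dX1
    lg$b_o <- colSums(dX1)
    Xin <- lc$Xin
    lg$heads <- vector("list", nh)
    for (a in seq_len(nh)) {
      hw <- lw$heads[[a]]
      hc <- lc$heads[[a]]
      hg <- list()
      dhead <- dM[, ((a - 1) * da + 1):(a * da), drop = FALSE]
      dalpha <- dhead %*% t(hc$V)
      dV <- t(hc$alpha) %*% dhead
      hg$Wv <- t(Xin) %*% dV
      dX0 <- dX0 + dV %*% t(hw$Wv)
      # edge-feature message term
      hg$Wev <- rbind(drop(t(dhead) %*% hc$C1), drop(t(dhead) %*% hc$C2))
      dC1 <- drop(dhead %*% hw$Wev[1, ])
      dC2 <- drop(dhead %*% hw$Wev[2, ])
      dalpha <- dalpha + dC1 * graph$E1 + dC2 * graph$E2
      # softmax rows
      srow <- rowSums(hc$alpha * dalpha)
      dscore <- hc$alpha * (dalpha - srow)
      dPl <- matrix(0, n, da)
      dPr <- matrix(0, n, da)
      hg$We <- matrix(0, 2, da)
      hg$av <- numeric(da)
      for (cc in seq_len(da)) {
        dGc <- dscore * hw$av[cc]
        hg$av[cc] <- sum(hc$G[, , cc] * dscore)
        dSc <- dGc * .lrelu_grad(hc$S[, , cc], slope)
        dPl[, cc] <- rowSums(dSc)
        dPr[, cc] <- colSums(dSc)
        hg$We[1, cc] <- sum(graph$E1 * dSc)
        hg$We[2, cc] <- sum(graph$E2 * dSc)
      }
      hg$Wl <- t(Xin) %*% dPl
      hg$Wr <- t(Xin) %*% dPr
      dX0 <- dX0 + dPl %*% t(hw$Wl) + dPr %*% t(hw$Wr)
      lg$heads[[a]] <- hg
    }
    g$layers[[l]] <- lg
    dX2 <- dX0
  }
  g$W_in <- t(cache$X_in) %*% dX2
  g$b_in <- colSums(dX2)
  g
}

# deterministic per-column sign representative: largest-|entry| positive
.canon_sign_cols <- function(X) {
  for (j in seq_len(ncol(X))) {
    if (X[which.max(abs(X[, j])), j] < 0) X[, j] <- -X[, j]
  }
  X
}

#' Sign-invariant forward pass
#'
#' Eigenvector node features carry an arbitrary sign per column. Two
#' mechanisms remove it exactly: each column is first mapped to its
#' canonical sign representative (largest-magnitude component positive),
#' making the pass invariant to negating any subset of columns by
#' construction; then [gnn_forward()] is run with the canonical `X` and
#' with `-X` and the two predictions are summed (elementwise, separately
#' for `L_hat` and `T_hat`), so neither global orientation is privileged.
#'
#' @inheritParams gnn_forward
#' @return A `PredictionOutput` (with caches of both passes when
#'   `keep_cache = TRUE`).
#' @export
sign_invariant_forward <- function(graph, weights, config,
                                   keep_cache = FALSE) {
  graph$X <- .canon_sign_cols(graph$X)
  gp <- graph
  gm <- graph
  gm$X <- -graph$X
  fp <- gnn_forward(gp, weights, config, keep_cache = keep_cache)
  fm <- gnn_forward(gm, weights, config, keep_cache = keep_cache)
  L_hat <- fp$L_hat + fm$L_hat
  T_hat <- fp$T_hat + fm$T_hat
  out <- list(L_hat = L_hat, T_hat = T_hat, U_hat = L_hat + T_hat,
              t_vals = fp$t_vals + fm$t_vals)
  if (keep_cache) out$caches <- list(pos = fp$cache, neg = fm$cache)
  class(out) <- "PredictionOutput"
  out
}

# --- training ---------------------------------------------------------------

# recurse two parallel weight/gradient trees, aligning named components by
# name (field order differs between init and backward) and unnamed ones
# (layer / head lists) by position
.tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    keys <- if (!is.null(names(a)) && all(names(a) != "")) names(a)
            else seq_along(a)
    out <- a
    for (k in keys) out[[k]] <- .tree_map2(f, a[[k]], b[[k]])
    out
  } else f(a, b)
}

.tree_zero <- function(a) {
  if (is.list(a)) lapply(a, .tree_zero) else a * 0
}

.adam_step <- function(w, g, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$m <- .tree_map2(function(m, gr) beta1 * m + (1 - beta1) * gr, st$m, g)
  st$v <- .tree_map2(function(v, gr) beta2 * v + (1 - beta2) * gr^2, st$v, g)
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  upd <- .tree_map2(function(m, v) lr * (m / corr1) / (sqrt(v / corr2) + eps),
                    st$m, st$v)
  attrs <- attributes(w)
  w <- .tree_map2(`-`, w, upd)
  attributes(w) <- attrs
  list(w = w, st = st)
}

.gnn_loss_grad <- function(graph, weights, config, U_target_slog) {
  graph$X <- .canon_sign_cols(graph$X)
  fwd <- sign_invariant_forward(graph, weights, config, keep_cache = TRUE)
  m2 <- length(U_target_slog)
  diffs <- signed_log_transform(fwd$U_hat) - U_target_slog
  loss <- mean(diffs^2)
  # d slog(u) / du = 1 / (|u| + 1)
  dU <- (2 / m2) * diffs / (abs(fwd$U_hat) + 1)
  gp <- gnn_backward(fwd$caches$pos, dU, graph, weights, config)
  gm_graph <- graph
  gm_graph$X <- -graph$X
  gm <- gnn_backward(fwd$caches$neg, dU, gm_graph, weights, config)
  list(loss = loss, grad = .tree_map2(`+`, gp, gm))
}

#' Train the parameter-prediction network
#'
#' Minimizes the mean squared error between the signed-log transformed
#' prediction and ground truth, `mean((U_hat^dagger - U^dagger)^2)`, with
#' Adam over minibatches. Each training pair's 50 kb contact map is
#' coarsened to 100 kb and converted to a graph once, up front. The data
#' are split 90/10 into train/validation by position after a seeded
#' shuffle.
#'
#' @param dataset List of `TrainingPair`s from [build_dataset()].
#' @param config A [gnn_config()].
#' @param verbose Print per-epoch losses.
#' @return List with `weights`, `config`, `history` (per-epoch data frame
#'   of train/validation loss), and `n_nodes`.
#' @export
train_gnn <- function(dataset, config, verbose = FALSE) {
  if (length(dataset) == 0) stop("empty dataset")
  m <- nrow(dataset[[1]]$H$values)
  graphs <- lapply(dataset, function(p) build_graph(coarsen_2x(p$H)))
  targets <- lapply(dataset, function(p) signed_log_transform(p$params$U))
  n_nodes <- graphs[[1]]$n

  set.seed(config$seed)
  idx <- sample(length(dataset))
  n_val <- max(1L, floor(0.1 * length(dataset)))
  if (length(dataset) < 2) n_val <- 0L
  val_idx <- if (n_val > 0) idx[seq_len(n_val)] else integer(0)
  train_idx <- setdiff(idx, val_idx)

  weights <- init_gnn_weights(config, n_nodes, m)
  st <- list(m = .tree_zero(weights), v = .tree_zero(weights))
  t_step <- 0L
  best_val <- Inf
  best_weights <- weights
  since_best <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))

  for (epoch in seq_len(config$n_epochs)) {
    ord <- sample(train_idx)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    epoch_loss <- 0
    for (b in batches) {
      grad <- NULL
      bl <- 0
      for (s in b) {
        lg <- .gnn_loss_grad(graphs[[s]], weights, config, targets[[s]])
        bl <- bl + lg$loss
        grad <- if (is.null(grad)) lg$grad else .tree_map2(`+`, grad, lg$grad)
      }
      grad <- .tree_map2(function(x, y) x / length(b), grad, grad)
      t_step <- t_step + 1L
      stepped <- .adam_step(weights, grad, st, config$learning_rate, t_step)
      weights <- stepped$w
      st <- stepped$st
      epoch_loss <- epoch_loss + bl
    }
    train_loss <- epoch_loss / length(train_idx)
    val_loss <- if (length(val_idx) > 0) {
      mean(vapply(val_idx, function(s) {
        fwd <- sign_invariant_forward(graphs[[s]], weights, config)
        mean((signed_log_transform(fwd$U_hat) - targets[[s]])^2)
      }, numeric(1)))
    } else NA_real_
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = train_loss,
                                         val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f", epoch, train_loss,
                      val_loss))
    if (is.finite(config$patience) && !is.na(val_loss)) {
      if (val_loss < best_val - 1e-9) {
        best_val <- val_loss
        best_weights <- weights
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$patience) break
      }
    }
  }
  if (is.finite(config$patience) && best_val < Inf) weights <- best_weights
  list(weights = weights, config = config, history = history,
       n_nodes = n_nodes)
}

#' Predict interaction parameters from a contact map
#'
#' The inference path: coarsen the 50 kb map to 100 kb, build the graph,
#' and run the sign-invariant forward pass. The returned `U_hat` at 50 kb
#' resolution can be fed directly to [sample_ensemble()].
#'
#' @param H_exp A preprocessed [contact_map()] at 50 kb with the bin count
#'   the network was trained on (the flattened-embedding distance head
#'   fixes the size).
#' @param weights Trained weights (from [train_gnn()], `$weights`).
#' @param config The matching [gnn_config()].
#' @return A `PredictionOutput` with `L_hat`, `T_hat`, `U_hat`.
#' @export
predict_params <- function(H_exp, weights, config) {
  stopifnot(inherits(H_exp, "ContactMap"))
  m <- nrow(H_exp$values)
  if (m != attr(weights, "m_out"))
    stop("map has ", m, " bins but the network was trained for ",
         attr(weights, "m_out"))
  graph <- build_graph(coarsen_2x(H_exp))
  sign_invariant_forward(graph, weights, config)
}

#' Save / load trained network weights
#'
#' Weights are serialized with `saveRDS` together with the configuration,
#' for run-time artifact storage.
#'
#' @param model Result of [train_gnn()].
#' @param path File path.
#' @return `path` (save) or the model list (load).
#' @export
save_gnn <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_gnn
#' @export
load_gnn <- function(path) readRDS(path)
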