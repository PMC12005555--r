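tiny_gnn_cfg <- function(seed = 3L, epochs = 5L) {
  gnn_config(n_message_layers = 2L, hidden_dim = 8L, n_attention_heads = 2L,
             mlp_hidden_dim = 8L, t_hidden_dim = 8L, n_epochs = epochs,
             learning_rate = 5e-3, batch_size = 4L, seed = seed)
}

tiny_graph <- function(m = 32, seed = 7) {
  build_graph(coarsen_2x(decaying_map(m, seed = seed)))
}

test_that("build_graph produces the documented (A, X, E) structure", {
  m <- 32
  H100 <- coarsen_2x(decaying_map(m, seed = 1))
  g <- build_graph(H100)
  n <- m / 2
  # strictly positive map -> complete graph
  expect_equal(g$A, matrix(1, n, n))
  # exactly 10 node-feature columns, unit-norm eigenvectors
  expect_identical(ncol(g$X), 10L)
  expect_equal(colSums(g$X^2), rep(1, 10))
  # edge features vs brute-force recomputation
  V <- H100$values / mean(diag(H100$values))
  diag(V) <- 1
  E1_oracle <- matrix(0, n, n)
  E2_oracle <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    d <- abs(i - j)
    vals <- c()
    for (a in 1:n) for (b in 1:n) if (abs(a - b) == d) vals <- c(vals, V[a, b])
    E1_oracle[i, j] <- log(V[i, j])
    E2_oracle[i, j] <- mean(vals)
  }
  expect_equal(g$E1, E1_oracle)
  expect_equal(g$E2, E2_oracle)
  # map with zeros -> those edges absent
  V0 <- decaying_map(m, seed = 2)$values
  V0[1, m] <- V0[m, 1] <- 0
  g0 <- build_graph(contact_map(V0, resolution_bp = 100000L))
  expect_true(any(g0$A == 0))
})

test_that("signed log transform closed forms, round trip, oddness", {
  expect_equal(signed_log_transform(0), 0)
  expect_equal(signed_log_transform(exp(1) - 1), 1)
  expect_equal(signed_log_transform(-(exp(1) - 1)), -1)
  set.seed(8)
  U <- matrix(stats::rnorm(100, sd = 3), 10, 10)
  expect_equal(signed_log_inverse(signed_log_transform(U)), U,
               tolerance = 1e-9)
  expect_equal(signed_log_transform(-U), -signed_log_transform(U))
})

test_that("forward pass has the documented structural properties", {
  cfg <- tiny_gnn_cfg()
  g <- tiny_graph()
  w <- init_gnn_weights(cfg, g$n, 2L * g$n)
  out <- gnn_forward(g, w, cfg)
  # output side length is twice the node count (2x upsampling)
  expect_identical(nrow(out$U_hat), 2L * g$n)
  expect_identical(out$U_hat, out$L_hat + out$T_hat)
  expect_symmetric(out$L_hat, tol = 1e-9)
  expect_equal(out$T_hat, stats::toeplitz(out$t_vals))
  # bilinear head: rank of the 100 kb L block is at most hidden_dim
  L100 <- out$L_hat[seq(1, 2 * g$n, by = 2), seq(1, 2 * g$n, by = 2)]
  sv <- svd(L100)$d
  expect_lte(sum(sv > 1e-8 * max(sv)), cfg$hidden_dim)
  # zeroed heads give a zero prediction
  w0 <- w
  w0$W_bilin[] <- 0
  w0$Wt2[] <- 0
  w0$bt2[] <- 0
  out0 <- gnn_forward(g, w0, cfg)
  expect_equal(out0$U_hat, matrix(0, 2 * g$n, 2 * g$n))
})

test_that("sign-invariant pass is exactly invariant and sums both signs", {
  cfg <- tiny_gnn_cfg()
  g <- tiny_graph()
  w <- init_gnn_weights(cfg, g$n, 2L * g$n)
  f1 <- sign_invariant_forward(g, w, cfg)
  # negating arbitrary subsets of eigenvector columns changes nothing
  for (cols in list(1L, c(2L, 5L), 1:10)) {
    g2 <- g
    g2$X[, cols] <- -g2$X[, cols]
    f2 <- sign_invariant_forward(g2, w, cfg)
    expect_identical(f1$U_hat, f2$U_hat)
  }
  # equals forward(X) + forward(-X) at the canonical orientation
  gc <- g
  gc$X <- hicstruct:::.canon_sign_cols(gc$X)
  gm <- gc
  gm$X <- -gc$X
  expect_equal(f1$U_hat,
               gnn_forward(gc, w, cfg)$U_hat + gnn_forward(gm, w, cfg)$U_hat,
               tolerance = 1e-12)
  # zero node features: both passes identical, so output is 2 x forward(0)
  gz <- g
  gz$X[] <- 0
  fz <- sign_invariant_forward(gz, w, cfg)
  expect_equal(fz$U_hat, 2 * gnn_forward(gz, w, cfg)$U_hat)
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_gnn_cfg(seed = 5)
  g <- tiny_graph(seed = 9)
  m <- 2L * g$n
  w <- init_gnn_weights(cfg, g$n, m)
  set.seed(2)
  U_t <- matrix(stats::rnorm(m * m), m, m)
  U_t <- (U_t + t(U_t)) / 2
  tgt <- signed_log_transform(U_t)
  lossfun <- function(wx) {
    mean((signed_log_transform(
      sign_invariant_forward(g, wx, cfg)$U_hat) - tgt)^2)
  }
  lg <- hicstruct:::.gnn_loss_grad(g, w, cfg, tgt)
  # align the gradient tree to the weight tree leaf order, then flatten
  align <- function(ref, tree) {
    if (!is.list(ref)) return(tree)
    keys <- if (!is.null(names(ref)) && all(names(ref) != "")) names(ref)
            else seq_along(ref)
    out <- list()
    for (k in keys) out[[length(out) + 1]] <- align(ref[[k]], tree[[k]])
    out
  }
  gflat <- unlist(align(unclass(w), lg$grad))
  wflat <- unlist(unclass(w))
  rebuild <- function(v) {
    wn <- utils::relist(v, skeleton = utils::as.relistable(unclass(w)))
    attributes(wn) <- attributes(w)
    wn
  }
  set.seed(3)
  idx <- sample(length(wflat), 30)
  eps <- 1e-6
  for (i in idx) {
    vp <- wflat; vp[i] <- vp[i] + eps
    vm <- wflat; vm[i] <- vm[i] - eps
    fd <- (lossfun(rebuild(vp)) - lossfun(rebuild(vm))) / (2 * eps)
    expect_lt(abs(fd - gflat[i]) / max(abs(fd), abs(gflat[i]), 1e-8), 1e-4)
  }
})

test_that("training overfits a small set and losses are coherent", {
  m <- 32
  pool <- build_fixture_pool(m, k = 4, n_members = 4, seed = 19)
  cfg <- quick_config(m, n_structures = 150)
  ds <- build_dataset(pool, 20, cfg, seed = 23)
  gcfg <- tiny_gnn_cfg(seed = 11, epochs = 30L)
  model <- train_gnn(ds, gcfg)
  hist <- model$history
  expect_identical(nrow(hist), 30L)
  expect_lt(hist$train_loss[30], 0.5 * hist$train_loss[1])
  # loss of a perfect prediction is zero: feed the target through the
  # loss formula directly
  U <- ds[[1]]$params$U
  expect_equal(mean((signed_log_transform(U) - signed_log_transform(U))^2), 0)
  # hand-computed toy loss on a 2x2 pair
  Uh <- matrix(c(0, exp(1) - 1, exp(1) - 1, 0), 2)
  Ut <- matrix(0, 2, 2)
  expect_equal(mean((signed_log_transform(Uh) - signed_log_transform(Ut))^2),
               mean(c(0, 1, 1, 0)))
  # determinism of training given the seed
  model2 <- train_gnn(ds, gcfg)
  expect_equal(model$weights$W_in, model2$weights$W_in, tolerance = 1e-12)
})

test_that("predict_params round-trips shape and enforces trained size", {
  m <- 32
  pool <- build_fixture_pool(m, k = 4, n_members = 3, seed = 29)
  cfg <- quick_config(m, n_structures = 120)
  ds <- build_dataset(pool, 6, cfg, seed = 31)
  model <- train_gnn(ds, tiny_gnn_cfg(seed = 13, epochs = 3L))
  pred1 <- predict_params(ds[[1]]$H, model$weights, model$config)
  pred2 <- predict_params(ds[[1]]$H, model$weights, model$config)
  # same input -> same output (tolerance only for multithreaded BLAS
  # reduction order; single-threaded runs are bitwise identical)
  expect_equal(pred1$U_hat, pred2$U_hat, tolerance = 1e-12)
  expect_identical(pred1$U_hat, pred1$L_hat + pred1$T_hat)
  expect_error(predict_params(decaying_map(64), model$weights, model$config),
               "trained")
})
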