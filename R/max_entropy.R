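# Maximum-entropy fitting of the heteropolymer interaction parameters.
# The low-rank term is parametrized as L = Psi chi Psi^T where Psi holds k
# particle-label tracks and chi is a symmetric k x k type-type interaction
# matrix; the Toeplitz term is parametrized by its per-distance diagonal
# values t_d. Both are adjusted iteratively until the simulated ensemble's
# observables match those of the target contact map.

#' Default particle labels from a target contact map
#'
#' When no experimental annotation tracks are supplied, the top-k principal
#' component score vectors of the observed/expected map are used as labels,
#' each rescaled to unit maximum magnitude. These components are the
#' standard proxy for epigenetic state (compartment signal and its
#' harmonics).
#'
#' @param H A [contact_map()] (normalized).
#' @param k Number of label tracks.
#' @return m x k matrix Psi.
#' @export
default_labels <- function(H, k = 10L) {
  Hn <- distance_normalize(H)
  C <- sweep(Hn$values, 2, colMeans(Hn$values))
  sv <- svd(C, nu = 0, nv = k)
  scores <- C %*% sv$v[, seq_len(k), drop = FALSE]
  apply(scores, 2, function(v) {
    mx <- max(abs(v))
    if (mx < 1e-12) v else v / mx
  })
}

#' Maximum-entropy observables of a contact map
#'
#' Two observable families drive the fit: type-type co-contact sums
#' `f_ab = sum_{i<j} (Psi_ia Psi_jb + Psi_ib Psi_ja) H_ij` (conjugate to
#' `chi_ab`) and per-distance diagonal means `g_d` (conjugate to `t_d`).
#'
#' @param H A [contact_map()] or plain symmetric matrix.
#' @param Psi m x k label matrix.
#' @return List with `f` (k x k symmetric) and `g` (length-m vector).
#' @export
compute_observables <- function(H, Psi) {
  V <- .map_values(H)
  Psi <- as.matrix(Psi)
  if (nrow(Psi) != nrow(V)) stop("Psi rows must match contact map bins")
  # sum_{i != j} Psi_ia H_ij Psi_jb == full quadratic form minus diagonal
  f <- crossprod(Psi, V %*% Psi) - crossprod(Psi, diag(V) * Psi)
  f <- (f + t(f)) / 2
  list(f = f, g = diag_means(V))
}

#' One maximum-entropy parameter update
#'
#' Gradient-style update with constant learning rate:
#' `chi <- chi + eta (f_sim - f_target) / N_pairs` and
#' `t_d <- t_d + eta (g_sim - g_target)`. A simulated contact excess makes
#' the corresponding parameter more positive (repulsive), which suppresses
#' the contact on the next iteration. The type-type mismatch is divided by
#' the pair count `N_pairs = m (m - 1) / 2` so both observable families
#' enter on a per-pair scale and a learning rate of order 1 is a sensible
#' default for either (the raw co-contact sums grow with m^2 and would
#' otherwise force m-dependent step sizes). The recorded residual is the
#' maximum relative parameter change `|delta| / (|param| + 1e-8)`.
#'
#' @param state An `MEState` (see [me_fit()]).
#' @param sim_obs,target_obs Observable lists from [compute_observables()].
#' @param learning_rate Step size eta.
#' @return Updated `MEState` with incremented iteration counter.
#' @export
me_update <- function(state, sim_obs, target_obs, learning_rate = 1.0) {
  m <- length(state$t_diag)
  n_pairs <- m * (m - 1) / 2
  d_chi <- learning_rate * (sim_obs$f - target_obs$f) / n_pairs
  d_t <- learning_rate * (sim_obs$g - target_obs$g)
  if (!all(is.finite(d_chi)) || !all(is.finite(d_t)))
    stop("non-finite maximum-entropy update; aborting")
  rel <- max(abs(d_chi) / (abs(state$chi) + 1e-8),
             abs(d_t) / (abs(state$t_diag) + 1e-8))
  state$chi <- state$chi + d_chi
  state$t_diag <- state$t_diag + d_t
  state$iteration <- state$iteration + 1L
  state$observable_residuals <- c(state$observable_residuals, rel)
  state$converged <- rel < state$epsilon
  state
}

me_state <- function(k, m, epsilon) {
  structure(list(iteration = 0L, chi = matrix(0, k, k),
                 t_diag = rep(0, m), observable_residuals = numeric(0),
                 converged = FALSE, epsilon = epsilon),
            class = "MEState")
}

#' Fit interaction parameters to a target contact map by maximum entropy
#'
#' Iterates simulate -> compare observables -> update until the maximum
#' relative parameter change drops below `epsilon` or `max_iter` is
#' reached. Non-convergence is reported through the `converged` flag, not
#' an error, so partial fits remain usable. Each iteration simulates with a
#' reduced sampling effort (`n_structures_opt`); callers typically follow a
#' converged fit with one full-effort simulation.
#'
#' When the learning rate overshoots (the residual increases), the step
#' size is damped by 0.5 for subsequent iterations.
#'
#' @param H_target Normalized target [contact_map()].
#' @param Psi m x k particle labels; `NULL` uses [default_labels()].
#' @param epsilon Convergence tolerance on the relative parameter change
#'   (the two conventional settings are 1e-2 and 1e-3).
#' @param poly_cfg [polymer_config()] for the per-iteration simulations.
#' @param max_iter Maximum number of simulate/update iterations.
#' @param learning_rate Initial step size eta.
#' @param n_structures_opt Structures sampled per optimization iteration.
#' @param k Number of label tracks when `Psi` is `NULL`.
#' @param verbose Print per-iteration residuals.
#' @return List with `params` (an [interaction_params()] built from the
#'   final `chi`, `t_diag`: `L = Psi chi Psi^T`, `T = toeplitz(t_diag)`),
#'   `state` (the final `MEState`), and `Psi`.
#' @export
me_fit <- function(H_target, Psi = NULL, epsilon = 1e-2, poly_cfg,
                   max_iter = 30L, learning_rate = 1.0,
                   n_structures_opt = 5000L, k = 10L, verbose = FALSE) {
  stopifnot(inherits(H_target, "ContactMap"), inherits(poly_cfg, "PolymerConfig"))
  m <- nrow(H_target$values)
  if (poly_cfg$m != m) stop("polymer config m does not match target map")
  if (is.null(Psi)) Psi <- default_labels(H_target, k = k)
  Psi <- as.matrix(Psi)
  if (nrow(Psi) != m) stop("Psi rows must match target map bins")
  k <- ncol(Psi)

  target_obs <- compute_observables(H_target, Psi)
  state <- me_state(k, m, epsilon)
  eta <- learning_rate
  opt_cfg <- poly_cfg
  opt_cfg$n_structures <- as.integer(n_structures_opt)

  for (it in seq_len(max_iter)) {
    params <- interaction_params(Psi %*% state$chi %*% t(Psi), state$t_diag)
    opt_cfg$seed <- poly_cfg$seed + it
    ens <- sample_ensemble(params, opt_cfg)
    H_sim <- contact_map_from_ensemble(ens)
    sim_obs <- compute_observables(H_sim, Psi)
    prev_res <- if (state$iteration > 0)
      state$observable_residuals[state$iteration] else Inf
    state <- me_update(state, sim_obs, target_obs, learning_rate = eta)
    res <- state$observable_residuals[state$iteration]
    if (verbose)
      message(sprintf("ME iter %d: residual %.4g (eta %.3g)", it, res, eta))
    if (res > prev_res) eta <- eta * 0.5
    if (state$converged) break
  }

  params <- interaction_params(Psi %*% state$chi %*% t(Psi), state$t_diag)
  list(params = params, state = state, Psi = Psi)
}

#' Serialize a maximum-entropy fit
#'
#' Writes `chi`, `t_diag` and `Psi` as TSV tables plus the convergence
#' history into one directory.
#'
#' @param fit Result of [me_fit()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_me_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  state <- fit$state
  utils::write.table(state$chi, file.path(dir, "chi.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  write_track_tsv(state$t_diag, file.path(dir, "t_diag.tsv"),
                  names = c("distance_bins", "t"))
  utils::write.table(fit$Psi, file.path(dir, "psi.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  hist <- data.frame(iteration = seq_along(state$observable_residuals),
                     residual = state$observable_residuals)
  utils::write.table(hist, file.path(dir, "history.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
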