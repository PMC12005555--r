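# Synthetic training data for the parameter-prediction network.
# Ground-truth interaction parameters are drawn from a pool of (L, T)
# matrices: eigenvalues of L are resampled from per-rank kernel density
# estimates over the pool, the eigenspace is borrowed from a random pool
# member, and T is taken verbatim from a random member. Simulating each
# sampled U yields (contact map, parameters) training pairs.
#
# In production the pool would hold maximum-entropy fits to experimental
# maps; build_fixture_pool() generates a synthetic stand-in pool with the
# same structure so the whole pipeline runs without external data.

#' Generate a synthetic parameter pool
#'
#' Each member is built as a maximum-entropy fit would be: label tracks
#' `Psi` are smoothed random walks (correlation length about 20 bins,
#' mimicking the megabase-scale coherence of epigenetic state), the
#' type-type matrix `chi` is symmetrized Uniform(-1, 1), and
#' `L = Psi chi Psi^T` is rescaled to unit maximum magnitude. The Toeplitz
#' diagonals decay as `t_d = -c (1 + d)^(-alpha)` with
#' `c ~ Uniform(0.3, 1)` and `alpha ~ Uniform(0.7, 1.3)`: a net attraction
#' strongest at short genomic separation, the shape required to bend an
#' ideal chain's contact scaling toward the experimental decay.
#'
#' @param m Beads per member.
#' @param k Rank of every `L` (label track count).
#' @param n_members Pool size.
#' @param seed Integer seed; the pool is a pure function of the arguments.
#' @return A `ParameterPool`: list with `L_pool`, `T_pool`, `Psi_pool`,
#'   `m`, `k`, `provenance = "fixture"`.
#' @export
build_fixture_pool <- function(m, k = 10L, n_members = 33L, seed = 1L) {
  stopifnot(m >= 2, k >= 1, n_members >= 1)
  set.seed(seed)
  smooth_walk <- function(m, span = 21L) {
    w <- stats::filter(cumsum(stats::rnorm(m + span)), rep(1 / span, span),
                       sides = 2)
    w <- w[!is.na(w)][seq_len(m)]
    w <- w - mean(w)
    s <- stats::sd(w)
    if (s < 1e-12) stats::rnorm(m) else w / s
  }
  L_pool <- vector("list", n_members)
  T_pool <- vector("list", n_members)
  Psi_pool <- vector("list", n_members)
  for (l in seq_len(n_members)) {
    Psi <- sapply(seq_len(k), function(j) smooth_walk(m))
    chi <- matrix(stats::runif(k * k, -1, 1), k, k)
    chi <- (chi + t(chi)) / 2
    L <- Psi %*% chi %*% t(Psi)
    mx <- max(abs(L))
    if (mx > 0) L <- L / mx
    cc <- stats::runif(1, 0.3, 1)
    alpha <- stats::runif(1, 0.7, 1.3)
    t_d <- -cc * (1 + 0:(m - 1))^(-alpha)
    L_pool[[l]] <- L
    T_pool[[l]] <- stats::toeplitz(t_d)
    Psi_pool[[l]] <- Psi
  }
  structure(list(L_pool = L_pool, T_pool = T_pool, Psi_pool = Psi_pool,
                 m = as.integer(m), k = as.integer(k),
                 provenance = "fixture"),
            class = "ParameterPool")
}

#' Assemble a parameter pool from maximum-entropy fits
#'
#' @param fits List of [me_fit()] results sharing m and k.
#' @return A `ParameterPool` with `provenance = "me_fits"`.
#' @export
pool_from_me_fits <- function(fits) {
  stopifnot(length(fits) >= 1)
  L_pool <- lapply(fits, function(f) f$params$L)
  T_pool <- lapply(fits, function(f) f$params$T)
  Psi_pool <- lapply(fits, function(f) f$Psi)
  structure(list(L_pool = L_pool, T_pool = T_pool, Psi_pool = Psi_pool,
                 m = nrow(L_pool[[1]]), k = ncol(Psi_pool[[1]]),
                 provenance = "me_fits"),
            class = "ParameterPool")
}

# eigendecomposition with a deterministic sign convention: eigenvectors
# ordered by decreasing |eigenvalue|, each with its largest-magnitude
# component positive
.pool_eigs <- function(L, k) {
  e <- eigen(L, symmetric = TRUE)
  ord <- order(abs(e$values), decreasing = TRUE)[seq_len(k)]
  vec <- e$vectors[, ord, drop = FALSE]
  for (j in seq_len(ncol(vec))) {
    v <- vec[, j]
    if (v[which.max(abs(v))] < 0) vec[, j] <- -v
  }
  list(values = e$values[ord], vectors = vec)
}

#' Per-rank kernel density estimates of pool eigenvalues
#'
#' For each rank r = 1..k (eigenvalues sorted by decreasing magnitude), a
#' one-dimensional Gaussian KDE is fitted over the pool members' r-th
#' eigenvalues. Sampling from rank r draws a pool eigenvalue uniformly and
#' adds Gaussian noise with the rank's bandwidth.
#'
#' @param pool A `ParameterPool`.
#' @param bandwidth Positive numeric, or `"auto"` for Silverman's rule
#'   (`stats::bw.nrd0`); a degenerate rank (single member or zero spread)
#'   falls back to a small fixed bandwidth.
#' @return An `EigenvalueKDE`: list of k components, each with `values`
#'   and `bandwidth`.
#' @export
fit_eigenvalue_kde <- function(pool, bandwidth = "auto") {
  stopifnot(inherits(pool, "ParameterPool"))
  k <- pool$k
  eigs <- sapply(pool$L_pool, function(L) .pool_eigs(L, k)$values)
  eigs <- matrix(eigs, nrow = k)  # k x n_members
  kdes <- lapply(seq_len(k), function(r) {
    v <- eigs[r, ]
    bw <- if (identical(bandwidth, "auto")) {
      if (length(v) < 2 || stats::sd(v) < 1e-12) {
        1e-3 * max(abs(v), 1)
      } else {
        stats::bw.nrd0(v)
      }
    } else bandwidth
    list(values = v, bandwidth = bw)
  })
  structure(list(kdes = kdes, k = k), class = "EigenvalueKDE")
}

#' Draw one value from a fitted eigenvalue KDE rank
#'
#' @param kde An `EigenvalueKDE`.
#' @param rank Rank index 1..k.
#' @param n Number of draws.
#' @return Numeric vector of draws from the Gaussian-kernel mixture.
#' @export
sample_kde <- function(kde, rank, n = 1L) {
  comp <- kde$kdes[[rank]]
  centers <- comp$values[sample.int(length(comp$values), n, replace = TRUE)]
  centers + stats::rnorm(n, sd = comp$bandwidth)
}

#' Sample a synthetic low-rank interaction matrix
#'
#' Draws one eigenvalue per rank from the KDE and combines them with the
#' eigenvectors of a uniformly chosen pool member:
#' `L = V diag(lambda) V^T`. The result is symmetric with rank at most k.
#'
#' @param kde An `EigenvalueKDE` fitted on `pool`.
#' @param pool The `ParameterPool`.
#' @param rng_seed Optional integer seed (`NULL` uses the current RNG
#'   stream).
#' @return m x m symmetric matrix of rank <= k.
#' @export
sample_L <- function(kde, pool, rng_seed = NULL) {
  stopifnot(inherits(kde, "EigenvalueKDE"), inherits(pool, "ParameterPool"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  member <- sample.int(length(pool$L_pool), 1)
  V <- .pool_eigs(pool$L_pool[[member]], pool$k)$vectors
  lambda <- vapply(seq_len(pool$k), function(r) sample_kde(kde, r, 1L),
                   numeric(1))
  if (!all(is.finite(lambda))) stop("non-finite sampled eigenvalues")
  L <- V %*% (lambda * t(V))
  (L + t(L)) / 2
}

#' Sample a synthetic Toeplitz interaction matrix
#'
#' A uniformly chosen pool member's `T`, returned unchanged.
#'
#' @param pool A `ParameterPool`.
#' @param rng_seed Optional integer seed.
#' @return m x m symmetric Toeplitz matrix.
#' @export
sample_T <- function(pool, rng_seed = NULL) {
  stopifnot(inherits(pool, "ParameterPool"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  pool$T_pool[[sample.int(length(pool$T_pool), 1)]]
}

#' Build a simulated training set of (contact map, parameters) pairs
#'
#' For each sample: `U = sample_L + sample_T`, the polymer model is
#' simulated, and the resulting contact probability map is paired with the
#' generating parameters. The whole set is a pure function of
#' (pool, n_samples, poly_cfg, seed).
#'
#' @param pool A `ParameterPool`.
#' @param n_samples Number of pairs.
#' @param poly_cfg [polymer_config()] used for every simulation (its seed
#'   field is overridden per sample, derived from `seed`).
#' @param seed Master seed.
#' @param kde Optional pre-fitted `EigenvalueKDE` (fitted from `pool` when
#'   `NULL`).
#' @param verbose Print progress.
#' @return List of `TrainingPair`s: each has `H` (a [contact_map()] of
#'   probabilities), `params` (an [interaction_params()]), and `seed`.
#' @export
build_dataset <- function(pool, n_samples, poly_cfg, seed = 1L, kde = NULL,
                          verbose = FALSE) {
  stopifnot(n_samples >= 1, inherits(poly_cfg, "PolymerConfig"),
            poly_cfg$m == pool$m)
  if (is.null(kde)) kde <- fit_eigenvalue_kde(pool)
  out <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    sample_seed <- (seed * 10007L + s) %% 2147483647L
    set.seed(sample_seed)
    L <- sample_L(kde, pool)
    T_mat <- sample_T(pool)
    params <- interaction_params(L, T_mat)
    cfg <- poly_cfg
    cfg$seed <- sample_seed
    ens <- sample_ensemble(params, cfg)
    H <- contact_map_from_ensemble(ens)
    out[[s]] <- structure(list(H = H, params = params, seed = sample_seed),
                          class = "TrainingPair")
    if (verbose) message(sprintf("dataset sample %d/%d", s, n_samples))
  }
  out
}

#' Save a training set to a directory archive
#'
#' One dense binary matrix file per component (H, L, T) per sample, plus a
#' `manifest.tsv` (sample id, seed, file names) and the polymer
#' configuration as JSON.
#'
#' @param dataset List of `TrainingPair`s from [build_dataset()].
#' @param dir Output directory.
#' @param poly_cfg The [polymer_config()] used to generate the set.
#' @return `dir`, invisibly.
#' @export
save_dataset <- function(dataset, dir, poly_cfg = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(dataset), function(s) {
    pair <- dataset[[s]]
    hf <- sprintf("H_%04d.bin", s)
    lf <- sprintf("L_%04d.tsv", s)
    tf <- sprintf("T_%04d.tsv", s)
    save_contact_map(pair$H, file.path(dir, hf), "dense_binary")
    utils::write.table(pair$params$L, file.path(dir, lf), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    write_track_tsv(pair$params$T[1, ], file.path(dir, tf),
                    names = c("distance_bins", "t"))
    data.frame(sample = s, seed = pair$seed, H = hf, L = lf, T = tf)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(poly_cfg))
    jsonlite::write_json(unclass(poly_cfg), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a training set saved by [save_dataset()]
#'
#' @param dir Archive directory.
#' @return List of `TrainingPair`s.
#' @export
load_dataset <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(r) {
    H <- load_contact_map(file.path(dir, manifest$H[r]), "dense_binary")
    L <- as.matrix(utils::read.table(file.path(dir, manifest$L[r])))
    tv <- utils::read.table(file.path(dir, manifest$T[r]), header = TRUE,
                            sep = "\t")$t
    structure(list(H = H,
                   params = interaction_params(unname(L), tv),
                   seed = manifest$seed[r]),
              class = "TrainingPair")
  })
}
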