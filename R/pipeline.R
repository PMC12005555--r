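# End-to-end orchestration. Two routes lead from an experimental contact
# map to a simulated ensemble: the maximum-entropy route iterates
# simulate/update until the observables match, while the network route
# predicts the interaction parameters in one shot and simulates once.
# Both archive their configuration and intermediates so every artifact is
# reproducible from config + seed.

#' Assemble a run configuration
#'
#' @param m Bin count of the maps processed in this run.
#' @param poly Named list of [polymer_config()] overrides.
#' @param gnn Named list of [gnn_config()] overrides.
#' @param me Named list of maximum-entropy settings: `epsilon`,
#'   `learning_rate`, `max_iter`, `n_structures_opt`, `k`.
#' @param metrics Named list: `h`, `K`, `kappa`.
#' @param seed Global seed.
#' @param out_dir Output directory for archived artifacts (`NULL` to skip
#'   archiving).
#' @return A `RunConfig` list.
#' @export
run_config <- function(m, poly = list(), gnn = list(), me = list(),
                       metrics = list(), seed = 1L, out_dir = NULL) {
  pc <- do.call(polymer_config, c(list(m = m, seed = seed), poly))
  gc <- do.call(gnn_config, c(list(seed = seed), gnn))
  me_def <- list(epsilon = 1e-2, learning_rate = 1.0, max_iter = 30L,
                 n_structures_opt = 5000L, k = 10L)
  me_def[names(me)] <- me
  met_def <- list(h = 5L, K = 100L, kappa = 10L)
  met_def[names(metrics)] <- metrics
  structure(list(m = as.integer(m), poly = pc, gnn = gc, me = me_def,
                 metrics = met_def, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "RunConfig")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file with any subset of the [run_config()] arguments
#'   (`m` is required).
#' @param overrides Named list applied on top of the file values.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw[names(overrides)] <- overrides
  args <- raw[intersect(names(raw),
                        c("m", "poly", "gnn", "me", "metrics", "seed",
                          "out_dir"))]
  args[c("poly", "gnn", "me", "metrics")] <-
    lapply(args[c("poly", "gnn", "me", "metrics")], as.list)
  args <- args[!vapply(args, is.null, logical(1))]
  do.call(run_config, args)
}

.archive_config <- function(cfg, dir) {
  if (is.null(dir)) return(invisible(NULL))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ser <- list(m = cfg$m, poly = unclass(cfg$poly), gnn = unclass(cfg$gnn),
              me = cfg$me, metrics = cfg$metrics, seed = cfg$seed)
  jsonlite::write_json(ser, file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

.metric_K <- function(cfg, m) min(cfg$metrics$K, m %/% 2L)

#' Maximum-entropy route: fit, final simulation, evaluation
#'
#' Fits the interaction parameters to the target map with [me_fit()], runs
#' one full-effort simulation with the converged parameters, and compares
#' the resulting simulated map against the target. Non-convergence is
#' reported in the result, not raised; the outputs are still produced.
#'
#' @param H_exp Normalized target [contact_map()].
#' @param Psi Particle labels (`NULL` for [default_labels()]).
#' @param cfg A [run_config()].
#' @param verbose Print fit progress.
#' @return List with `H_sim`, `params`, `state`, `metrics` (one-row data
#'   frame), `n_simulations` (ME iterations + 1).
#' @export
run_me_approach <- function(H_exp, Psi = NULL, cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "RunConfig"), inherits(H_exp, "ContactMap"))
  .archive_config(cfg, cfg$out_dir)
  fit <- me_fit(H_exp, Psi = Psi, epsilon = cfg$me$epsilon,
                poly_cfg = cfg$poly, max_iter = cfg$me$max_iter,
                learning_rate = cfg$me$learning_rate,
                n_structures_opt = cfg$me$n_structures_opt,
                k = cfg$me$k, verbose = verbose)
  final_cfg <- cfg$poly
  final_cfg$seed <- cfg$seed + 1000L
  ens <- sample_ensemble(fit$params, final_cfg)
  H_sim <- contact_map_from_ensemble(ens)
  mets <- evaluate_maps(H_sim, H_exp, h = cfg$metrics$h,
                        K = .metric_K(cfg, cfg$m), kappa = cfg$metrics$kappa)
  if (!is.null(cfg$out_dir)) {
    save_me_fit(fit, file.path(cfg$out_dir, "me_fit"))
    save_contact_map(H_sim, file.path(cfg$out_dir, "H_sim.tsv"))
    utils::write.table(mets, file.path(cfg$out_dir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(H_sim = H_sim, params = fit$params, state = fit$state,
       metrics = mets, n_simulations = fit$state$iteration + 1L)
}

#' Network route: predict parameters, simulate once, evaluate
#'
#' Bypasses the iterative optimization entirely: the trained network
#' predicts `U_hat` from the map and exactly one simulation is run.
#'
#' @param H_exp Normalized target [contact_map()].
#' @param model Result of [train_gnn()] (weights + config).
#' @param cfg A [run_config()].
#' @return List with `H_sim`, `prediction` (a `PredictionOutput`),
#'   `metrics`, `n_simulations` (always 1).
#' @export
run_gnn_approach <- function(H_exp, model, cfg) {
  stopifnot(inherits(cfg, "RunConfig"), inherits(H_exp, "ContactMap"))
  .archive_config(cfg, cfg$out_dir)
  pred <- predict_params(H_exp, model$weights, model$config)
  sim_cfg <- cfg$poly
  sim_cfg$seed <- cfg$seed + 2000L
  ens <- sample_ensemble(pred$U_hat, sim_cfg)
  H_sim <- contact_map_from_ensemble(ens)
  mets <- evaluate_maps(H_sim, H_exp, h = cfg$metrics$h,
                        K = .metric_K(cfg, cfg$m), kappa = cfg$metrics$kappa)
  if (!is.null(cfg$out_dir)) {
    save_contact_map(H_sim, file.path(cfg$out_dir, "H_sim_gnn.tsv"))
    utils::write.table(mets, file.path(cfg$out_dir, "metrics_gnn.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(H_sim = H_sim, prediction = pred, metrics = mets,
       n_simulations = 1L)
}

#' Generate a synthetic training set and train the network
#'
#' Fixture pool -> simulated dataset -> training; the dataset manifest,
#' loss curves and weights are archived under `cfg$out_dir` when set.
#'
#' @param cfg A [run_config()].
#' @param n_pool Fixture pool size.
#' @param n_samples Training pairs to simulate.
#' @param verbose Print progress.
#' @return List with `model` (from [train_gnn()]), `dataset`, `pool`.
#' @export
run_generate_and_train <- function(cfg, n_pool = 33L, n_samples = 100L,
                                   verbose = FALSE) {
  stopifnot(inherits(cfg, "RunConfig"))
  .archive_config(cfg, cfg$out_dir)
  pool <- build_fixture_pool(cfg$m, k = cfg$me$k, n_members = n_pool,
                             seed = cfg$seed)
  dataset <- build_dataset(pool, n_samples, cfg$poly, seed = cfg$seed,
                           verbose = verbose)
  model <- train_gnn(dataset, cfg$gnn, verbose = verbose)
  if (!is.null(cfg$out_dir)) {
    save_dataset(dataset, file.path(cfg$out_dir, "dataset"), cfg$poly)
    utils::write.table(model$history,
                       file.path(cfg$out_dir, "training_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    save_gnn(model, file.path(cfg$out_dir, "gnn_model.rds"))
  }
  list(model = model, dataset = dataset, pool = pool)
}
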