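# TICG heteropolymer simulator. Chromatin is a bead-spring chain of m
# particles (50 kb each) in a hard-walled cubic box; non-bonded
# interactions are evaluated on a cubic grid: two beads in the same grid
# cell contribute U[i, j] (in kT) to the energy. Sampling is Metropolis
# Monte Carlo; the performance-critical sweep loop lives in C++.

#' Simulation configuration for the TICG polymer model
#'
#' @param m Number of beads (one per 50 kb bin).
#' @param bond_length_nm Gaussian-chain bond length b in nm. The bonded
#'   energy is `3/(2 b^2) * sum |r_{i+1} - r_i|^2` (kT), so the equilibrium
#'   mean squared bond length is `b^2`.
#' @param volume_um3 Confinement volume V in cubic micrometres; the box is
#'   a cube of side `V^(1/3)` with hard walls.
#' @param grid_cell_nm Contact grid cell size; beads sharing a cell are in
#'   contact. Defaults to the bond length.
#' @param n_structures Number of structures to sample.
#' @param n_equilibration_sweeps Sweeps discarded before sampling.
#' @param n_sweeps_between_samples Sweeps between recorded structures.
#' @param seed Integer seed; the full ensemble is reproducible given the
#'   seed and configuration.
#' @param move_weights Probabilities of the three Monte Carlo moves:
#'   single-bead Gaussian displacement, crankshaft rotation of an internal
#'   segment, and whole-chain translation.
#' @param step_bead_nm Displacement-move standard deviation per axis.
#' @param crank_max_angle Maximum crankshaft rotation angle (radians).
#' @param step_chain_nm Whole-chain translation standard deviation.
#' @return A `PolymerConfig` list.
#' @export
polymer_config <- function(m,
                           bond_length_nm = 200,
                           volume_um3 = 8,
                           grid_cell_nm = bond_length_nm,
                           n_structures = 30000L,
                           n_equilibration_sweeps = 1000L,
                           n_sweeps_between_samples = 10L,
                           seed = 1L,
                           move_weights = c(bead = 0.8, crank = 0.15,
                                            translate = 0.05),
                           step_bead_nm = bond_length_nm / 2,
                           crank_max_angle = pi / 2,
                           step_chain_nm = bond_length_nm / 2) {
  stopifnot(m >= 2, bond_length_nm > 0, volume_um3 > 0, grid_cell_nm > 0,
            n_structures >= 1, length(move_weights) == 3,
            all(move_weights >= 0), sum(move_weights) > 0)
  structure(list(
    m = as.integer(m),
    bond_length_nm = bond_length_nm,
    volume_um3 = volume_um3,
    grid_cell_nm = grid_cell_nm,
    n_structures = as.integer(n_structures),
    n_equilibration_sweeps = as.integer(n_equilibration_sweeps),
    n_sweeps_between_samples = as.integer(n_sweeps_between_samples),
    seed = as.integer(seed),
    move_weights = move_weights / sum(move_weights),
    step_bead_nm = step_bead_nm,
    crank_max_angle = crank_max_angle,
    step_chain_nm = step_chain_nm), class = "PolymerConfig")
}

#' Interaction parameters U = L + T of the heteropolymer
#'
#' `L` is the low-rank "chromatin types" term coupling beads of similar
#' epigenetic state; `T` is the Toeplitz "ideal chromosome" term, constant
#' along descending diagonals, which reshapes the contact-probability
#' scaling. `U = L + T` is the per-pair interaction energy (kT) applied
#' when two beads co-occupy a grid cell: negative attracts, positive
#' repels.
#'
#' @param L Symmetric m x m matrix.
#' @param T_mat Symmetric Toeplitz m x m matrix (or a length-m vector of
#'   diagonal values `t_d`).
#' @return An `InteractionParams` list with fields `L`, `T`, `U`.
#' @export
interaction_params <- function(L, T_mat = NULL) {
  L <- as.matrix(L)
  m <- nrow(L)
  if (is.null(T_mat)) T_mat <- matrix(0, m, m)
  if (is.vector(T_mat)) T_mat <- stats::toeplitz(T_mat)
  stopifnot(ncol(L) == m, all(dim(T_mat) == c(m, m)))
  if (max(abs(L - t(L))) > 1e-9 * max(1, max(abs(L))))
    stop("L must be symmetric")
  tvec <- T_mat[1, ]
  if (max(abs(T_mat - stats::toeplitz(tvec))) > 1e-9 * max(1, max(abs(T_mat))))
    stop("T must be a symmetric Toeplitz matrix")
  L <- (L + t(L)) / 2
  structure(list(L = L, T = stats::toeplitz(tvec), U = L + stats::toeplitz(tvec)),
            class = "InteractionParams")
}

#' Gaussian-chain bonded energy
#'
#' @param coords m x 3 matrix of bead positions (nm).
#' @param b Bond length (nm).
#' @return Energy in kT: `3/(2 b^2) * sum_i |r_{i+1} - r_i|^2`.
#' @export
bonded_energy <- function(coords, b) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  stopifnot(nrow(coords) >= 2, ncol(coords) == 3, b > 0)
  d <- diff(coords)
  3 / (2 * b^2) * sum(d^2)
}

#' Assign beads to contact-grid cells
#'
#' Cell index per axis is `floor((r + offset) / grid_cell_nm)`; two beads
#' are in contact iff all three indices match.
#'
#' @param coords m x 3 coordinate matrix (nm).
#' @param grid_cell_nm Grid cell edge (nm).
#' @param offset Length-3 grid offset in `[0, grid_cell_nm)`.
#' @return List with `cells` (m x 3 integer matrix) and `I` (m x m 0/1
#'   contact indicator, reflexive and symmetric).
#' @export
assign_grid <- function(coords, grid_cell_nm, offset = c(0, 0, 0)) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, grid_cell_nm > 0, length(offset) == 3)
  cells <- floor(sweep(coords, 2, offset, "+") / grid_cell_nm)
  key <- paste(cells[, 1], cells[, 2], cells[, 3])
  I <- outer(key, key, "==") * 1
  list(cells = cells, I = I)
}

#' Non-bonded TICG energy of a configuration
#'
#' Sum over unordered bead pairs sharing a grid cell of `U[i, j]`
#' (self-pairs excluded; including them would only add a
#' configuration-independent constant).
#'
#' @param assignment Output of [assign_grid()].
#' @param U m x m interaction matrix (kT).
#' @return Energy in kT.
#' @export
nonbonded_energy <- function(assignment, U) {
  I <- assignment$I
  stopifnot(all(dim(U) == dim(I)), all(is.finite(U)))
  sum(U[upper.tri(U)] * I[upper.tri(I)])
}

#' Sample a structure ensemble by Metropolis Monte Carlo
#'
#' Runs the grid-based TICG sampler: after the configured equilibration,
#' structures are recorded every `n_sweeps_between_samples` sweeps. The grid
#' offset is redrawn uniformly in `[0, grid_cell)^3` at the start of every
#' sweep, restoring approximate translational invariance of the contact
#' definition; the offset in force when a structure is recorded is stored
#' with it and used for contact-map evaluation. The chain is initialized as
#' an exact Gaussian-chain draw folded into the box.
#'
#' @param params An [interaction_params()] (or a bare m x m `U` matrix).
#' @param config A [polymer_config()] with matching `m`.
#' @param check_energy_every If positive, every that many moves the
#'   incrementally tracked non-bonded energy is compared against a full
#'   recomputation (tolerance 1e-6 kT) and the maximum discrepancy is
#'   reported in the result (debug mode).
#' @return A `StructureEnsemble`: list with `coords`
#'   (n_structures x m x 3 array, nm), `offsets` (n_structures x 3 grid
#'   offsets), `config`, and `energy_check_max` (NA unless debug mode).
#' @export
sample_ensemble <- function(params, config, check_energy_every = 0L) {
  U <- if (inherits(params, "InteractionParams")) params$U else as.matrix(params)
  stopifnot(inherits(config, "PolymerConfig"), nrow(U) == config$m,
            ncol(U) == config$m)
  if (!all(is.finite(U))) stop("non-finite interaction parameters")
  set.seed(config$seed)
  box <- (config$volume_um3 * 1e9)^(1 / 3)  # um^3 -> nm^3, cube side in nm
  res <- ticg_sample(U, config$m, config$bond_length_nm, box,
                     config$grid_cell_nm, config$n_structures,
                     config$n_equilibration_sweeps,
                     config$n_sweeps_between_samples,
                     config$move_weights, config$step_bead_nm,
                     config$crank_max_angle, config$step_chain_nm,
                     as.integer(check_energy_every))
  structure(list(coords = res$coords, offsets = res$offsets,
                 config = config,
                 energy_check_max = res$energy_check_max,
                 acceptance_rate = res$acceptance_rate),
            class = "StructureEnsemble")
}

#' @export
print.StructureEnsemble <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("StructureEnsemble: %d structures x %d beads (acceptance %.2f)\n",
              d[1], d[2], x$acceptance_rate))
  invisible(x)
}

#' Simulated contact map from a structure ensemble
#'
#' The simulated contact probability `H_sim[i, j]` is the fraction of
#' structures in which beads i and j share a grid cell, each structure
#' evaluated under the grid offset in force when it was recorded. The main
#' diagonal is 1 by reflexivity of the contact indicator.
#'
#' @param ensemble A `StructureEnsemble` from [sample_ensemble()].
#' @return A [contact_map()] of contact probabilities (`is_normalized`
#'   stays `FALSE`; probabilities are already on the simulation scale).
#' @export
contact_map_from_ensemble <- function(ensemble) {
  stopifnot(inherits(ensemble, "StructureEnsemble"),
            dim(ensemble$coords)[1] >= 1)
  cfg <- ensemble$config
  H <- ticg_contact_map(ensemble$coords, ensemble$offsets, cfg$grid_cell_nm)
  contact_map(H, resolution_bp = 50000L, chrom = "sim", start_bp = 0L)
}

#' Ensemble-mean spatial distance matrix
#'
#' @param ensemble A `StructureEnsemble`.
#' @return m x m matrix; entry (i, j) is the ensemble mean of the Euclidean
#'   distance between beads i and j, in nm.
#' @export
mean_distance_matrix <- function(ensemble) {
  stopifnot(inherits(ensemble, "StructureEnsemble"),
            dim(ensemble$coords)[1] >= 1)
  ticg_mean_distance(ensemble$coords)
}

#' Export an ensemble as multi-model XYZ
#'
#' One model per frame; element symbol "C" for every bead; coordinates in
#' nm. Suitable for quick visualization in molecular viewers.
#'
#' @param ensemble A `StructureEnsemble`.
#' @param path Output file.
#' @param n_max Maximum number of frames to write.
#' @return `path`, invisibly.
#' @export
export_xyz <- function(ensemble, path, n_max = 100L) {
  stopifnot(inherits(ensemble, "StructureEnsemble"))
  n <- min(dim(ensemble$coords)[1], n_max)
  m <- dim(ensemble$coords)[2]
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seq_len(n)) {
    writeLines(c(as.character(m), sprintf("frame %d (nm)", s)), con)
    xyz <- ensemble$coords[s, , ]
    writeLines(sprintf("C %.3f %.3f %.3f", xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}
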