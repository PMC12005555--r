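# Shared fixture builders. Everything is generated in code at test time;
# no stored data files.

# multithreaded BLAS reductions are not bit-reproducible; the determinism
# tests assert exact equality, so pin to one thread
Sys.setenv(OPENBLAS_NUM_THREADS = "1", OMP_NUM_THREADS = "1")

# random dense symmetric strictly positive "raw count" map
random_raw_map <- function(m, seed = 1L, scale = 50) {
  set.seed(seed)
  V <- matrix(stats::rexp(m * m, rate = 1 / scale), m, m)
  V <- (V + t(V)) / 2 + 1
  contact_map(V)
}

# symmetric map with exponential genomic-distance decay plus noise:
# qualitatively Hi-C-like, strictly positive
decaying_map <- function(m, seed = 1L, tau = 8) {
  set.seed(seed)
  base <- exp(-abs(outer(seq_len(m), seq_len(m), "-")) / tau)
  noise <- matrix(stats::runif(m * m, 0, 0.05), m, m)
  contact_map(base + (noise + t(noise)) / 2 + 0.01)
}

# small equilibrated ensemble with U = 0 (ideal chain, huge box)
ideal_ensemble <- function(m = 16, n_structures = 50, seed = 3L) {
  cfg <- polymer_config(m, volume_um3 = 1e9, n_structures = n_structures,
                        n_equilibration_sweeps = 20,
                        n_sweeps_between_samples = 2, seed = seed)
  sample_ensemble(matrix(0, m, m), cfg)
}

# fast polymer config for desk-scale simulations
quick_config <- function(m, n_structures = 400, seed = 1L) {
  polymer_config(m, n_structures = n_structures,
                 n_equilibration_sweeps = 100,
                 n_sweeps_between_samples = 4, seed = seed)
}

expect_symmetric <- function(M, tol = 1e-9) {
  expect_lt(max(abs(M - t(M))), tol)
}
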