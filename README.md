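# hicstruct

Estimation of three-dimensional chromatin organization from Hi-C contact
maps, for computational biologists who want sampled structural ensembles —
not a single consensus structure — behind every contact map.

Hi-C measures the population-averaged contact frequency `H_ij` between
pairs of genomic loci, but not structure itself. `hicstruct` models a
25.6 Mb genomic region as a heteropolymer of `m` beads (50 kb per bead)
whose energy, in units of kT, is

    U(r) = 3/(2 b^2) * sum_i |r_{i+1} - r_i|^2  +  sum_{i<j} I(r_i, r_j) U_ij

a Gaussian chain plus a grid-based (TICG) non-bonded term: `I(r_i, r_j)`
is 1 when beads i and j occupy the same cell of a cubic grid, and
`U = L + T` is the pairwise interaction matrix — `L` a low-rank
"chromatin types" term (`L = Psi chi Psi^T`, rank 10) coupling beads of
similar epigenetic state, `T` a Toeplitz "ideal chromosome" term that
shapes the contact-probability scaling `P(s)`. Metropolis Monte Carlo
sampling of this model yields a structural ensemble whose contact map
`H_sim_ij = <I(r_i, r_j)>` can be compared to experiment.

Two routes lead from a map to parameters:

* **Maximum entropy** (`me_fit`, `run_me_approach`): iterate
  simulate → match observables → update `(chi, t_d)` until the simulated
  ensemble reproduces the target map.
* **Graph neural network** (`train_gnn`, `predict_params`,
  `run_gnn_approach`): a sign-invariant graph attention network, trained
  purely on simulated `(H, U)` pairs from the synthetic-data generator,
  predicts `U` in one shot — no iterative optimization, a single
  simulation.

Also included: Hi-C preprocessing (region extraction, the 0.1
first-off-diagonal normalization, observed/expected maps, compartment
PC1, 2x coarsening), the synthetic training-data generator (per-rank
eigenvalue KDEs over a parameter pool), and the comparison metrics used
to evaluate both routes (stratum-adjusted correlation, spectral Laplacian
score, PC1 correlation, observed/expected RMSE).

## Worked example

Simulate a two-compartment "experimental" target, then recover its
parameters from the map alone:

```r
library(hicstruct)

# 1. a synthetic target: the polymer model with known parameters
m <- 64
blocks <- rep(c(1, -1), each = m / 2)            # A/B compartment labels
L <- -0.6 * outer(blocks, blocks)                # like attracts like
t_d <- -0.5 * (1 + 0:(m - 1))^-1                 # ideal-chromosome decay
params <- interaction_params(L, t_d)
cfg <- polymer_config(m, n_structures = 2000, n_equilibration_sweeps = 300,
                      n_sweeps_between_samples = 5, seed = 1)
H_target <- contact_map_from_ensemble(sample_ensemble(params, cfg))

# 2. recover the parameters by maximum entropy
run <- run_config(m, poly = list(n_structures = 2000,
                                 n_equilibration_sweeps = 300,
                                 n_sweeps_between_samples = 5),
                  me = list(max_iter = 40L, n_structures_opt = 1500L),
                  metrics = list(K = 32L), seed = 7)
res <- run_me_approach(H_target, cfg = run)
cat(sprintf("converged: %s after %d iterations\n",
            res$state$converged, res$state$iteration))
print(round(res$metrics[, 1:4], 3))

# 3. compartment signal of target vs fit
pc_t <- compartment_pc1(distance_normalize(H_target))
pc_s <- compartment_pc1(distance_normalize(res$H_sim))
cat(sprintf("PC1 block separation reproduced: cor = %.3f\n", cor(pc_t, pc_s)))
```

Output:

```
converged: TRUE after 29 iterations
    scc hic_spector corr_pc1 rmse_norm
1 0.987       0.465    0.976     0.717
PC1 block separation reproduced: cor = 0.976
```

The fit converged (maximum relative parameter change below the 1e-2
tolerance) in 29 simulate/update iterations. The stratum-adjusted
correlation of 0.99 between the refitted and target maps means the
distance-stratified contact structure is recovered almost exactly, and
the PC1 correlation of 0.98 says the A/B compartment pattern — the
plaid — is reproduced; the residuals reflect Monte Carlo noise at this
modest sampling effort (2000 structures; production runs use 30,000).

A command-line surface wraps the same pipeline:

```sh
Rscript -e 'hicstruct::cli_main()' preprocess chrom.tsv --out regions/
Rscript -e 'hicstruct::cli_main()' me-fit regions/region_001.tsv --out fit/
Rscript -e 'hicstruct::cli_main()' gen-data --m 64 --n-samples 128 --out data/
Rscript -e 'hicstruct::cli_main()' train data/ --out model/
Rscript -e 'hicstruct::cli_main()' predict map.tsv --model model/gnn_model.rds --out pred/
Rscript -e 'hicstruct::cli_main()' evaluate map1.tsv map2.tsv --out metrics.tsv
```

## Layout

* `R/` — preprocessing, simulator surface, maximum entropy, synthetic
  data, network, metrics, pipeline + CLI
* `src/ticg.cpp` — the Monte Carlo core (grid-hashed incremental
  energies; bead, crankshaft, and chain-translation moves)
* `vignettes/hicstruct-methods.Rmd` — model assumptions, parameter
  choices, numerical decisions, limitations
* `tests/testthat/` — unit, property, and acceptance tiers
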