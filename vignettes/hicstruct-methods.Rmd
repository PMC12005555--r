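---
title: "hicstruct: model, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hicstruct: model, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the polymer model and its assumptions, the two parameter-estimation
routes, what the synthetic-data generator does and does not emulate, and
the numerical decisions taken where the design was genuinely open. It
states no empirical result that the test suite or the acceptance script
does not itself compute.

## The chromatin model

A 25.6 Mb genomic region at 50 kb resolution is a chain of `m = 512`
beads (desk-scale tests use `m = 64`). The potential energy, in units of
kT, is

$$U(\mathbf r) \;=\; \frac{3}{2b^2}\sum_{i=1}^{m-1}|\mathbf r_{i+1}-\mathbf r_i|^2
\;+\; \sum_{i<j} I(\mathbf r_i,\mathbf r_j)\,U_{ij},$$

a Gaussian-chain bonded term plus a grid-based non-bonded term in the
TICG (theoretically informed coarse-grained) style: instead of a
distance-dependent pair potential, space is partitioned into cubic cells
and $I=1$ exactly when two beads co-occupy a cell. This makes the energy
of a move updatable in O(cell occupancy) and is what makes million-move
Monte Carlo runs cheap.

The interaction matrix decomposes as $U = L + T$:

* $L = \Psi\chi\Psi^{\mathsf T}$ — rank-`k` (default 10) "chromatin
  types" term. $\Psi$ holds per-bead label tracks (epigenetic state
  proxies), $\chi$ the symmetric type–type interaction strengths.
  Negative entries attract: like-labelled beads clustering is what
  produces A/B compartmentalization, the plaid pattern of Hi-C maps.
* $T$ — symmetric Toeplitz "ideal chromosome" term: all pairs at genomic
  distance $d=|i-j|$ share the value $t_d$. It reshapes the
  contact-probability scaling $P(s)$ away from the ideal-chain decay.

**Assumptions.** Temperature is absorbed into the energy scale (all
parameters in kT). Self-pairs are excluded from the non-bonded sum; with
the grid indicator they would only add a configuration-independent
constant. Confinement is a hard-walled cube of side $V^{1/3}$ (default
$V = 8\,\mu m^3$, i.e. a 2 μm box); the model has no loop extrusion, no
nucleosome-scale detail, and Monte Carlo is used for sampling only — no
kinetic claims.

## Sampling

Metropolis Monte Carlo with three move types — single-bead Gaussian
displacement, crankshaft rotation of an internal segment (bonded energy
invariant), and whole-chain translation (non-bonded energy changes
because the grid is fixed in space) — with weights 0.8/0.15/0.05 and
step sizes near 50% acceptance at the defaults. The grid offset is
redrawn uniformly in $[0,\text{cell})^3$ at every sweep, restoring
approximate translational invariance of the contact definition; the
offset in force when a structure is recorded travels with it and is used
for contact-map evaluation, so $H^{sim}_{ij}$ is the fraction of recorded
structures in which beads $i,j$ share a cell under the recording-time
grid.

Parameters that matter, with defaults and why:

| parameter | default | meaning |
|---|---|---|
| `bond_length_nm` (b) | 200 nm | sets the distance scale; equilibrium mean squared bond length is $b^2$ |
| `volume_um3` (V) | 8 μm³ | confinement; with b chosen so simulated distance scaling matches imaging data |
| `grid_cell_nm` | b | contact radius at the bond scale |
| `n_structures` | 30000 | ensemble size for production contact maps |
| equilibration / spacing | 1000 / 10 sweeps | decorrelation at desk scale; chain initialized from an exact Gaussian draw so U = 0 starts in equilibrium |

The incremental non-bonded bookkeeping is checked against full
recomputation (`check_energy_every`), asserted to 1e-6 kT in the suite.
Correctness anchors: with $U=0$ in an effectively unconfined box the
sampler reproduces $\langle|\mathbf r_{i+s}-\mathbf r_i|^2\rangle = s b^2$
within three batch-mean standard errors (the acceptance tier checks
$s\in\{1,4,16\}$ at $m=64$, 2000 structures), and a single strongly
attractive distant pair measurably raises its contact probability
against a matched-seed control.

## Maximum-entropy fitting

Given a normalized target map and labels $\Psi$ (defaults: top-k PCs of
the observed/expected map, rescaled to unit maximum), the fit iterates
simulate → observables → update. Observables are the type–type
co-contact sums $f_{ab}=\sum_{i<j}(\Psi_{ia}\Psi_{jb}+\Psi_{ib}\Psi_{ja})H_{ij}$
and per-distance diagonal means $g_d$; updates are

$$\chi \mathrel{+}= \eta\,(f^{sim}-f^{tgt})/N_{pairs},\qquad
t_d \mathrel{+}= \eta\,(g^{sim}_d-g^{tgt}_d),$$

with $\eta = 1$ and halving of $\eta$ whenever the residual increases.
**Design note:** the $\chi$ gradient is divided by
$N_{pairs}=m(m-1)/2$. The raw co-contact sums grow with $m^2$, so a
fixed $\eta$ on raw sums would need retuning with every $m$ and at
$\eta=1,\ m=64$ produced multi-kT oscillations of $\chi$; per-pair
scaling puts both observable families on the same footing and makes
$\eta=1$ a sensible default. The convergence residual is the maximum
relative parameter change $|\Delta\theta|/(|\theta|+10^{-8})$, compared
against $\epsilon$ (conventional values $10^{-2}$, $10^{-3}$).
Convergence is a flag, not an exception — maximum-entropy fits
occasionally fail to converge and the partial fit is still returned.
Sampling effort is reduced during optimization (`n_structures_opt`,
default 5000) with a full-effort final simulation in the pipeline route.

## Synthetic training data

The generator stands in for a pool of maximum-entropy fits to
experimental maps, so every stage is testable offline. Each fixture pool
member draws $\Psi$ as smoothed random walks (correlation length ~20
bins — megabase-scale coherence of epigenetic state), $\chi$ symmetric
Uniform(−1, 1), rescales $L$ to unit maximum magnitude, and sets
$t_d = -c\,(1+d)^{-\alpha}$ with $c\sim U(0.3,1)$,
$\alpha\sim U(0.7,1.3)$ — a net short-range attraction whose strength
and decay vary across members the way fitted ideal-chromosome terms do.

Sampling a training parameter set follows the estimated-distribution
recipe: per-rank Gaussian-kernel KDEs over the pool's $L$ eigenvalues
(rank-1 eigenvalues pooled together, etc., preserving the spectral
shape; Silverman's-rule bandwidth), eigenvectors borrowed from a random
pool member (deterministic sign convention: largest-magnitude component
positive), $T$ taken verbatim from a random member. Simulating each
$U^{(s)}=L^{(s)}+T^{(s)}$ yields the $(H^{(s)},U^{(s)})$ pairs.

**What a green test does and does not establish.** The fixture world
reproduces the *structure* of the real training distribution (rank,
Toeplitz decay, smooth labels, simulated maps) but not its empirical
parameter values, which would require experimental Hi-C and full
maximum-entropy runs. Passing the network-sanity criterion shows the
architecture can learn the map→parameter inverse on this family; it does
not certify accuracy on experimental chromatin.

## The network

Input is the 100 kb coarsening of the 50 kb map (2×2 block sums), then:
normalize by the main-diagonal mean, overwrite the diagonal with 1,
adjacency $A_{ij}=\mathbb 1[H^{100kb}_{ij}>0]$ (near-complete in
practice), node features the top-10 eigenvectors of the
observed/expected map, edge features
$[\log H_{ij},\ \text{diag-mean}_{|i-j|}]$.

Architecture: linear embedding → `n_message_layers` blocks of dynamic
(GATv2-style) attention + residual MLP → latent $Z$. Two decoding heads:
$\hat L_{100} = Z W Z^{\mathsf T}$ with $W$ symmetrized at use, upsampled
2× by nearest-neighbour replication to 50 kb; and an MLP on the
flattened $Z$ emitting the $m$ Toeplitz diagonal values of $\hat T$.
$\hat U = \hat L + \hat T$ exactly, by construction.

Open design points, resolved as follows:

* **Edge features in messages.** Edge features enter the attention
  logits *and* the aggregated message
  ($\sum_j \alpha_{ij}(W_v x_j + W_{ev} e_{ij})$). With logits-only edge
  features the scaling-curve magnitudes cannot reach $Z$ (attention
  weights are normalized away), and the distance head demonstrably fails
  to recover $T$; the message path fixes this.
* **Sign invariance.** Eigenvector features have arbitrary sign per
  column. Each column is first canonicalized (largest-|entry| positive),
  giving exact invariance to any subset of column flips; the whole
  network is then run on $+X$ and $-X$ and the two predictions summed,
  so neither global orientation is privileged. The invariance is exact
  (tested with `expect_identical`).
* **Fixed m at inference.** The flattened-$Z$ distance head ties a
  trained model to one region size; maps of other sizes are rejected
  with a clear error.
* **Training.** Loss is the MSE between signed-log transforms
  $U^\dagger=\mathrm{sign}(U)\ln(|U|+1)$ of prediction and truth
  (compresses the dynamic range symmetrically; the transform is odd and
  exactly invertible). Adam at 1e-3–2e-3, minibatch 8, 90/10
  train/validation split after a seeded shuffle, optional early
  stopping. Forward and backward passes are hand-written (no autodiff
  framework in this stack); the backward pass is verified against
  central finite differences to 1e-4 relative error in the suite.

## Metrics

* **SCC** — distance-stratified Pearson correlations combined with
  HiCRep-style weights $w_d = N_d\,\mathrm{sd}(\mathrm{rank}(x)/N_d)\,
  \mathrm{sd}(\mathrm{rank}(y)/N_d)$ after a $(2h+1)^2$ mean filter
  (defaults h = 5, K = 100 bins; zero-variance strata skipped).
* **Spectral score** — symmetric normalized Laplacians (self-loops
  dropped), $\kappa=10$ smallest nontrivial eigenvectors, per-pair sign
  alignment, score $1-\frac{1}{\kappa}\sum\|v_i-u_i\|/\sqrt 2 \in [0,1]$;
  isolated bins are dropped with a warning.
* **PC1 correlation** — compartment tracks correlated after sign
  alignment (PC1 sign is arbitrary, so the reported value is
  non-negative). PC1 itself is computed on the Pearson-correlation
  transform of the observed/expected map (zero-variance bins zeroed),
  as the first right singular vector of the column-centered correlation
  matrix scaled by its singular value, sign fixed by the
  largest-magnitude entry; a degenerate (constant) map returns a zero
  vector with a warning. The correlation pre-transform is essential for
  sharply compartmentalized maps, where the raw observed/expected
  spectrum is near-degenerate and its PC1 rotates into within-block
  variance.
* **RMSE** of observed/expected maps, and upper-triangle Pearson for
  mean spatial distance matrices.

## Numerical choices and degenerate inputs

* Observed/expected division maps zero-mean diagonals to 0 (not NaN) so
  eigendecompositions stay defined.
* `normalize_map` requires a positive first off-diagonal mean; region
  extraction discards windows with any zero main-diagonal entry
  (centromeres/telomeres/unmappable bins) and the trailing partial
  window, tiling from position 0.
* Coarsening sums (not averages) 2×2 blocks, preserving count semantics
  and conserving total mass exactly.
* Asymmetry up to 1e-6 relative is averaged away at load; beyond that it
  is an error.
* Crankshaft moves with coincident endpoints and moves leaving the box
  are rejected; the non-bonded energy is tracked incrementally and
  cross-checked in debug mode.
* All randomness flows through R's RNG (the C++ core uses the R API), so
  every ensemble, dataset, fit, and training run is reproducible from
  its seed; multithreaded BLAS can perturb the last ulp of network
  outputs, which is why two determinism tests use 1e-12/1e-9 tolerances
  rather than bitwise equality.

## Known limitations

* The maximum-entropy update is first-order with damping; no
  second-order (Newton) acceleration.
* The fixture pool's parameter distributions are plausible, not
  empirical; cross-cell-line transfer claims cannot be assessed offline.
* Labels $\Psi$ from real epigenetic tracks are out of scope (the
  default is PCA-derived).
* Matrix balancing (ICE/Knight–Ruiz), read-level processing,
  inter-chromosomal maps, and multi-resolution container input are not
  implemented; dense text/binary matrices are the interchange format.
* Wall-clock comparisons between the two routes are hardware-dependent
  and deliberately unreported; the structural claim — the network route
  performs exactly one sampling stage versus iterations + 1 — is what
  the suite asserts.
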