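test_that("bonded_energy matches the Gaussian-chain closed form", {
  b <- 200
  coords <- matrix(0, 3, 3)
  expect_equal(bonded_energy(coords, b), 0)
  # two beads one bond length apart: 3/(2 b^2) * b^2 = 1.5
  coords <- rbind(c(0, 0, 0), c(b, 0, 0))
  expect_equal(bonded_energy(coords, b), 1.5)
  # homogeneity: doubling coordinates quadruples the energy
  set.seed(1)
  coords <- matrix(stats::rnorm(12, sd = 100), 4, 3)
  expect_equal(bonded_energy(2 * coords, b), 4 * bonded_energy(coords, b))
  expect_error(bonded_energy(matrix(c(1, NA, 0, 0, 0, 0), 2), b),
               "non-finite")
})

test_that("assign_grid implements the offset floor rule", {
  g <- 100
  # two beads 0.1 cells apart in a cell interior: same cell
  coords <- rbind(c(25, 25, 25), c(35, 25, 25))
  expect_equal(assign_grid(coords, g)$I, matrix(1, 2, 2))
  # beads straddling a boundary: split at offset 0, joined at half-cell
  coords <- rbind(c(95, 50, 50), c(105, 50, 50))
  expect_equal(assign_grid(coords, g, offset = c(0, 0, 0))$I[1, 2], 0)
  expect_equal(assign_grid(coords, g, offset = c(50, 0, 0))$I[1, 2], 1)
  # direct floor computation oracle on random coordinates
  set.seed(2)
  coords <- matrix(stats::runif(30, 0, 1000), 10, 3)
  off <- stats::runif(3, 0, g)
  I <- assign_grid(coords, g, off)$I
  oracle <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    oracle[i, j] <- as.numeric(all(floor((coords[i, ] + off) / g) ==
                                     floor((coords[j, ] + off) / g)))
  }
  expect_identical(I, oracle)
  expect_symmetric(I)
  expect_true(all(diag(I) == 1))
})

test_that("nonbonded_energy equals the pair enumeration oracle", {
  g <- 100
  coords <- rbind(c(10, 10, 10), c(20, 10, 10), c(500, 500, 500))
  asg <- assign_grid(coords, g)
  U <- matrix(0, 3, 3)
  expect_equal(nonbonded_energy(asg, U), 0)
  U[1, 2] <- U[2, 1] <- -1
  expect_equal(nonbonded_energy(asg, U), -1)
  # random configurations vs O(m^2) double loop
  set.seed(3)
  for (trial in 1:5) {
    coords <- matrix(stats::runif(24, 0, 400), 8, 3)
    U <- matrix(stats::rnorm(64), 8, 8)
    U <- (U + t(U)) / 2
    asg <- assign_grid(coords, g)
    oracle <- 0
    for (i in 1:7) for (j in (i + 1):8) {
      if (asg$I[i, j] == 1) oracle <- oracle + U[i, j]
    }
    expect_equal(nonbonded_energy(asg, U), oracle)
  }
})

test_that("sampling is deterministic given seed and config", {
  cfg <- quick_config(12, n_structures = 20, seed = 77)
  U <- matrix(0, 12, 12)
  e1 <- sample_ensemble(U, cfg)
  e2 <- sample_ensemble(U, cfg)
  expect_identical(e1$coords, e2$coords)
  expect_identical(e1$offsets, e2$offsets)
  cfg2 <- cfg
  cfg2$seed <- 78L
  e3 <- sample_ensemble(U, cfg2)
  expect_false(identical(e1$coords, e3$coords))
})

test_that("incremental energy bookkeeping matches full recomputation", {
  set.seed(5)
  m <- 24
  L <- matrix(stats::rnorm(m * m, sd = 0.3), m, m)
  params <- interaction_params((L + t(L)) / 2,
                               -0.5 * (1 + 0:(m - 1))^-1)
  cfg <- quick_config(m, n_structures = 50, seed = 9)
  ens <- sample_ensemble(params, cfg, check_energy_every = 500L)
  expect_lt(ens$energy_check_max, 1e-6)
})

test_that("U = 0 sampling reproduces ideal-chain bond statistics", {
  m <- 32
  cfg <- polymer_config(m, volume_um3 = 1e9, n_structures = 400,
                        n_equilibration_sweeps = 50,
                        n_sweeps_between_samples = 2, seed = 21)
  ens <- sample_ensemble(matrix(0, m, m), cfg)
  b2 <- cfg$bond_length_nm^2
  # per-structure mean squared bond length; batch-mean standard error
  per <- rowMeans(sapply(1:(m - 1), function(i) {
    rowSums((ens$coords[, i + 1, ] - ens$coords[, i, ])^2)
  }))
  nb <- 20
  bm <- tapply(per, rep(seq_len(nb), each = length(per) / nb), mean)
  se <- stats::sd(bm) / sqrt(nb)
  expect_lt(abs(mean(per) - b2), 3 * se)
})

test_that("contact map and distance matrix match counting oracles", {
  ens <- ideal_ensemble(m = 10, n_structures = 30, seed = 6)
  H <- contact_map_from_ensemble(ens)
  expect_true(all(diag(H$values) == 1))
  expect_true(all(H$values >= 0 & H$values <= 1))
  expect_symmetric(H$values)
  # counting oracle via assign_grid per structure
  g <- ens$config$grid_cell_nm
  n <- dim(ens$coords)[1]
  counts <- matrix(0, 10, 10)
  for (s in seq_len(n)) {
    counts <- counts + assign_grid(ens$coords[s, , ], g, ens$offsets[s, ])$I
  }
  oracle <- counts / n
  diag(oracle) <- 1
  expect_equal(H$values, oracle)

  D <- mean_distance_matrix(ens)
  # brute-force loop oracle
  oracle_d <- matrix(0, 10, 10)
  for (s in seq_len(n)) {
    for (i in 1:10) for (j in 1:10) {
      oracle_d[i, j] <- oracle_d[i, j] +
        sqrt(sum((ens$coords[s, i, ] - ens$coords[s, j, ])^2))
    }
  }
  expect_equal(D, oracle_d / n, tolerance = 1e-9)

  # 2-bead 2-structure hand case
  ens2 <- ens
  ens2$coords <- array(0, c(2, 2, 3))
  ens2$coords[1, 2, 1] <- 1
  ens2$coords[2, 2, 1] <- 3
  expect_equal(mean_distance_matrix(ens2)[1, 2], 2)
})

test_that("a strong attraction raises the pair's contact probability", {
  m <- 40
  cfg <- quick_config(m, n_structures = 600, seed = 31)
  H0 <- contact_map_from_ensemble(sample_ensemble(matrix(0, m, m), cfg))
  U <- matrix(0, m, m)
  U[5, 35] <- U[35, 5] <- -6
  H1 <- contact_map_from_ensemble(sample_ensemble(U, cfg))
  expect_gt(H1$values[5, 35], H0$values[5, 35])
})

test_that("two-block attraction pattern produces a plaid compartment map", {
  m <- 48
  blocks <- rep(c(1, -1), each = m / 2)
  L <- -0.7 * outer(blocks, blocks)   # intra-block negative, inter positive
  params <- interaction_params(L, -0.3 * (1 + 0:(m - 1))^-1)
  cfg <- quick_config(m, n_structures = 800, seed = 41)
  H <- contact_map_from_ensemble(sample_ensemble(params, cfg))
  pc1 <- compartment_pc1(distance_normalize(H))
  agree <- sign(pc1) == sign(pc1[1])
  frac <- max(mean(agree[blocks == 1]), mean(agree[blocks == -1]))
  other <- min(mean(agree[blocks == 1]), mean(agree[blocks == -1]))
  expect_gt(frac, 0.9)   # one block dominated by one PC1 sign
  expect_lt(other, 0.1)  # the other block takes the opposite sign
})

test_that("XYZ export writes one model per frame", {
  ens <- ideal_ensemble(m = 5, n_structures = 4)
  f <- withr::local_tempfile(fileext = ".xyz")
  export_xyz(ens, f, n_max = 3)
  lines <- readLines(f)
  expect_length(lines, 3 * (5 + 2))
  expect_identical(lines[1], "5")
})
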