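test_that("contact_map validates and symmetrizes", {
  H <- contact_map(matrix(c(4, 2, 1, 2, 4, 2, 1, 2, 4), 3))
  expect_s3_class(H, "ContactMap")
  expect_identical(dim(H), c(3L, 3L))

  expect_error(contact_map(matrix(1, 2, 3)), "square")
  M <- matrix(c(1, -0.5, -0.5, 1), 2)
  expect_error(contact_map(M), "non-negative")
  # mild asymmetry averaged away, large asymmetry rejected
  M <- matrix(c(1, 2, 2 + 1e-8, 1), 2)
  expect_equal(contact_map(M)$values[1, 2], 2 + 5e-9)
  M <- matrix(c(1, 2, 3, 1), 2)
  expect_error(contact_map(M), "asymmetry")
})

test_that("dense text and binary round-trips are bit exact", {
  H <- random_raw_map(17, seed = 4)
  txt <- withr::local_tempfile(fileext = ".tsv")
  bin <- withr::local_tempfile(fileext = ".bin")
  save_contact_map(H, txt, "dense_text")
  save_contact_map(H, bin, "dense_binary")
  # text round-trip (write.table prints full precision via default 15 sig
  # digits; binary must be bitwise)
  Ht <- load_contact_map(txt, "dense_text")
  expect_equal(Ht$values, H$values, tolerance = 1e-12)
  Hb <- load_contact_map(bin, "dense_binary")
  expect_identical(Hb$values, H$values)
  expect_identical(Hb$resolution_bp, H$resolution_bp)
  expect_identical(Hb$chrom, H$chrom)

  expect_error(load_contact_map(txt, "hic_container"), "dense_text")
  expect_error(load_contact_map("/nonexistent/x.tsv", "dense_text"),
               "no such file")
})

test_that("extract_regions tiles, filters zero diagonals, drops partials", {
  # 25.6 Mb at 50 kb -> 512 bins per region
  expect_identical(as.integer(25.6e6 / 50000), 512L)

  # synthetic 1200-bin chromosome, zero diagonal at bin 600
  m <- 1200
  d <- rep(1, m)
  d[600] <- 0
  V <- diag(d)
  V[1, 2] <- V[2, 1] <- 0.5
  Hc <- contact_map(V)
  w <- 512L
  regions <- extract_regions(Hc, region_mb = 25.6)
  # direct scan oracle
  expected_starts <- c()
  for (s in seq(1L, m - w + 1L, by = w)) {
    if (all(d[s:(s + w - 1L)] > 0)) expected_starts <- c(expected_starts, s)
  }
  expect_length(regions, length(expected_starts))
  expect_identical(vapply(regions, function(r) r$start_bp, integer(1)),
                   as.integer((expected_starts - 1L) * 50000L))
  # bin 600 is inside window 2 (513..1024): that window must be absent
  expect_false(any(vapply(regions, function(r) r$start_bp, integer(1)) ==
                     512L * 50000L))

  # map exactly one region long with positive diagonal -> itself
  H1 <- decaying_map(512, seed = 2)
  out <- extract_regions(H1)
  expect_length(out, 1)
  expect_identical(out[[1]]$values, H1$values)

  # chromosome shorter than a region -> empty list, no error
  expect_length(extract_regions(decaying_map(100)), 0)
})

test_that("normalize_map hits the 0.1 first-off-diagonal convention", {
  H <- contact_map(matrix(c(4, 2, 1, 2, 4, 2, 1, 2, 4), 3))
  Hn <- normalize_map(H)
  # hand computation: scale 0.1 / 2
  expect_equal(Hn$values,
               matrix(c(1, 0.1, 0.05, 0.1, 1, 0.1, 0.05, 0.1, 1), 3))
  expect_true(Hn$is_normalized)

  H2 <- random_raw_map(40, seed = 9)
  Hn2 <- normalize_map(H2)
  i <- 1:39
  expect_equal(mean(Hn2$values[cbind(i, i + 1)]), 0.1, tolerance = 1e-12)
  expect_true(all(diag(Hn2$values) == 1))
  # idempotent
  expect_equal(normalize_map(Hn2)$values, Hn2$values, tolerance = 1e-12)

  expect_error(normalize_map(contact_map(diag(3))), "off-diagonal")
})

test_that("distance_normalize divides by diagonal means", {
  M <- matrix(c(1, 0.5, 0.2, 0.5, 1, 0.3, 0.2, 0.3, 1), 3)
  Hn <- distance_normalize(contact_map(M))
  expect_equal(Hn$values,
               matrix(c(1, 1.25, 1, 1.25, 1, 0.75, 1, 0.75, 1), 3))
  # Toeplitz input -> ones on nonzero diagonals
  Tm <- stats::toeplitz(c(1, 0.5, 0.25, 0.1))
  expect_equal(distance_normalize(Tm)$values, matrix(1, 4, 4))
  # output diagonal means all 1 (or 0 for zero diagonals), any input
  H <- random_raw_map(30, seed = 5)
  dm <- hicstruct:::diag_means(distance_normalize(H)$values)
  expect_equal(dm, rep(1, 30), tolerance = 1e-9)
  # zero diagonal stays zero
  V <- diag(4)
  out <- distance_normalize(V)
  expect_equal(out$values[1, 3], 0)
})

test_that("compartment_pc1 separates a two-block checkerboard", {
  m <- 24
  blocks <- rep(c(1, -1), each = m / 2)
  V <- 0.5 + 0.3 * outer(blocks, blocks)
  pc1 <- compartment_pc1(distance_normalize(contact_map(V)))
  # brute-force oracle: eigendecomposition of the centered covariance
  expect_true(all(sign(pc1[1:12]) == sign(pc1[1])))
  expect_true(all(sign(pc1[13:24]) == -sign(pc1[1])))
  # sign convention: largest-magnitude entry positive
  expect_gt(pc1[which.max(abs(pc1))], 0)
  # scale equivariance up to parallel direction
  H <- decaying_map(30, seed = 7)
  Hn <- distance_normalize(H)
  p1 <- compartment_pc1(Hn)
  p2 <- compartment_pc1(list(values = 2 * Hn$values))
  expect_gt(abs(stats::cor(p1, p2)), 1 - 1e-9)
  # degenerate constant map -> zeros with warning
  expect_warning(z <- compartment_pc1(matrix(1, 5, 5)), "degenerate")
  expect_identical(z, rep(0, 5))
})

test_that("coarsen_2x sums 2x2 blocks and conserves mass", {
  H4 <- contact_map(matrix(1, 4, 4))
  H2 <- coarsen_2x(H4)
  expect_equal(H2$values, matrix(4, 2, 2))
  expect_identical(H2$resolution_bp, 100000L)

  H <- random_raw_map(16, seed = 11)
  Hc <- coarsen_2x(H)
  expect_equal(sum(Hc$values), sum(H$values))
  # naive double-loop oracle
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    oracle[i, j] <- sum(H$values[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  }
  expect_equal(Hc$values, oracle)
  expect_error(coarsen_2x(decaying_map(5)), "even")
})

test_that("contact_scaling equals per-diagonal means", {
  expect_equal(contact_scaling(contact_map(diag(4))), c(1, 0, 0, 0))
  Tm <- stats::toeplitz(c(1, 0.5, 0.25))
  expect_equal(contact_scaling(contact_map(Tm)), c(1, 0.5, 0.25))
  H <- random_raw_map(12, seed = 13)
  oracle <- sapply(0:11, function(d) {
    vals <- c()
    for (i in 1:12) for (j in 1:12) if (j - i == d) vals <- c(vals, H$values[i, j])
    mean(vals)
  })
  expect_equal(contact_scaling(H), oracle)
})

test_that("track TSV writer emits two columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_track_tsv(c(0.1, 0.2, 0.3), f)
  df <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_identical(colnames(df), c("index", "value"))
  expect_equal(df$value, c(0.1, 0.2, 0.3))
})
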