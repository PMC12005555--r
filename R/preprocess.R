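# Preprocessing of Hi-C contact maps: region extraction, the two
# normalization conventions (off-diagonal scale and per-diagonal
# observed/expected), compartment PC1, scaling curves, and the 2x
# coarsening used by the graph neural network.

#' Mean of each descending diagonal of a square matrix
#'
#' @param M Square matrix.
#' @return Numeric vector `v` of length `nrow(M)`; `v[d + 1]` is the mean of
#'   entries with `|i - j| == d`.
#' @keywords internal
diag_means <- function(M) {
  m <- nrow(M)
  vapply(0:(m - 1), function(d) {
    i <- seq_len(m - d)
    mean(M[cbind(i, i + d)])
  }, numeric(1))
}

#' Split a chromosome-scale map into fixed-size regions
#'
#' Tiles the map with consecutive non-overlapping windows of
#' `region_mb` megabases starting at the first bin (25.6 Mb is 512 bins at
#' 50 kb). Windows containing any zero main-diagonal entry — centromeres,
#' telomeres, unmappable bins — are discarded, as is a trailing partial
#' window.
#'
#' @param chrom_map A [contact_map()] covering (part of) a chromosome.
#' @param region_mb Window size in Mb.
#' @return List of `ContactMap` regions (possibly empty).
#' @export
extract_regions <- function(chrom_map, region_mb = 25.6) {
  stopifnot(inherits(chrom_map, "ContactMap"))
  res <- chrom_map$resolution_bp
  w <- as.integer(round(region_mb * 1e6 / res))
  if (w < 1) stop("region smaller than one bin")
  m <- nrow(chrom_map$values)
  if (m < w) return(list())
  d <- diag(chrom_map$values)
  out <- list()
  for (s in seq(1L, m - w + 1L, by = w)) {
    idx <- s:(s + w - 1L)
    if (all(d[idx] > 0)) {
      out[[length(out) + 1L]] <- contact_map(
        chrom_map$values[idx, idx, drop = FALSE],
        resolution_bp = res, chrom = chrom_map$chrom,
        start_bp = chrom_map$start_bp + (s - 1L) * res,
        is_normalized = chrom_map$is_normalized)
    }
  }
  out
}

#' Normalize a contact map to the simulation's contact-probability scale
#'
#' Rescales the map so the mean contact probability between first
#' neighbours (bins `i` and `i +- 1`) is 0.1, then overwrites the main
#' diagonal (self-self contacts) with 1. This places experimental counts on
#' the same scale as simulated contact probabilities. Idempotent.
#'
#' @param H A [contact_map()] with a positive first off-diagonal mean.
#' @return A normalized `ContactMap` (`is_normalized = TRUE`).
#' @export
normalize_map <- function(H) {
  stopifnot(inherits(H, "ContactMap"))
  m <- nrow(H$values)
  if (m < 2) stop("need at least 2 bins")
  i <- seq_len(m - 1)
  off1 <- mean(H$values[cbind(i, i + 1)])
  if (off1 <= 0) stop("mean of first off-diagonal is zero; cannot normalize")
  V <- H$values * (0.1 / off1)
  diag(V) <- 1
  contact_map(V, resolution_bp = H$resolution_bp, chrom = H$chrom,
              start_bp = H$start_bp, is_normalized = TRUE)
}

#' Genomic-distance (observed/expected) normalization
#'
#' Divides every entry by the mean of its descending diagonal, removing the
#' generic polymer decay of contact probability with genomic separation.
#' Diagonals whose mean is zero are mapped to zero so downstream
#' eigendecompositions stay well defined.
#'
#' @param H A [contact_map()] (or bare symmetric matrix).
#' @return A `NormalizedMap`: list with `values` and the parent metadata.
#' @export
distance_normalize <- function(H) {
  V <- .map_values(H)
  m <- nrow(V)
  dm <- diag_means(V)
  scale <- dm
  scale[scale == 0] <- Inf           # zero-mean diagonals -> 0 in output
  D <- abs(row(V) - col(V))
  out <- V / matrix(scale[D + 1], m, m)
  structure(
    list(values = out,
         resolution_bp = if (inherits(H, "ContactMap")) H$resolution_bp else NA_integer_,
         chrom = if (inherits(H, "ContactMap")) H$chrom else NA_character_,
         start_bp = if (inherits(H, "ContactMap")) H$start_bp else NA_integer_),
    class = "NormalizedMap")
}

#' @export
print.NormalizedMap <- function(x, ...) {
  cat(sprintf("NormalizedMap (observed/expected): %d x %d bins\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Compartment signal: first principal component of an observed/expected map
#'
#' Computes the first principal component score vector of the Pearson
#' correlation transform of the genomic-distance normalized map (the
#' field's standard compartment call): the column-correlation matrix is
#' mean-centered, the first right singular vector is scaled by its
#' singular value, and the sign is fixed so the entry of largest
#' magnitude is positive. The sign of this vector partitions bins into
#' the two interaction-preference classes (A/B compartments) that appear
#' as the plaid pattern of Hi-C maps. The correlation transform is what
#' makes PC1 the compartment mode even for sharply separated maps, where
#' PC1 of the raw observed/expected matrix is dominated by
#' near-degenerate within-block variance.
#'
#' @param Hn A `NormalizedMap` from [distance_normalize()] (or matrix).
#' @return Numeric score vector of length `m`. A degenerate input (no
#'   variance after centering) returns the zero vector with a warning.
#' @export
compartment_pc1 <- function(Hn) {
  V <- .map_values(Hn)
  if (!all(is.finite(V))) stop("non-finite entries in normalized map")
  R <- suppressWarnings(stats::cor(V))
  R[!is.finite(R)] <- 0
  flat <- apply(V, 2, stats::sd) == 0  # zero-variance bins carry no signal
  R[flat, ] <- 0
  R[, flat] <- 0
  C <- sweep(R, 2, colMeans(R))
  sv <- svd(C, nu = 0, nv = 1)
  if (sv$d[1] < 1e-12 * max(1, nrow(V))) {
    warning("degenerate map: PC1 direction undefined, returning zeros")
    return(rep(0, nrow(V)))
  }
  pc1 <- drop(C %*% sv$v[, 1])
  if (pc1[which.max(abs(pc1))] < 0) pc1 <- -pc1
  pc1
}

#' Coarsen a contact map by a factor of two
#'
#' Sums each 2x2 block, halving the bin count and doubling the resolution
#' (50 kb to 100 kb). Summation preserves the count semantics of raw Hi-C;
#' total mass is conserved exactly.
#'
#' @param H50 A [contact_map()] with an even number of bins.
#' @return A `ContactMap` with `m/2` bins at twice the resolution.
#' @export
coarsen_2x <- function(H50) {
  stopifnot(inherits(H50, "ContactMap"))
  m <- nrow(H50$values)
  if (m %% 2L != 0L) stop("bin count must be even to coarsen 2x, got ", m)
  n <- m %/% 2L
  idx <- rep(seq_len(n), each = 2L)
  # sum rows into n groups, then columns
  G <- rowsum(H50$values, idx)
  V <- t(rowsum(t(G), idx))
  contact_map(V, resolution_bp = 2L * H50$resolution_bp, chrom = H50$chrom,
              start_bp = H50$start_bp, is_normalized = FALSE)
}

#' Contact-probability scaling curve
#'
#' Mean contact frequency as a function of genomic separation `d = |i - j|`
#' in bins; on a log-log scale this is the familiar polymer scaling curve
#' P(s).
#'
#' @param H A [contact_map()].
#' @return Numeric vector of length `m`; entry `d + 1` is the mean over
#'   diagonal `d`.
#' @export
contact_scaling <- function(H) {
  V <- .map_values(H)
  diag_means(V)
}

#' Write a per-bin (or per-distance) track as two-column TSV
#'
#' Used for PC1 vectors and scaling curves. Column 1 is the zero-based bin
#' or separation index, column 2 the value.
#'
#' @param x Numeric vector.
#' @param path Output file.
#' @param names Column names.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(x, path, names = c("index", "value")) {
  df <- data.frame(seq_along(x) - 1L, as.numeric(x))
  colnames(df) <- names
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
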