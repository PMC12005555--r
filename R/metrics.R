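# Contact-map and structure comparison metrics: stratum-adjusted
# correlation (SCC), the spectral Laplacian reproducibility score,
# compartment-PC1 correlation, observed/expected RMSE, and the
# upper-triangle Pearson correlation used for distance matrices.

# (2h+1) x (2h+1) box mean filter with shrinking windows at the borders,
# computed with summed-area tables
.box_smooth <- function(M, h) {
  if (h == 0) return(M)
  m <- nrow(M)
  cs <- function(X) {
    X <- apply(X, 2, cumsum)
    t(apply(X, 1, cumsum))
  }
  S <- cs(M)
  Spad <- matrix(0, m + 1, m + 1)
  Spad[2:(m + 1), 2:(m + 1)] <- S
  r1 <- pmax(row(M) - h, 1); r2 <- pmin(row(M) + h, m)
  c1 <- pmax(col(M) - h, 1); c2 <- pmin(col(M) + h, m)
  look <- function(r, c) Spad[cbind(as.vector(r), as.vector(c))]
  tot <- look(r2 + 1, c2 + 1) - look(r1, c2 + 1) -
    look(r2 + 1, c1) + look(r1, c1)
  matrix(tot, m, m) / ((r2 - r1 + 1) * (c2 - c1 + 1))
}

#' Stratum-adjusted correlation coefficient (SCC)
#'
#' A weighted average of the Pearson correlations between pairs of
#' off-diagonals (strata) of two contact maps. Both maps are first
#' smoothed with a `(2h+1) x (2h+1)` mean filter; for each genomic
#' separation `d = 1..K` the Pearson correlation `r_d` between the two
#' d-th diagonals is combined with weights
#' `w_d = N_d * sd(rank(x_d)/N_d) * sd(rank(y_d)/N_d)` — the stratum size
#' times the variance-stabilized (rank-uniform) standard deviations.
#' Strata in which either map has zero variance are skipped.
#'
#' @param H1,H2 Contact maps (or matrices) of identical shape.
#' @param h Smoothing half-width (default 5).
#' @param K Largest stratum in bins (default 100, i.e. 5 Mb at 50 kb);
#'   must be smaller than the map size.
#' @return SCC in `[-1, 1]`.
#' @export
scc <- function(H1, H2, h = 5L, K = 100L) {
  A <- .map_values(H1); B <- .map_values(H2)
  if (!all(dim(A) == dim(B))) stop("contact maps differ in shape")
  m <- nrow(A)
  if (K >= m) stop("K must be smaller than the number of bins")
  if (h < 0) stop("h must be >= 0")
  As <- .box_smooth(A, h)
  Bs <- .box_smooth(B, h)
  num <- 0; den <- 0
  for (d in seq_len(K)) {
    i <- seq_len(m - d)
    x <- As[cbind(i, i + d)]
    y <- Bs[cbind(i, i + d)]
    sx <- stats::sd(x); sy <- stats::sd(y)
    if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) next
    r <- stats::cor(x, y)
    nd <- length(x)
    w <- nd * stats::sd(rank(x) / nd) * stats::sd(rank(y) / nd)
    num <- num + w * r
    den <- den + w
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' Spectral (Laplacian eigenvector) reproducibility score
#'
#' Treats each contact map as the weighted adjacency matrix of a graph,
#' forms the symmetric normalized Laplacian
#' `I - D^(-1/2) W D^(-1/2)` (self-loops dropped), and compares the
#' eigenvectors of the `kappa` smallest nontrivial eigenvalues. Each pair
#' is sign-aligned to minimize the Euclidean distance, and the score is
#' `1 - (1/kappa) * sum ||v_i - u_i|| / sqrt(2)`, which is 1 for
#' identical maps, 0 for mutually orthogonal aligned eigenvectors, and
#' invariant to positive rescaling of either map.
#'
#' Bins isolated (zero off-diagonal sum) in either map are dropped with a
#' warning; the score is computed on the remaining common subgraph.
#'
#' @param H1,H2 Contact maps (or matrices) of identical shape.
#' @param kappa Number of eigenvectors compared (default 10).
#' @return Score in `[0, 1]`.
#' @export
hic_spector <- function(H1, H2, kappa = 10L) {
  A <- .map_values(H1); B <- .map_values(H2)
  if (!all(dim(A) == dim(B))) stop("contact maps differ in shape")
  diag(A) <- 0
  diag(B) <- 0
  keep <- rowSums(A) > 0 & rowSums(B) > 0
  if (!all(keep)) {
    warning(sum(!keep), " isolated bin(s) dropped from spectral score")
    A <- A[keep, keep, drop = FALSE]
    B <- B[keep, keep, drop = FALSE]
  }
  m <- nrow(A)
  if (kappa >= m) stop("kappa must be smaller than the number of usable bins")
  lap_vecs <- function(W) {
    dd <- rowSums(W)
    Dm <- 1 / sqrt(dd)
    Lsym <- diag(m) - (Dm * W) * rep(Dm, each = m)
    e <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
    ord <- order(e$values)          # ascending; first is the trivial mode
    e$vectors[, ord[2:(kappa + 1)], drop = FALSE]
  }
  Va <- lap_vecs(A)
  Vb <- lap_vecs(B)
  dists <- vapply(seq_len(kappa), function(i) {
    min(sqrt(sum((Va[, i] - Vb[, i])^2)), sqrt(sum((Va[, i] + Vb[, i])^2)))
  }, numeric(1))
  1 - mean(dists) / sqrt(2)
}

#' Pearson correlation between compartment PC1 tracks
#'
#' Correlates the [compartment_pc1()] vectors of two observed/expected
#' maps. Because the sign of a principal component is arbitrary, one
#' vector's sign is flipped whenever that aligns them, so the reported
#' value is the magnitude-aligned correlation (always non-negative).
#'
#' @param Hn1,Hn2 `NormalizedMap`s (from [distance_normalize()]) or
#'   matrices of identical shape.
#' @return Correlation in `[0, 1]`, or `NaN` with a warning if either PC1
#'   is degenerate.
#' @export
corr_pc1 <- function(Hn1, Hn2) {
  v1 <- compartment_pc1(Hn1)
  v2 <- compartment_pc1(Hn2)
  if (length(v1) != length(v2)) stop("maps differ in shape")
  if (all(v1 == 0) || all(v2 == 0)) {
    warning("degenerate PC1; correlation undefined")
    return(NaN)
  }
  abs(stats::cor(v1, v2))
}

#' RMSE between observed/expected maps
#'
#' @param Hn1,Hn2 `NormalizedMap`s or matrices of identical shape.
#' @return Root of the mean over all entries of the squared differences.
#' @export
rmse_norm <- function(Hn1, Hn2) {
  A <- .map_values(Hn1); B <- .map_values(Hn2)
  if (!all(dim(A) == dim(B))) stop("maps differ in shape")
  sqrt(mean((A - B)^2))
}

#' Pearson correlation over the strict upper triangle
#'
#' Used to compare mean spatial distance matrices; symmetric matrices
#' would double-weight every pair if flattened whole.
#'
#' @param D1,D2 Symmetric matrices of identical shape.
#' @return Pearson correlation, or `NaN` with a warning for constant
#'   input.
#' @export
pearson_upper_triangle <- function(D1, D2) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  if (!all(dim(D1) == dim(D2))) stop("matrices differ in shape")
  ut <- upper.tri(D1)
  x <- D1[ut]; y <- D2[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant matrix; correlation undefined")
    return(NaN)
  }
  stats::cor(x, y)
}

#' All contact-map metrics for one pair of maps
#'
#' @param H1,H2 Contact maps of identical shape (typically a simulated and
#'   an experimental map on the same normalization).
#' @param h,K SCC parameters (see [scc()]).
#' @param kappa Spectral-score parameter (see [hic_spector()]).
#' @return One-row data frame: `scc`, `hic_spector`, `corr_pc1`,
#'   `rmse_norm`, plus the parameters used.
#' @export
evaluate_maps <- function(H1, H2, h = 5L, K = 100L, kappa = 10L) {
  Hn1 <- distance_normalize(.map_values(H1))
  Hn2 <- distance_normalize(.map_values(H2))
  data.frame(scc = scc(H1, H2, h = h, K = K),
             hic_spector = hic_spector(H1, H2, kappa = kappa),
             corr_pc1 = corr_pc1(Hn1, Hn2),
             rmse_norm = rmse_norm(Hn1, Hn2),
             h = h, K = K, kappa = kappa)
}
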