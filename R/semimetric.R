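#' Semi-metrics between curves
#'
#' Distances between functional observations. Two kinds are provided:
#'
#' * `semimetric_l2(grid)` — the quadrature \eqn{L^2} distance
#'   \eqn{\sqrt{\int (u_1 - u_2)^2}} computed with trapezoid weights on the
#'   stored grid;
#' * `semimetric_pca(sample, p)` — the functional-PCA projection semi-metric:
#'   the Euclidean distance between the first `p` principal-component scores
#'   of the two curves, \eqn{\sqrt{\sum_{j \le p} \langle u_1 - u_2, v_j
#'   \rangle^2}}, where \eqn{v_j} are eigenfunctions of the empirical
#'   covariance operator of the (mean-centered) sample and
#'   \eqn{\langle\cdot,\cdot\rangle} is the quadrature inner product.
#'
#' The PCA kind is a genuine semi-metric: distinct curves with identical
#' leading scores are at distance zero, so the triangle inequality holds but
#' identity of indiscernibles does not.
#'
#' @param grid strictly increasing numeric vector of evaluation points.
#' @return An object of class `"semimetric"` with elements `kind`
#'   (`"L2"` or `"PCA"`), `grid`, `qw` (quadrature weights), and for the PCA
#'   kind `p`, `basis` (a `p x m` matrix of eigenfunctions on the grid,
#'   orthonormal under the quadrature inner product) and `values`
#'   (eigenvalues).
#' @examples
#' fs <- functional_sample(seq(0, 1, length.out = 20),
#'                         matrix(rnorm(100), nrow = 5))
#' sm <- semimetric_pca(fs, p = 2)
#' semimetric_distance(sm, fs$curves[1, ], fs$curves[2, ])
#' @export
semimetric_l2 <- function(grid) {
  structure(list(kind = "L2", grid = as.numeric(grid),
                 qw = trapezoid_weights(grid)),
            class = "semimetric")
}

#' @rdname semimetric_l2
#' @param sample a [functional_sample()] the eigenbasis is estimated from;
#'   needs at least two curves.
#' @param p positive integer, number of principal components retained
#'   (`p <= min(n, m)`).
#' @export
semimetric_pca <- function(sample, p) {
  stopifnot(inherits(sample, "functional_sample"))
  X <- sample$curves
  n <- nrow(X); m <- ncol(X)
  if (n < 2L) stop_invalid("PCA semi-metric needs at least two curves")
  p <- as.integer(p)
  if (length(p) != 1L || is.na(p) || p < 1L || p > min(n, m))
    stop_invalid("p must be an integer in [1, min(n, m)]")
  qw <- trapezoid_weights(sample$grid)
  Xc <- sweep(X, 2, colMeans(X))
  # Covariance operator under the quadrature inner product: symmetrize with
  # D = diag(sqrt(qw)) so that a plain symmetric eigenproblem applies;
  # eigenfunctions v = D^{-1} u are orthonormal w.r.t. the quadrature weights.
  sq <- sqrt(qw)
  B <- crossprod(Xc * rep(sq, each = n)) / n
  eig <- eigen(B, symmetric = TRUE)
  if (eig$values[1] <= 1e-12 * max(1, mean(diag(B))))
    stop_degenerate("sample covariance is (numerically) zero; PCA basis undefined")
  basis <- t(eig$vectors[, seq_len(p), drop = FALSE] / sq)
  structure(list(kind = "PCA", grid = sample$grid, qw = qw, p = p,
                 basis = basis, values = eig$values[seq_len(p)]),
            class = "semimetric")
}

#' @export
print.semimetric <- function(x, ...) {
  cat(sprintf("<semimetric> %s%s on %d grid points\n", x$kind,
              if (x$kind == "PCA") sprintf(" (p = %d)", x$p) else "",
              length(x$grid)))
  invisible(x)
}

# Feature map under which every semimetric distance is Euclidean:
# L2 -> sqrt(qw) * u (length m); PCA -> the p projection scores.
# curves: matrix with one row per curve.
semimetric_features <- function(sm, curves) {
  if (is.vector(curves)) curves <- matrix(curves, nrow = 1)
  if (ncol(curves) != length(sm$grid))
    stop_invalid("curves must be evaluated on the semimetric's grid")
  switch(sm$kind,
    L2  = curves * rep(sqrt(sm$qw), each = nrow(curves)),
    PCA = tcrossprod(curves * rep(sm$qw, each = nrow(curves)), sm$basis))
}

#' Distance between two curves under a semi-metric
#'
#' @param sm a [semimetric_l2()] or [semimetric_pca()] object.
#' @param curve_a,curve_b numeric vectors on the semi-metric's grid.
#' @return a single nonnegative number.
#' @export
semimetric_distance <- function(sm, curve_a, curve_b) {
  if (length(curve_a) != length(curve_b))
    stop_invalid("curves must have equal length")
  f <- semimetric_features(sm, rbind(as.numeric(curve_a), as.numeric(curve_b)))
  sqrt(sum((f[1, ] - f[2, ])^2))
}

#' All pairwise distances within a sample
#'
#' @param sample a [functional_sample()].
#' @param sm a semi-metric.
#' @return a symmetric `n x n` matrix with zero diagonal.
#' @export
pairwise_distances <- function(sample, sm) {
  f <- semimetric_features(sm, sample$curves)
  unname(as.matrix(stats::dist(f)))
}

#' Distances from every curve of a sample to external target curves
#'
#' @param sample a [functional_sample()] (the reference set).
#' @param sm a semi-metric.
#' @param targets numeric vector (one curve) or matrix (one curve per row).
#' @return an `n x n_target` matrix of distances.
#' @export
cross_distances <- function(sample, sm, targets) {
  f <- semimetric_features(sm, sample$curves)
  g <- semimetric_features(sm, targets)
  out <- matrix(0, nrow(f), nrow(g))
  for (j in seq_len(nrow(g)))
    out[, j] <- sqrt(rowSums(sweep(f, 2, g[j, ])^2))
  out
}
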