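#' Half-vectorization of a symmetric matrix (diagonal-major order)
#'
#' The package-wide vectorization of a k x k symmetric matrix stacks the k
#' diagonal entries first, then the lower off-diagonal entries row-wise:
#' for k = 3 the order is (1,1), (2,2), (3,3), (2,1), (3,1), (3,2). Every
#' sampling covariance matrix produced by \code{\link{reml_fit}} and consumed
#' by \code{\link{variance_share_test}}, \code{\link{eigenvalue_ci}} and
#' \code{\link{delta_method_se}} uses this ordering.
#'
#' @param K Symmetric numeric matrix.
#' @return Numeric vector of length k(k+1)/2.
#' @seealso [unvech()]
#' @export
vech <- function(K) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  k <- nrow(K)
  idx <- vech_index(k)
  K[idx]
}

#' Rebuild a symmetric matrix from its half-vectorization
#'
#' @param v Numeric vector of length k(k+1)/2 in the ordering of [vech()].
#' @param k Matrix dimension (inferred from length(v) when omitted).
#' @return k x k symmetric matrix.
#' @export
unvech <- function(v, k = NULL) {
  if (is.null(k)) k <- as.integer((sqrt(8 * length(v) + 1) - 1) / 2)
  stopifnot(length(v) == k * (k + 1) / 2)
  K <- matrix(0, k, k)
  K[vech_index(k)] <- v
  K[upper.tri(K)] <- t(K)[upper.tri(K)]
  K
}

# Linear indices into a k x k matrix for the diagonal-major vech ordering:
# diagonal entries first, then lower off-diagonals row-wise.
vech_index <- function(k) {
  di <- cbind(1:k, 1:k)
  off <- NULL
  if (k >= 2) {
    for (r in 2:k) off <- rbind(off, cbind(r, seq_len(r - 1)))
  }
  ij <- rbind(di, off)
  (ij[, 2] - 1) * k + ij[, 1]
}

# Row/column pairs matching vech_index order; used for derivative bookkeeping.
vech_pairs <- function(k) {
  di <- cbind(1:k, 1:k)
  off <- NULL
  if (k >= 2) for (r in 2:k) off <- rbind(off, cbind(r, seq_len(r - 1)))
  rbind(di, off)
}

#' Assemble a covariance matrix from variances and correlations
#'
#' Convenience constructor used throughout the worked examples: given
#' per-component variances and the lower-triangle correlations (row-wise:
#' (2,1), (3,1), (3,2), ...), returns the implied covariance matrix. This is
#' how the genetic covariance function Kg is reconstructed from published
#' component variances and correlations.
#'
#' @param variances Numeric vector of component variances.
#' @param correlations Numeric vector of lower-triangle correlations, row-wise,
#'   length k(k-1)/2. Omit for a diagonal matrix.
#' @return k x k symmetric covariance matrix.
#' @examples
#' cov_from_correlations(c(0.0073, 0.0017, 0.0004), c(0.682, -0.678, -0.473))
#' @export
cov_from_correlations <- function(variances, correlations = NULL) {
  k <- length(variances)
  stopifnot(all(variances >= 0))
  K <- diag(variances, nrow = k)
  if (k >= 2) {
    if (is.null(correlations)) correlations <- rep(0, k * (k - 1) / 2)
    stopifnot(length(correlations) == k * (k - 1) / 2)
    idx <- 0
    for (r in 2:k) for (s in seq_len(r - 1)) {
      idx <- idx + 1
      K[r, s] <- K[s, r] <- correlations[idx] * sqrt(variances[r] * variances[s])
    }
  }
  K
}

# Is a symmetric matrix PSD (within tolerance)?
is_psd <- function(K, tol = 1e-10) {
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > -tol * max(abs(ev), 1)
}

# Project a symmetric matrix onto the PSD cone by eigenvalue flooring.
psd_project <- function(K, floor = 0) {
  e <- eigen(K, symmetric = TRUE)
  d <- pmax(e$values, floor)
  K2 <- e$vectors %*% (d * t(e$vectors))
  (K2 + t(K2)) / 2
}

# Draw from MVN(mu, Sigma) with an explicit seed-free RNG state (callers seed).
rmvnorm_chol <- function(n, mu, Sigma) {
  k <- length(mu)
  e <- eigen(Sigma, symmetric = TRUE)
  d <- pmax(e$values, 0)
  Z <- matrix(stats::rnorm(n * k), n, k)
  sweep(Z %*% (t(e$vectors) * sqrt(d)), 2, mu, `+`)
}
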