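#' Eigen-decomposition of the genetic covariance function
#'
#' Decomposes the coefficient-scale genetic covariance matrix
#' \eqn{K_g = E D E'} into orthonormal eigenvectors E and descending
#' eigenvalues D. Each eigenvector is an independent axis of genetic variation
#' across age; its eigenvalue's share of the trace is the fraction of genetic
#' variance captured. The sign of each eigenvector is fixed so its
#' largest-magnitude entry is positive, making eigenfunction signs
#' reproducible. Small negative eigenvalues (possible when Kg is reconstructed
#' from rounded published values) are floored at zero for the share
#' computation, with a warning.
#'
#' @param Kg Symmetric genetic covariance matrix (coefficient scale).
#' @return Object of class \code{genetic_pca}: list with \code{E}
#'   (eigenvectors, columns), \code{D} (eigenvalues, descending),
#'   \code{shares} (variance shares summing to 1), \code{Kg}.
#' @export
decompose_kg <- function(Kg) {
  stopifnot(is.matrix(Kg), nrow(Kg) == ncol(Kg))
  if (max(abs(Kg - t(Kg))) > 1e-8 * max(abs(Kg), 1)) {
    stop("Kg must be symmetric")
  }
  e <- eigen((Kg + t(Kg)) / 2, symmetric = TRUE)
  E <- e$vectors
  for (j in seq_len(ncol(E))) {
    i_max <- which.max(abs(E[, j]))
    if (E[i_max, j] < 0) E[, j] <- -E[, j]
  }
  D <- e$values
  D_floored <- D
  if (any(D < 0)) {
    warning("negative eigenvalues floored at 0 for variance shares")
    D_floored <- pmax(D, 0)
  }
  structure(list(E = E, D = D, shares = D_floored / sum(D_floored), Kg = Kg),
            class = "genetic_pca")
}

#' @export
print.genetic_pca <- function(x, ...) {
  cat("genetic_pca:", length(x$D), "components; variance shares:",
      paste(sprintf("%.1f%%", 100 * x$shares), collapse = ", "), "\n")
  invisible(x)
}

#' Eigenfunctions of the genetic covariance function
#'
#' Converts eigenvectors of Kg into eigenfunctions of standardized age:
#' column j of \eqn{\Lambda E} holds the monomial coefficients
#' (powers \eqn{m^0, \ldots, m^{k-1}}) of eigenfunction \eqn{\psi_j(m)}. The
#' returned evaluator computes \eqn{\psi_j} at arbitrary standardized ages.
#'
#' @param E k x k eigenvector matrix (columns), e.g. from
#'   \code{\link{decompose_kg}}.
#' @param Lambda Legendre coefficient matrix of matching order
#'   (default \code{lambda_matrix(nrow(E))}).
#' @return List with \code{coefficients} (k x k matrix, column j = psi_j
#'   monomial coefficients) and \code{evaluate(m, j)} returning psi_j at
#'   standardized ages m.
#' @export
eigenfunctions <- function(E, Lambda = lambda_matrix(nrow(E))) {
  if (!all(dim(Lambda) == dim(E))) stop("order mismatch between E and Lambda")
  coefs <- unclass(Lambda) %*% E
  dimnames(coefs) <- list(paste0("m^", 0:(nrow(E) - 1)),
                          paste0("psi", seq_len(ncol(E))))
  evaluate <- function(m, j) {
    M <- outer(m, 0:(nrow(E) - 1), `^`)
    drop(M %*% coefs[, j])
  }
  list(coefficients = coefs, evaluate = evaluate)
}

#' Chi-squared test of the variance captured by trailing principal components
#'
#' Tests whether Kg is adequately approximated after zeroing its q smallest
#' eigenvalues: with \eqn{K_g^* = E D^* E'} (D* has the q smallest eigenvalues
#' set to zero), the statistic
#' \eqn{\chi^2 = \mathrm{vech}(K_g - K_g^*)' S^{-1} \mathrm{vech}(K_g - K_g^*)}
#' is referred to a chi-squared distribution with q(q+1)/2 degrees of freedom.
#' S is the REML sampling covariance of vech(Kg) (package vech ordering, see
#' \code{\link{vech}}).
#'
#' @param Kg Symmetric genetic covariance matrix.
#' @param sampling_cov Sampling covariance of vech(Kg),
#'   k(k+1)/2 x k(k+1)/2 PSD.
#' @param q Number of trailing (smallest) eigenvalues to zero; 1 <= q < k.
#' @return List with \code{statistic}, \code{df}, \code{p_value}, \code{q}.
#' @export
variance_share_test <- function(Kg, sampling_cov, q) {
  k <- nrow(Kg)
  nv <- k * (k + 1) / 2
  stopifnot(all(dim(sampling_cov) == c(nv, nv)))
  if (q < 1 || q >= k) stop("q must satisfy 1 <= q < k")
  e <- eigen((Kg + t(Kg)) / 2, symmetric = TRUE)
  Dstar <- e$values
  Dstar[(k - q + 1):k] <- 0
  Kstar <- e$vectors %*% (Dstar * t(e$vectors))
  d <- vech(Kg - (Kstar + t(Kstar)) / 2)
  Sinv <- tryCatch(solve(sampling_cov), error = function(e) {
    warning("singular sampling covariance; using pseudo-inverse")
    pseudo_inverse(sampling_cov)
  })
  stat <- drop(t(d) %*% Sinv %*% d)
  df <- q * (q + 1) / 2
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE), q = q)
}

pseudo_inverse <- function(S, tol = 1e-12) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

#' Simulation confidence intervals for eigenvalues and variance shares
#'
#' Draws parameter vectors from MVN(vech(Kg), S), rebuilds symmetric matrices,
#' discards non-PSD draws (counted), eigendecomposes the rest and returns
#' empirical quantiles of the eigenvalues and of their variance shares.
#'
#' @param Kg Symmetric genetic covariance matrix (point estimate).
#' @param sampling_cov Sampling covariance of vech(Kg).
#' @param n_sim Number of Monte Carlo draws (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer RNG seed.
#' @param psd_mode How to treat non-PSD draws: \code{"discard"} (default) or
#'   \code{"project"} (eigenvalue flooring at 0).
#' @return List with \code{eigenvalue_ci} and \code{share_ci} (k x 2 matrices,
#'   lower/upper), \code{n_dropped}, \code{n_used}.
#' @export
eigenvalue_ci <- function(Kg, sampling_cov, n_sim = 10000, level = 0.95,
                          seed = 1, psd_mode = c("discard", "project")) {
  psd_mode <- match.arg(psd_mode)
  k <- nrow(Kg)
  set.seed(seed)
  draws <- rmvnorm_chol(n_sim, vech(Kg), sampling_cov)
  vals <- matrix(NA_real_, n_sim, k)
  dropped <- 0L
  for (i in seq_len(n_sim)) {
    Ki <- unvech(draws[i, ], k)
    ev <- eigen(Ki, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 0) {
      if (psd_mode == "discard") { dropped <- dropped + 1L; next }
      ev <- pmax(ev, 0)
    }
    vals[i, ] <- ev
  }
  if (dropped > n_sim / 2) {
    stop("more than half of the simulated draws were non-PSD; ",
         "use psd_mode = 'project' or reduce parameter uncertainty")
  }
  vals <- vals[stats::complete.cases(vals), , drop = FALSE]
  vals <- vals[rowSums(vals) > 0, , drop = FALSE]   # all-zero projections
  shares <- vals / rowSums(vals)
  a <- (1 - level) / 2
  qfun <- function(M) t(apply(M, 2, stats::quantile, probs = c(a, 1 - a)))
  list(eigenvalue_ci = qfun(vals), share_ci = qfun(shares),
       n_dropped = dropped, n_used = nrow(vals))
}

#' Principal-component polygenic scores from genetic BLUPs
#'
#' Projects per-individual estimated genetic regression coefficients onto the
#' eigenvectors of Kg: \eqn{\hat G = \hat\alpha E}. Column j of \eqn{\hat G}
#' is each individual's polygenic score for the j-th axis of genetic variation
#' across age. Individuals are stratified per PC at one standard deviation
#' around the mean score: low (< mean - SD), average, high (> mean + SD).
#'
#' @param blup_g N x k matrix of genetic coefficient BLUPs (rows =
#'   individuals), e.g. \code{fit$blup_g}.
#' @param E k x k eigenvector matrix from \code{\link{decompose_kg}}.
#' @param standardizer Age standardizer used for stratum trajectories.
#' @param ages Age grid for stratum mean trajectories (default 1:18).
#' @return Object of class \code{pc_polygenic_scores}: list with \code{scores}
#'   (N x k), \code{strata} (N x k character matrix: low/average/high), and
#'   \code{stratum_trajectories} (per PC, a 3 x t matrix of mean genetic-value
#'   trajectories for the strata).
#' @export
pc_polygenic_scores <- function(blup_g, E, standardizer = age_standardizer(),
                                ages = 1:18) {
  if (is.null(dim(blup_g)) || nrow(blup_g) == 0) stop("empty BLUP matrix")
  if (ncol(blup_g) != nrow(E)) stop("BLUP columns do not match E order")
  G <- blup_g %*% E
  colnames(G) <- paste0("PC", seq_len(ncol(G)))
  strata <- matrix("average", nrow(G), ncol(G), dimnames = dimnames(G))
  Phi <- basis_matrix(standardize_age(ages, standardizer), ncol(blup_g))
  traj <- vector("list", ncol(G))
  names(traj) <- colnames(G)
  gv <- blup_g %*% t(Phi)   # N x t genetic-value trajectories
  for (j in seq_len(ncol(G))) {
    mu <- mean(G[, j]); sdj <- stats::sd(G[, j])
    strata[G[, j] < mu - sdj, j] <- "low"
    strata[G[, j] > mu + sdj, j] <- "high"
    tm <- matrix(NA_real_, 3, length(ages),
                 dimnames = list(c("low", "average", "high"), ages))
    for (s in rownames(tm)) {
      sel <- strata[, j] == s
      if (any(sel)) tm[s, ] <- colMeans(gv[sel, , drop = FALSE])
    }
    traj[[j]] <- tm
  }
  structure(list(scores = G, strata = strata, stratum_trajectories = traj,
                 ages = ages),
            class = "pc_polygenic_scores")
}
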