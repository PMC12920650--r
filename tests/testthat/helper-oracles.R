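# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: dense matrices, generic solvers, quadrature.

# Dense projection-based REML log-likelihood: build the full n x n covariance
# V = Zg (A (x) Kg) Zg' + Zi (I (x) Ki) Zi' + R and evaluate
# -0.5 [ log|V| + log|X'V^-1 X| + y'Py + (n-p) log 2pi ].
dense_reml_oracle <- function(Kg, Ki, s2_rec, design, A) {
  n <- design$n
  p <- design$p
  N <- length(design$ids)
  kg <- if (is.null(design$Phig)) 0L else ncol(design$Phig)
  ki <- if (is.null(design$Phii)) 0L else ncol(design$Phii)
  V <- diag(s2_rec, n)
  if (kg > 0) {
    Zg <- matrix(0, n, N * kg)
    for (i in seq_len(N)) {
      rows <- design$rows_by_id[[i]]
      Zg[rows, (i - 1) * kg + seq_len(kg)] <- design$Phig[rows, , drop = FALSE]
    }
    V <- V + Zg %*% kronecker(A, Kg) %*% t(Zg)
  }
  if (ki > 0) {
    Zi <- matrix(0, n, N * ki)
    for (i in seq_len(N)) {
      rows <- design$rows_by_id[[i]]
      Zi[rows, (i - 1) * ki + seq_len(ki)] <- design$Phii[rows, , drop = FALSE]
    }
    V <- V + Zi %*% kronecker(diag(N), Ki) %*% t(Zi)
  }
  X <- design$X
  y <- design$y
  Vinv <- solve(V)
  XtViX <- crossprod(X, Vinv %*% X)
  P <- Vinv - Vinv %*% X %*% solve(XtViX, crossprod(X, Vinv))
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                       drop(t(y) %*% P %*% y) + (n - p) * log(2 * pi)))
}

# Two-component GREML oracle for single-record data: y = Xb + g + e with
# var = sg2 * A + se2 * I. Profile REML maximized by a fine 1-D optimization
# over the heritability ratio; returns (sg2, se2, logL).
greml_oracle <- function(y, X, A) {
  n <- length(y)
  p <- ncol(X)
  eA <- eigen(A, symmetric = TRUE)
  # log-restricted-likelihood as a function of (sg2, se2)
  negll <- function(par) {
    sg2 <- exp(par[1]); se2 <- exp(par[2])
    V <- sg2 * A + diag(se2, n)
    Vinv <- chol2inv(chol(V))
    XtViX <- crossprod(X, Vinv %*% X)
    P <- Vinv - Vinv %*% X %*% solve(XtViX, crossprod(X, Vinv))
    0.5 * as.numeric(determinant(V)$modulus + determinant(XtViX)$modulus +
                       drop(t(y) %*% P %*% y) + (n - p) * log(2 * pi))
  }
  vy <- stats::var(y)
  opt <- stats::optim(log(c(0.5 * vy, 0.5 * vy)), negll, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt <- stats::optim(opt$par, negll, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  list(sg2 = exp(opt$par[1]), se2 = exp(opt$par[2]), logL = -opt$value)
}

# Gauss-Legendre nodes and weights on [-1, 1] (Golub-Welsch via eigen of the
# Jacobi matrix) - quadrature oracle for orthonormality checks.
gauss_legendre <- function(n) {
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

# Small long-format phenotype table with hand-countable filter outcomes.
fixture_pheno_10 <- function() {
  mk <- function(iid, ages) {
    data.frame(iid = iid, sex = "F", age = ages, source = "clinic",
               bmi = 16, log_bmi = log(16), stringsAsFactors = FALSE)
  }
  rbind(
    mk("a01", c(1, 3, 7, 12, 17)),          # all in window, kept
    mk("a02", c(0.5, 2, 6, 10)),            # 1 row out of window -> 3 left -> dropped
    mk("a03", c(0.8, 1.5, 5, 9, 14)),       # 1 out -> 4 left -> kept
    mk("a04", c(2, 4, 9)),                  # 3 in window -> dropped
    mk("a05", c(1, 2, 3, 4, 5, 6)),         # kept
    mk("a06", c(19, 20)),                   # all out -> dropped (0 rows)
    mk("a07", c(1, 18, 9, 5)),              # boundary ages kept -> kept
    mk("a08", c(0.2, 0.4, 3, 8, 11, 16)),   # 2 out -> 4 left -> kept
    mk("a09", c(7)),                        # singleton -> dropped
    mk("a10", c(2.5, 6.5, 10.5, 14.5, 18.5))# 1 out -> 4 left -> kept
  )
}

# PSD check used in surface tests.
is_psd_matrix <- function(V) {
  min(eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values) >
    -1e-10 * max(abs(V))
}

# Wishart-type sampling covariance of vech(K) at reference K with n_eff
# effective observations, in the package's diagonal-major vech ordering:
# Cov(K_ab, K_cd) = (K_ac K_bd + K_ad K_bc) / n_eff.
wishart_vech_cov <- function(K, n_eff) {
  pr <- rbind(cbind(1:3, 1:3), c(2, 1), c(3, 1), c(3, 2))
  S <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    a <- pr[i, 1]; b <- pr[i, 2]; c2 <- pr[j, 1]; d <- pr[j, 2]
    S[i, j] <- (K[a, c2] * K[b, d] + K[a, d] * K[b, c2]) / n_eff
  }
  S
}

rmvnorm_oracle <- function(n, mu, Sigma, seed) {
  set.seed(seed)
  e <- eigen(Sigma, symmetric = TRUE)
  Z <- matrix(rnorm(n * length(mu)), n)
  sweep(Z %*% (t(e$vectors) * sqrt(pmax(e$values, 0))), 2, mu, `+`)
}

# Bend a GRM to comfortable positive definiteness. In-sample-frequency GRMs
# are intrinsically singular (ones null vector); oracle-equivalence tests
# bend once up front so the MME path and the dense oracle see the same A.
bend_grm <- function(grm, eps = 1e-4) {
  grm$A <- grm$A + diag(eps * mean(diag(grm$A)), nrow(grm$A))
  grm
}
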