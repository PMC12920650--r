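#' Random regression model specification
#'
#' Describes one model from the analysis menu: fixed polynomial order
#' (cubic by default, per sex), genetic and individual random-coefficient
#' orders, covariates and residual structure.
#'
#' @param k_f Fixed-effect polynomial order (degree + 1); default 4 (cubic).
#' @param k_g Genetic random order; 0 removes the genetic term entirely
#'   (the reduced model used for GWAS phenotype derivation). Must be <= k_f.
#' @param k_i Individual random order; must be <= k_f.
#' @param covariates Character vector of fixed covariates. Supported:
#'   \code{"sex"} (sex-by-polynomial interactions), \code{"source"}
#'   (measurement source indicator), \code{"pgs"} (external polygenic score
#'   and its interactions with the linear, quadratic and cubic polynomials).
#' @param residual \code{"homogeneous"} (one residual variance) or
#'   \code{"per_year"} (one residual variance per whole year of age; 17 bins
#'   on the default 1-18 window).
#' @return Object of class \code{rrm_spec}.
#' @export
rrm_spec <- function(k_f = 4, k_g = 3, k_i = 3,
                     covariates = c("sex", "source"),
                     residual = c("homogeneous", "per_year")) {
  residual <- match.arg(residual)
  if (k_f < 1) stop("k_f must be >= 1")
  if (k_g < 0 || k_i < 0) stop("orders cannot be negative")
  if (k_g > k_f || k_i > k_f) stop("k_g and k_i must not exceed k_f")
  unknown <- setdiff(covariates, c("sex", "source", "pgs"))
  if (length(unknown)) stop("unknown covariates: ", paste(unknown, collapse = ", "))
  structure(list(k_f = as.integer(k_f), k_g = as.integer(k_g),
                 k_i = as.integer(k_i), covariates = covariates,
                 residual = residual),
            class = "rrm_spec")
}

#' Build the design bundle for a random regression fit
#'
#' Assembles the response, fixed-effect design matrix and per-record Legendre
#' basis rows for the random terms from a cleaned long-format phenotype table.
#' Fixed effects: the k_f scaled Legendre polynomials of standardized age
#' (the first is the overall mean), sex interactions with every polynomial
#' (when \code{"sex"} is a covariate), a measurement-source indicator (when
#' \code{"source"}), and optionally an external PGS with its interactions
#' with the non-constant polynomials (when \code{"pgs"}).
#'
#' @param pheno Long phenotype table with \code{iid}, \code{sex}, \code{age},
#'   \code{source}, \code{log_bmi}; already filtered to the analysis window.
#' @param spec An \code{\link{rrm_spec}}.
#' @param standardizer An \code{\link{age_standardizer}}.
#' @param pgs Optional named numeric vector of per-individual polygenic
#'   scores (names = iid); required when \code{"pgs"} is in the covariates.
#' @return Object of class \code{rrm_design}.
#' @export
build_design <- function(pheno, spec, standardizer = age_standardizer(),
                         pgs = NULL) {
  stopifnot(inherits(spec, "rrm_spec"), is.data.frame(pheno))
  req <- c("iid", "age", "log_bmi")
  if (!all(req %in% names(pheno))) {
    stop("phenotype table must have columns: ", paste(req, collapse = ", "))
  }
  if (any(pheno$age < standardizer$min_age - 1e-9 |
          pheno$age > standardizer$max_age + 1e-9)) {
    stop("ages outside the standardizer window; run apply_inclusion_filters")
  }
  ord <- order(pheno$iid, pheno$age)
  pheno <- pheno[ord, , drop = FALSE]
  n <- nrow(pheno)
  m <- standardize_age(pheno$age, standardizer)
  m <- pmin(pmax(m, -1), 1)
  Phif <- basis_matrix(m, spec$k_f)
  X <- Phif
  colnames(X) <- paste0("poly", 0:(spec$k_f - 1))
  if ("sex" %in% spec$covariates) {
    if (!"sex" %in% names(pheno)) stop("covariate 'sex' requested but absent")
    sex_num <- as.numeric(pheno$sex == "M")
    SX <- Phif * sex_num
    colnames(SX) <- paste0("sexM_poly", 0:(spec$k_f - 1))
    X <- cbind(X, SX)
  }
  if ("source" %in% spec$covariates) {
    if (!"source" %in% names(pheno)) stop("covariate 'source' requested but absent")
    X <- cbind(X, source_clinic = as.numeric(pheno$source == "clinic"))
  }
  if ("pgs" %in% spec$covariates) {
    if (is.null(pgs)) stop("covariate 'pgs' requested but no scores supplied")
    pv <- pgs[as.character(pheno$iid)]
    if (any(is.na(pv))) stop("missing PGS for analyzed individuals")
    if (stats::sd(pv) == 0) {
      # degenerate score (e.g. all-zero weights): the adjusted model is the
      # unadjusted one
      warning("PGS has zero variance; omitting PGS fixed effects")
    } else {
      PX <- Phif * as.numeric(pv)
      # main effect plus interactions with the non-constant polynomials;
      # the main-effect column is the raw score, not scaled by the constant
      # basis value
      PX[, 1] <- as.numeric(pv)
      colnames(PX) <- c("pgs", paste0("pgs_poly", seq_len(spec$k_f - 1)))
      X <- cbind(X, PX)
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fixed-effect design is rank deficient; offending columns: ",
         paste(bad, collapse = ", "))
  }
  ids <- unique(as.character(pheno$iid))
  id_idx <- match(as.character(pheno$iid), ids)
  n_bins <- max(1L, as.integer(floor(standardizer$max_age) -
                                 floor(standardizer$min_age)))
  bin <- pmin(pmax(floor(pheno$age) - floor(standardizer$min_age) + 1L, 1L),
              n_bins)
  structure(list(
    y = pheno$log_bmi, X = X, n = n, p = ncol(X),
    ids = ids, id_idx = id_idx,
    rows_by_id = split(seq_len(n), id_idx),
    Phig = if (spec$k_g > 0) Phif[, seq_len(spec$k_g), drop = FALSE],
    Phii = if (spec$k_i > 0) Phif[, seq_len(spec$k_i), drop = FALSE],
    kg = spec$k_g, ki = spec$k_i,
    bin = as.integer(bin), n_bins = n_bins,
    ages = pheno$age, m = m,
    spec = spec, standardizer = standardizer),
    class = "rrm_design")
}

#' @export
print.rrm_design <- function(x, ...) {
  cat(sprintf("rrm_design: %d records, %d individuals, p = %d, k_g = %d, k_i = %d\n",
              x$n, length(x$ids), x$p, x$kg, x$ki))
  invisible(x)
}

#' Variance parameter bundle
#'
#' @param Kg k_g x k_g symmetric PSD genetic covariance (log-BMI^2 units);
#'   use a 0 x 0 matrix when k_g = 0.
#' @param Ki k_i x k_i symmetric PSD individual covariance.
#' @param sigma2_e Positive residual variance: scalar, or one value per
#'   yearly bin for the heterogeneous-residual model.
#' @return Object of class \code{variance_params}.
#' @export
variance_params <- function(Kg, Ki, sigma2_e) {
  Kg <- as.matrix(Kg); Ki <- as.matrix(Ki)
  if (nrow(Kg) > 0 && !is_psd(Kg, tol = 1e-8)) stop("Kg is not PSD")
  if (nrow(Ki) > 0 && !is_psd(Ki, tol = 1e-8)) stop("Ki is not PSD")
  if (any(sigma2_e <= 0) || any(!is.finite(sigma2_e))) {
    stop("sigma2_e must be positive and finite")
  }
  structure(list(Kg = Kg, Ki = Ki, sigma2_e = as.numeric(sigma2_e)),
            class = "variance_params")
}

# Align (subset + reorder) a GRM to the design individuals; returns list with
# A, its inverse and log-determinant.
#
# A GRM standardized with in-sample allele frequencies is intrinsically
# singular (column centering puts the ones vector in its null space), and the
# mixed-model equations need A^-1. A deterministic ridge ("bending",
# 1e-6 x mean diagonal, escalated if required) is therefore added whenever A
# is not comfortably positive definite. Its effect on estimates is O(1e-6).
prepare_A <- function(grm, ids) {
  stopifnot(inherits(grm, "grm"))
  pos <- match(ids, grm$iids)
  if (any(is.na(pos))) {
    stop("individuals in phenotypes but absent from GRM ids: ",
         paste(utils::head(ids[is.na(pos)], 3), collapse = ", "))
  }
  A <- grm$A[pos, pos, drop = FALSE]
  scale <- mean(diag(A))
  eps <- 1e-6 * scale
  for (k in 0:8) {
    ch <- tryCatch(chol(A), error = function(e) NULL)
    # reject spurious factorizations of a numerically singular matrix
    if (!is.null(ch) && min(diag(ch))^2 > 1e-9 * scale) break
    A <- A + diag(eps, nrow(A))
    eps <- eps * 10
    ch <- NULL
  }
  if (is.null(ch)) stop("GRM could not be bent to positive definite")
  list(A = A, Ainv = chol2inv(ch), logdetA = 2 * sum(log(diag(ch))))
}

# Core evaluation of the random regression REML objective at given variance
# parameters, via Henderson mixed-model equations after marginalizing the
# individual-specific effects into per-individual covariance blocks.
# Returns the restricted log-likelihood and, when derivatives = TRUE, the
# score vector, average-information matrix, EM parameter updates and BLUPs.
# Parameter ordering: vech(Kg), vech(Ki), residual bins (see vech()).
rrm_eval <- function(design, Aprep, Kg, Ki, s2_bins, derivatives = FALSE) {
  d <- design
  n <- d$n; p <- d$p
  N <- length(d$ids)
  kg <- if (is.null(d$Phig)) 0L else ncol(d$Phig)
  ki <- if (is.null(d$Phii)) 0L else ncol(d$Phii)
  nb <- length(s2_bins)
  s2_rec <- s2_bins[if (nb == 1) rep(1L, n) else d$bin]

  Kginv <- NULL; logdetKg <- 0
  if (kg > 0) {
    chKg <- tryCatch(chol(Kg), error = function(e) NULL)
    if (is.null(chKg)) return(list(logL = -Inf, ok = FALSE))
    Kginv <- chol2inv(chKg)
    logdetKg <- 2 * sum(log(diag(chKg)))
  }

  q <- p + N * kg
  XtVX <- matrix(0, p, p)
  XtVy <- numeric(p)
  C <- matrix(0, q, q)
  rhs <- numeric(q)
  ytVy <- 0
  logdetV <- 0
  Vi_inv_list <- vector("list", N)
  ok <- TRUE
  for (i in seq_len(N)) {
    rows <- d$rows_by_id[[i]]
    ni <- length(rows)
    Ri <- s2_rec[rows]
    if (ki > 0) {
      Zi <- d$Phii[rows, , drop = FALSE]
      Vi <- Zi %*% Ki %*% t(Zi)
      diag(Vi) <- diag(Vi) + Ri
      chV <- tryCatch(chol(Vi), error = function(e) NULL)
      if (is.null(chV)) { ok <- FALSE; break }
      Vi_inv <- chol2inv(chV)
      logdetV <- logdetV + 2 * sum(log(diag(chV)))
    } else {
      Vi_inv <- diag(1 / Ri, nrow = ni)
      logdetV <- logdetV + sum(log(Ri))
    }
    Vi_inv_list[[i]] <- Vi_inv
    Xi <- d$X[rows, , drop = FALSE]
    yi <- d$y[rows]
    ViX <- Vi_inv %*% Xi
    XtVX <- XtVX + crossprod(Xi, ViX)
    XtVy <- XtVy + drop(crossprod(ViX, yi))
    ytVy <- ytVy + sum(yi * (Vi_inv %*% yi))
    if (kg > 0) {
      Zg <- d$Phig[rows, , drop = FALSE]
      ViZ <- Vi_inv %*% Zg
      gidx <- p + (i - 1) * kg + seq_len(kg)
      C[seq_len(p), gidx] <- crossprod(Xi, ViZ)
      C[gidx, gidx] <- crossprod(Zg, ViZ)
      rhs[gidx] <- drop(crossprod(ViZ, yi))
    }
  }
  if (!ok) return(list(logL = -Inf, ok = FALSE))
  C[seq_len(p), seq_len(p)] <- XtVX
  rhs[seq_len(p)] <- XtVy
  logdetG <- 0
  if (kg > 0) {
    gcols <- (p + 1):q
    C[gcols, gcols] <- C[gcols, gcols] + kronecker(Aprep$Ainv, Kginv)
    logdetG <- kg * Aprep$logdetA + N * logdetKg
  }
  C[lower.tri(C)] <- t(C)[lower.tri(C)]
  chC <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(chC)) return(list(logL = -Inf, ok = FALSE))
  logdetC <- 2 * sum(log(diag(chC)))
  sol <- backsolve(chC, backsolve(chC, rhs, transpose = TRUE))
  Ghat <- if (kg > 0) matrix(sol[(p + 1):q], N, kg, byrow = TRUE)
  # y'Py in the cancellation-free residual form:
  # r' Vtilde^-1 r + ghat' (A^-1 (x) Kg^-1) ghat
  b <- sol[seq_len(p)]
  r <- d$y - drop(d$X %*% b)
  if (kg > 0) r <- r - rowSums(d$Phig * Ghat[d$id_idx, , drop = FALSE])
  yPy <- 0
  for (i in seq_len(N)) {
    rows <- d$rows_by_id[[i]]
    yPy <- yPy + sum(r[rows] * (Vi_inv_list[[i]] %*% r[rows]))
  }
  if (kg > 0) {
    yPy <- yPy + sum((Aprep$Ainv %*% Ghat) * (Ghat %*% Kginv))
  }
  logL <- -0.5 * (logdetV + logdetG + logdetC + yPy + (n - p) * log(2 * pi))
  if (!is.finite(logL)) return(list(logL = -Inf, ok = FALSE))

  res <- list(logL = logL, ok = TRUE, b = b,
              Kg = Kg, Ki = Ki, s2_bins = s2_bins)
  res$Ghat <- Ghat
  if (!derivatives) return(res)

  # ---- pieces shared by score, AI and EM ----
  Cinv <- chol2inv(chC)
  b <- sol[seq_len(p)]
  Py <- numeric(n)
  diagP <- numeric(n)
  U2 <- if (ki > 0) matrix(0, N, ki)        # Zi' P y per individual
  Ti_sum_quad <- if (ki > 0) vector("list", N)  # (Zi' P Zi)_ii blocks
  B_list <- vector("list", N)
  idx_list <- vector("list", N)
  for (i in seq_len(N)) {
    rows <- d$rows_by_id[[i]]
    Xi <- d$X[rows, , drop = FALSE]
    Vi_inv <- Vi_inv_list[[i]]
    gidx <- if (kg > 0) p + (i - 1) * kg + seq_len(kg) else integer(0)
    idx_i <- c(seq_len(p), gidx)
    Wi <- if (kg > 0) cbind(Xi, d$Phig[rows, , drop = FALSE]) else Xi
    Bi <- Vi_inv %*% Wi                       # Vtilde^-1 W, individual block
    resid_i <- d$y[rows] - drop(Wi %*% sol[idx_i])
    Py_i <- drop(Vi_inv %*% resid_i)
    Py[rows] <- Py_i
    Csub <- Cinv[idx_i, idx_i, drop = FALSE]
    diagP[rows] <- diag(Vi_inv) - rowSums((Bi %*% Csub) * Bi)
    B_list[[i]] <- Bi
    idx_list[[i]] <- idx_i
    if (ki > 0) {
      Zi <- d$Phii[rows, , drop = FALSE]
      U2[i, ] <- drop(crossprod(Zi, Py_i))
      Hi <- crossprod(Bi, Zi)                 # Wi' Vi^-1 Zi, (p+kg) x ki
      # (Zi' P Zi) diagonal block for individual i
      Ti_sum_quad[[i]] <- crossprod(Zi, Vi_inv %*% Zi) -
        crossprod(Hi, Csub %*% Hi)
    }
  }

  # parameter bookkeeping
  pg <- if (kg > 0) vech_pairs(kg) else matrix(0, 0, 2)
  pi_ <- if (ki > 0) vech_pairs(ki) else matrix(0, 0, 2)
  ng <- nrow(pg); ni_ <- nrow(pi_)
  ntheta <- ng + ni_ + nb
  score <- numeric(ntheta)
  Fmat <- matrix(0, n, ntheta)

  if (kg > 0) {
    U <- matrix(0, N, kg)                     # Zg' P y per individual
    for (i in seq_len(N)) {
      rows <- d$rows_by_id[[i]]
      U[i, ] <- drop(crossprod(d$Phig[rows, , drop = FALSE], Py[rows]))
    }
    # Q[a,b] = sum_ij Ainv[i,j] * Cgg[(i,a),(j,b)]
    gall <- (p + 1):q
    Q <- matrix(0, kg, kg)
    for (a in seq_len(kg)) for (b2 in a:kg) {
      ra <- p + seq(a, N * kg, by = kg)
      rb <- p + seq(b2, N * kg, by = kg)
      Q[a, b2] <- Q[b2, a] <- sum(Aprep$Ainv * Cinv[ra, rb])
    }
    AU <- Aprep$A %*% U
    for (jj in seq_len(ng)) {
      r <- pg[jj, 1]; s <- pg[jj, 2]
      E <- matrix(0, kg, kg)
      E[r, s] <- E[r, s] + 1; E[s, r] <- E[s, r] + 1
      if (r == s) E[r, s] <- 1
      W <- Kginv %*% E %*% Kginv
      tr_term <- N * sum(E * Kginv) - sum(W * Q)
      quad <- sum(U * (AU %*% E))
      score[jj] <- -0.5 * (tr_term - quad)
      V <- AU %*% E                            # rows: (A U E)_i
      Fmat[, jj] <- rowSums(d$Phig * V[d$id_idx, , drop = FALSE])
    }
  }
  if (ki > 0) {
    for (jj in seq_len(ni_)) {
      r <- pi_[jj, 1]; s <- pi_[jj, 2]
      E <- matrix(0, ki, ki)
      E[r, s] <- E[r, s] + 1; E[s, r] <- E[s, r] + 1
      if (r == s) E[r, s] <- 1
      tr_term <- 0
      for (i in seq_len(N)) tr_term <- tr_term + sum(E * Ti_sum_quad[[i]])
      quad <- sum(U2 * (U2 %*% E))
      score[ng + jj] <- -0.5 * (tr_term - quad)
      VE <- U2 %*% E
      Fmat[, ng + jj] <- rowSums(d$Phii * VE[d$id_idx, , drop = FALSE])
    }
  }
  bin_rec <- if (nb == 1) rep(1L, n) else d$bin
  for (b2 in seq_len(nb)) {
    sel <- bin_rec == b2
    score[ng + ni_ + b2] <- -0.5 * (sum(diagP[sel]) - sum(Py[sel]^2))
    Fmat[sel, ng + ni_ + b2] <- Py[sel]
  }

  # ---- average information: AI[j,k] = 0.5 * f_j' P f_k ----
  rhsF <- matrix(0, q, ntheta)
  VF <- matrix(0, n, ntheta)                   # Vtilde^-1 F
  for (i in seq_len(N)) {
    rows <- d$rows_by_id[[i]]
    VFi <- Vi_inv_list[[i]] %*% Fmat[rows, , drop = FALSE]
    VF[rows, ] <- VFi
    Wi <- if (kg > 0) cbind(d$X[rows, , drop = FALSE],
                            d$Phig[rows, , drop = FALSE])
          else d$X[rows, , drop = FALSE]
    rhsF[idx_list[[i]], ] <- rhsF[idx_list[[i]], ] + crossprod(Wi, VFi)
  }
  solF <- backsolve(chC, backsolve(chC, rhsF, transpose = TRUE))
  PF <- VF
  for (i in seq_len(N)) {
    rows <- d$rows_by_id[[i]]
    PF[rows, ] <- PF[rows, ] - B_list[[i]] %*% solF[idx_list[[i]], , drop = FALSE]
  }
  AI <- 0.5 * crossprod(Fmat, PF)
  AI <- (AI + t(AI)) / 2

  # ---- EM updates ----
  em <- list()
  if (kg > 0) {
    em$Kg <- (crossprod(Ghat, Aprep$Ainv %*% Ghat) + Q) / N
    em$Kg <- (em$Kg + t(em$Kg)) / 2
  }
  if (ki > 0) {
    S <- matrix(0, ki, ki)
    Ai_hat <- U2 %*% Ki                       # alpha_i = Ki Zi'Py, rows
    for (i in seq_len(N)) {
      S <- S + tcrossprod(Ai_hat[i, ]) + Ki - Ki %*% Ti_sum_quad[[i]] %*% Ki
    }
    em$Ki <- (S + t(S)) / (2 * N)
    res$blup_i <- Ai_hat
  }
  s2_new <- s2_bins
  for (b2 in seq_len(nb)) {
    sel <- bin_rec == b2
    nb_rec <- sum(sel)
    if (nb_rec > 0) {
      s2_new[b2] <- s2_bins[b2] + (s2_bins[b2]^2 / nb_rec) *
        (sum(Py[sel]^2) - sum(diagP[sel]))
    }
  }
  em$s2 <- pmax(s2_new, 1e-12)

  res$score <- score
  res$AI <- AI
  res$em <- em
  res$Py <- Py
  res
}

# Pack / unpack the variance parameter vector (vech Kg, vech Ki, bins).
theta_pack <- function(Kg, Ki, s2_bins) {
  c(if (nrow(Kg) > 0) vech(Kg), if (nrow(Ki) > 0) vech(Ki), s2_bins)
}
theta_unpack <- function(theta, kg, ki, nb) {
  ng <- kg * (kg + 1) / 2
  ni <- ki * (ki + 1) / 2
  list(Kg = if (kg > 0) unvech(theta[seq_len(ng)], kg) else matrix(0, 0, 0),
       Ki = if (ki > 0) unvech(theta[ng + seq_len(ni)], ki) else matrix(0, 0, 0),
       s2 = theta[ng + ni + seq_len(nb)])
}
theta_names <- function(kg, ki, nb) {
  nm <- character(0)
  if (kg > 0) {
    pr <- vech_pairs(kg)
    nm <- c(nm, paste0("Kg", pr[, 1], pr[, 2]))
  }
  if (ki > 0) {
    pr <- vech_pairs(ki)
    nm <- c(nm, paste0("Ki", pr[, 1], pr[, 2]))
  }
  c(nm, if (nb == 1) "sigma2_e" else paste0("sigma2_e_bin", seq_len(nb)))
}

# Is a candidate theta admissible (PSD covariances, positive residuals)?
theta_admissible <- function(theta, kg, ki, nb) {
  up <- theta_unpack(theta, kg, ki, nb)
  if (kg > 0 && !is_psd(up$Kg, tol = 1e-12)) return(FALSE)
  if (ki > 0 && !is_psd(up$Ki, tol = 1e-12)) return(FALSE)
  all(up$s2 > 0)
}

# ---- Cholesky/log parameterization for the Newton steps ----------------
# Internally the optimizer works on phi = (lower Cholesky factors of Kg and
# Ki with log-transformed diagonals, log residual variances), which keeps
# every candidate inside the parameter space; score and average information
# are computed on the vech scale and mapped through the Jacobian
# J = d theta(vech) / d phi.

phi_pack_K <- function(K) {
  k <- nrow(K)
  L <- tryCatch(t(chol(K)), error = function(e) {
    t(chol(psd_project(K, floor = 1e-12 * max(diag(K), 1e-12)) +
             diag(1e-14, k)))
  })
  pr <- vech_pairs(k)
  vapply(seq_len(nrow(pr)), function(j) {
    a <- pr[j, 1]; b <- pr[j, 2]
    if (a == b) log(max(L[a, a], 1e-150)) else L[a, b]
  }, numeric(1))
}

phi_unpack_K <- function(phi_k, k) {
  L <- matrix(0, k, k)
  pr <- vech_pairs(k)
  for (j in seq_len(nrow(pr))) {
    a <- pr[j, 1]; b <- pr[j, 2]
    L[a, b] <- if (a == b) exp(phi_k[j]) else phi_k[j]
  }
  tcrossprod(L)
}

phi_pack <- function(Kg, Ki, s2) {
  c(if (nrow(Kg) > 0) phi_pack_K(Kg),
    if (nrow(Ki) > 0) phi_pack_K(Ki),
    log(s2))
}

phi_unpack <- function(phi, kg, ki, nb) {
  ng <- kg * (kg + 1) / 2
  ni <- ki * (ki + 1) / 2
  list(Kg = if (kg > 0) phi_unpack_K(phi[seq_len(ng)], kg) else matrix(0, 0, 0),
       Ki = if (ki > 0) phi_unpack_K(phi[ng + seq_len(ni)], ki) else matrix(0, 0, 0),
       s2 = exp(phi[ng + ni + seq_len(nb)]))
}

# Jacobian d vech(K) / d phi_K for one covariance block.
phi_jacobian_K <- function(phi_k, k) {
  pr <- vech_pairs(k)
  np <- nrow(pr)
  L <- matrix(0, k, k)
  for (j in seq_len(np)) {
    a <- pr[j, 1]; b <- pr[j, 2]
    L[a, b] <- if (a == b) exp(phi_k[j]) else phi_k[j]
  }
  J <- matrix(0, np, np)
  for (cj in seq_len(np)) {          # chol parameter (a, b)
    a <- pr[cj, 1]; b <- pr[cj, 2]
    for (rj in seq_len(np)) {        # vech entry (r, s)
      r <- pr[rj, 1]; s <- pr[rj, 2]
      v <- (r == a) * L[s, b] + (s == a) * L[r, b]
      J[rj, cj] <- v
    }
    if (a == b) J[, cj] <- J[, cj] * L[a, a]   # chain rule through log
  }
  J
}

phi_jacobian <- function(phi, kg, ki, nb) {
  ng <- kg * (kg + 1) / 2
  ni <- ki * (ki + 1) / 2
  n_all <- ng + ni + nb
  J <- matrix(0, n_all, n_all)
  if (kg > 0) {
    J[seq_len(ng), seq_len(ng)] <- phi_jacobian_K(phi[seq_len(ng)], kg)
  }
  if (ki > 0) {
    J[ng + seq_len(ni), ng + seq_len(ni)] <-
      phi_jacobian_K(phi[ng + seq_len(ni)], ki)
  }
  for (b2 in seq_len(nb)) {
    J[ng + ni + b2, ng + ni + b2] <- exp(phi[ng + ni + b2])
  }
  J
}

#' REML log-likelihood of a random regression model
#'
#' Evaluates the restricted log-likelihood (including its
#' \eqn{-\frac{n-p}{2}\log 2\pi} constant) at given variance parameters,
#' under \eqn{V = Z_g (A \otimes K_g) Z_g' + Z_i (I \otimes K_i) Z_i' +
#' R \sigma^2_e}. Computed via Henderson mixed-model equations with the
#' individual effects marginalized into per-individual blocks; agrees with a
#' direct dense-matrix REML evaluation to high precision.
#'
#' @param varparams A \code{\link{variance_params}} bundle.
#' @param design An \code{\link{build_design}} bundle.
#' @param grm A \code{\link{build_grm}} object (required when k_g > 0).
#' @return The restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(varparams, design, grm = NULL) {
  stopifnot(inherits(varparams, "variance_params"),
            inherits(design, "rrm_design"))
  Aprep <- if (design$kg > 0) {
    if (is.null(grm)) stop("a GRM is required when k_g > 0")
    prepare_A(grm, design$ids)
  }
  nb_spec <- if (design$spec$residual == "per_year") design$n_bins else 1L
  s2 <- varparams$sigma2_e
  if (length(s2) == 1 && nb_spec > 1) s2 <- rep(s2, nb_spec)
  if (length(s2) != nb_spec) stop("sigma2_e length does not match residual structure")
  out <- rrm_eval(design, Aprep, varparams$Kg, varparams$Ki, s2)
  if (!out$ok) stop("likelihood evaluation failed (singular V or non-PSD input)")
  out$logL
}

#' Fit a random regression model by REML
#'
#' Estimates the variance parameters (Kg, Ki, residual variance or per-year
#' residual variances) by restricted maximum likelihood: five EM-REML warm-up
#' iterations followed by average-information (AI) Newton steps with
#' step-halving whenever a step leaves the PSD cone or decreases the
#' likelihood. Convergence requires both the log-likelihood change below
#' \code{tol_logl} and the maximum relative parameter change below
#' \code{tol_param}. The sampling covariance of the variance parameters is the
#' inverse AI matrix at the optimum (ordering: vech(Kg), vech(Ki), residual
#' terms; see \code{\link{vech}}). BLUPs of the genetic and individual
#' regression coefficients are computed from the mixed-model equations at the
#' converged parameters.
#'
#' @param design From \code{\link{build_design}}.
#' @param grm From \code{\link{build_grm}} (omit when \code{k_g = 0}).
#' @param init Optional \code{\link{variance_params}} starting values.
#'   Default: diagonal Kg and Ki at 10\% of the phenotypic variance each
#'   (scaled by the mean square of the corresponding basis column),
#'   residual at 80\%.
#' @param max_iter Maximum AI iterations (default 200).
#' @param tol_logl Convergence tolerance on the log-likelihood change.
#' @param tol_param Convergence tolerance on relative parameter change.
#' @param em_iter Number of EM warm-up iterations (default 5).
#' @param verbose Print iteration trace.
#' @return Object of class \code{rrm_fit}: fixed effects \code{b} with SEs,
#'   \code{varparams}, \code{logL_reml}, \code{aic} (\eqn{-2 logL + 2
#'   \times} number of variance parameters), \code{sampling_cov},
#'   \code{blup_g} (N x k_g), \code{blup_i} (N x k_i), \code{convergence}
#'   diagnostics, the design dimensions and the standardizer.
#' @export
reml_fit <- function(design, grm = NULL, init = NULL, max_iter = 200,
                     tol_logl = 1e-6, tol_param = 1e-4, em_iter = 5,
                     verbose = FALSE) {
  stopifnot(inherits(design, "rrm_design"))
  d <- design
  if (length(d$ids) < 2) stop("need at least 2 individuals")
  kg <- d$kg; ki <- d$ki
  nb <- if (d$spec$residual == "per_year") d$n_bins else 1L
  if (nb > 1) {
    # merge empty bins into their lower neighbour
    present <- tabulate(d$bin, nb)
    if (any(present == 0)) {
      warning("empty residual bins merged with neighbours")
      map <- cumsum(present > 0)
      map[map == 0] <- 1
      d$bin <- as.integer(map[d$bin])
      nb <- max(d$bin)
      d$n_bins <- nb
    }
  }
  Aprep <- if (kg > 0) {
    if (is.null(grm)) stop("a GRM is required when k_g > 0")
    prepare_A(grm, d$ids)
  }

  vy <- stats::var(d$y)
  if (is.null(init)) {
    Kg0 <- if (kg > 0) diag(0.1 * vy / colMeans(d$Phig^2), kg) else matrix(0, 0, 0)
    Ki0 <- if (ki > 0) diag(0.1 * vy / colMeans(d$Phii^2), ki) else matrix(0, 0, 0)
    s20 <- rep(0.8 * vy, nb)
  } else {
    stopifnot(inherits(init, "variance_params"))
    Kg0 <- init$Kg; Ki0 <- init$Ki
    s20 <- init$sigma2_e
    if (length(s20) == 1 && nb > 1) s20 <- rep(s20, nb)
  }

  # boundary handling: covariance eigenvalues are floored at a negligible
  # fraction of the phenotypic variance (and residuals bounded away from 0),
  # which keeps the mixed-model equations well conditioned when a component
  # is estimated at the edge of the parameter space
  eig_floor <- 1e-7 * vy
  s2_floor <- 1e-8 * vy
  clamp_up <- function(up) {
    if (kg > 0 && min(eigen(up$Kg, symmetric = TRUE,
                            only.values = TRUE)$values) < eig_floor) {
      up$Kg <- psd_project(up$Kg, floor = eig_floor)
    }
    if (ki > 0 && min(eigen(up$Ki, symmetric = TRUE,
                            only.values = TRUE)$values) < eig_floor) {
      up$Ki <- psd_project(up$Ki, floor = eig_floor)
    }
    up$s2 <- pmax(up$s2, s2_floor)
    up
  }

  cur <- rrm_eval(d, Aprep, Kg0, Ki0, s20, derivatives = TRUE)
  if (!cur$ok) stop("likelihood undefined at starting values")
  # EM warm-up
  for (it in seq_len(em_iter)) {
    cl <- clamp_up(list(Kg = if (kg > 0) cur$em$Kg else Kg0,
                        Ki = if (ki > 0) cur$em$Ki else Ki0,
                        s2 = cur$em$s2))
    nxt <- rrm_eval(d, Aprep, cl$Kg, cl$Ki, cl$s2, derivatives = TRUE)
    if (!nxt$ok) break
    if (verbose) message(sprintf("EM %d: logL = %.6f", it, nxt$logL))
    Kg0 <- cl$Kg; Ki0 <- cl$Ki; s20 <- cl$s2
    cur <- nxt
  }

  theta <- theta_pack(Kg0, Ki0, s20)
  phi <- phi_pack(Kg0, Ki0, s20)
  status <- "max_iterations"
  iters <- 0L
  grad_norm <- NA_real_
  nu <- 1e-8   # Levenberg-Marquardt damping, adapted across iterations
  stall <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    # Newton step on the Cholesky/log scale (always admissible), with
    # Marquardt damping raised until the step increases the likelihood
    J <- phi_jacobian(phi, kg, ki, nb)
    s_phi <- drop(crossprod(J, cur$score))
    AI_phi <- crossprod(J, cur$AI %*% J)
    dscale <- pmax(diag(AI_phi), 1e-12 * max(diag(AI_phi), 1e-300))
    accepted <- FALSE
    ev <- NULL
    for (h in 1:25) {
      step <- tryCatch(
        solve(AI_phi + nu * diag(dscale, nrow(AI_phi)), s_phi),
        error = function(e) NULL)
      if (!is.null(step) && all(is.finite(step))) {
        cap <- max(abs(step))
        if (cap > 3) step <- step * (3 / cap)
        up <- clamp_up(phi_unpack(phi + step, kg, ki, nb))
        cand_phi <- phi_pack(up$Kg, up$Ki, up$s2)
        # first attempt evaluates derivatives directly so an accepted step
        # needs no second pass
        ev0 <- rrm_eval(d, Aprep, up$Kg, up$Ki, up$s2, derivatives = (h == 1))
        if (ev0$ok && ev0$logL >= cur$logL - 1e-10) {
          accepted <- TRUE
          if (h == 1) ev <- ev0
          nu <- max(nu / 10, 1e-10)
          break
        }
      }
      nu <- min(nu * 10, 1e12)
    }
    if (!accepted) {
      # fall back to one EM step (never decreases the likelihood)
      up <- clamp_up(list(Kg = if (kg > 0) cur$em$Kg else matrix(0, 0, 0),
                          Ki = if (ki > 0) cur$em$Ki else matrix(0, 0, 0),
                          s2 = cur$em$s2))
      cand_phi <- phi_pack(up$Kg, up$Ki, up$s2)
    }
    if (is.null(ev)) ev <- rrm_eval(d, Aprep, up$Kg, up$Ki, up$s2,
                                    derivatives = TRUE)
    if (!ev$ok) { status <- "failed"; break }
    cand <- theta_pack(up$Kg, up$Ki, up$s2)
    dlog <- ev$logL - cur$logL
    # relative change: against the parameter's own magnitude, floored by its
    # sampling SE so wobble along likelihood-flat (boundary) directions does
    # not block convergence
    se_theta <- sqrt(pmax(diag(tryCatch(solve(ev$AI), error = function(e)
      pseudo_inverse(ev$AI))), 0))
    rel <- max(abs(cand - theta) / pmax(abs(theta), se_theta, 1e-12))
    if (verbose) {
      message(sprintf("AI %d: logL = %.6f (d = %.2e, rel = %.2e, nu = %g)",
                      it, ev$logL, dlog, rel, nu))
    }
    theta <- cand
    phi <- cand_phi
    cur <- ev
    grad_norm <- sqrt(sum(cur$score^2))
    if (abs(dlog) < tol_logl && rel < tol_param) {
      status <- "converged"
      break
    }
    # boundary stall: when a covariance component sits on the PSD boundary
    # the log-likelihood keeps creeping along the constraint although the
    # estimates are stationary (changes far below their sampling SEs);
    # several consecutive such iterations end the fit
    stall <- stall + (rel < tol_param && abs(dlog) < 1e-3)
    if (rel >= tol_param || abs(dlog) >= 1e-3) stall <- 0L
    if (stall >= 6L) {
      status <- "converged_boundary"
      break
    }
  }

  up <- theta_unpack(theta, kg, ki, nb)
  sampling_cov <- tryCatch({
    S <- solve(cur$AI)
    (S + t(S)) / 2
  }, error = function(e) {
    warning("AI matrix singular at optimum; sampling covariance by pseudo-inverse")
    pseudo_inverse(cur$AI)
  })
  nm <- theta_names(kg, ki, nb)
  dimnames(sampling_cov) <- list(nm, nm)

  # fixed-effect covariance: (X' Vfull^-1 X)^-1 read off the MME inverse
  b_cov <- fit_b_cov(d, Aprep, up, nb)
  n_varpar <- length(theta)
  fit <- structure(list(
    b = stats::setNames(cur$b, colnames(d$X)),
    b_se = stats::setNames(sqrt(pmax(diag(b_cov), 0)), colnames(d$X)),
    varparams = variance_params_relaxed(up$Kg, up$Ki, up$s2),
    logL_reml = cur$logL,
    aic = -2 * cur$logL + 2 * n_varpar,
    n_varpar = n_varpar,
    sampling_cov = sampling_cov,
    blup_g = if (kg > 0) structure(cur$Ghat, dimnames = list(d$ids, NULL)),
    blup_i = if (ki > 0) structure(cur$blup_i, dimnames = list(d$ids, NULL)),
    convergence = list(status = status, iterations = iters,
                       grad_norm = grad_norm),
    n = d$n, N = length(d$ids), p = d$p,
    spec = d$spec, standardizer = d$standardizer,
    ids = d$ids),
    class = "rrm_fit")
  if (!startsWith(status, "converged")) {
    warning("REML did not converge (status: ", status, ")")
  }
  fit
}

# variance_params without the strict PSD check (estimates can sit exactly on
# the boundary after step-halving).
variance_params_relaxed <- function(Kg, Ki, s2) {
  structure(list(Kg = as.matrix(Kg), Ki = as.matrix(Ki),
                 sigma2_e = as.numeric(s2)), class = "variance_params")
}

# Covariance of the fixed effects at the converged parameters: the (b, b)
# block of the inverse mixed-model coefficient matrix.
fit_b_cov <- function(d, Aprep, up, nb) {
  kg <- d$kg
  N <- length(d$ids)
  s2_rec <- up$s2[if (nb == 1) rep(1L, d$n) else d$bin]
  p <- d$p
  q <- p + N * kg
  C <- matrix(0, q, q)
  for (i in seq_len(N)) {
    rows <- d$rows_by_id[[i]]
    Ri <- s2_rec[rows]
    if (d$ki > 0) {
      Zi <- d$Phii[rows, , drop = FALSE]
      Vi <- Zi %*% up$Ki %*% t(Zi)
      diag(Vi) <- diag(Vi) + Ri
      Vi_inv <- chol2inv(chol(Vi))
    } else {
      Vi_inv <- diag(1 / Ri, nrow = length(rows))
    }
    Xi <- d$X[rows, , drop = FALSE]
    C[seq_len(p), seq_len(p)] <- C[seq_len(p), seq_len(p)] +
      crossprod(Xi, Vi_inv %*% Xi)
    if (kg > 0) {
      Zg <- d$Phig[rows, , drop = FALSE]
      ViZ <- Vi_inv %*% Zg
      gidx <- p + (i - 1) * kg + seq_len(kg)
      C[seq_len(p), gidx] <- crossprod(Xi, ViZ)
      C[gidx, gidx] <- crossprod(Zg, ViZ)
    }
  }
  if (kg > 0) {
    gcols <- (p + 1):q
    Kginv <- chol2inv(chol(up$Kg + diag(1e-12, kg)))
    C[gcols, gcols] <- C[gcols, gcols] + kronecker(Aprep$Ainv, Kginv)
  }
  C[lower.tri(C)] <- t(C)[lower.tri(C)]
  Cinv <- tryCatch(chol2inv(chol(C)), error = function(e) pseudo_inverse(C))
  Cinv[seq_len(p), seq_len(p), drop = FALSE]
}

#' @export
print.rrm_fit <- function(x, ...) {
  cat(sprintf("rrm_fit: n = %d records, N = %d individuals; logL = %.4f, AIC = %.4f\n",
              x$n, x$N, x$logL_reml, x$aic))
  cat("convergence:", x$convergence$status, "in", x$convergence$iterations,
      "iterations\n")
  if (nrow(x$varparams$Kg) > 0) {
    cat("Kg diagonal:", signif(diag(x$varparams$Kg), 4), "\n")
  }
  if (nrow(x$varparams$Ki) > 0) {
    cat("Ki diagonal:", signif(diag(x$varparams$Ki), 4), "\n")
  }
  cat("sigma2_e:", signif(x$varparams$sigma2_e, 4), "\n")
  invisible(x)
}

#' Compare two random regression fits
#'
#' AIC difference and likelihood-ratio test between nested fits. REML
#' likelihoods are only comparable between models with identical fixed
#' effects; differing fixed-effect structures are a hard error. The LRT
#' p-value uses a naive chi-squared reference with df = difference in
#' variance-parameter count; when the reduced model sits on the boundary of
#' the parameter space (e.g. a variance fixed at zero) the naive p-value is
#' conservative, and the result carries a \code{boundary_caveat} flag.
#'
#' @param fit_full,fit_reduced \code{rrm_fit} objects, reduced nested in full.
#' @return List with \code{delta_aic} (full minus reduced), \code{lrt},
#'   \code{df}, \code{p_value}, \code{boundary_caveat}.
#' @export
compare_models <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "rrm_fit"), inherits(fit_reduced, "rrm_fit"))
  if (fit_full$p != fit_reduced$p || fit_full$n != fit_reduced$n) {
    stop("fixed effects differ; REML likelihoods are not comparable")
  }
  df <- fit_full$n_varpar - fit_reduced$n_varpar
  if (df < 0) stop("models are not nested as (full, reduced)")
  lrt <- max(2 * (fit_full$logL_reml - fit_reduced$logL_reml), 0)
  p <- if (df == 0) 1 else stats::pchisq(lrt, df = df, lower.tail = FALSE)
  list(delta_aic = fit_full$aic - fit_reduced$aic,
       lrt = lrt, df = df, p_value = p,
       boundary_caveat = TRUE)
}

#' Fit the reduced model (individual effects only)
#'
#' Convenience wrapper: refits with \code{k_g = 0}, keeping everything else
#' from the spec. The genetic term is removed so the BLUPs of the individual
#' polynomial coefficients can serve as GWAS phenotypes without GRM-induced
#' inflation.
#'
#' @param design From \code{\link{build_design}} (its spec's k_g is ignored).
#' @param pheno,standardizer,pgs Alternatively, rebuild the design from a
#'   phenotype table when \code{design} is NULL.
#' @param ... Passed to \code{\link{reml_fit}}.
#' @return An \code{rrm_fit} with no genetic component.
#' @export
fit_reduced <- function(design = NULL, pheno = NULL,
                        standardizer = age_standardizer(), pgs = NULL, ...) {
  if (is.null(design)) {
    stopifnot(!is.null(pheno))
    spec <- rrm_spec(k_g = 0)
    design <- build_design(pheno, spec, standardizer, pgs = pgs)
  } else {
    spec <- design$spec
    if (spec$k_g != 0) {
      spec$k_g <- 0L
      design$spec <- spec
      design$Phig <- NULL
      design$kg <- 0L
    }
  }
  reml_fit(design, grm = NULL, ...)
}

#' Fit the PGS-adjusted model
#'
#' Adds an external polygenic score (e.g. for adult BMI) and its interactions
#' with the linear, quadratic and cubic polynomials to the fixed effects, then
#' fits by REML. Used to ask how much of the age-varying SNP heritability is
#' captured by known adult-trait loci.
#'
#' @param pheno Cleaned long phenotype table.
#' @param grm GRM covering the phenotyped individuals.
#' @param pgs Named numeric vector of per-individual scores (names = iid).
#' @param spec An \code{\link{rrm_spec}}; \code{"pgs"} is appended to its
#'   covariates.
#' @param standardizer Age standardizer.
#' @param ... Passed to \code{\link{reml_fit}}.
#' @return An \code{rrm_fit}.
#' @export
fit_pgs_adjusted <- function(pheno, grm, pgs, spec = rrm_spec(),
                             standardizer = age_standardizer(), ...) {
  if (!"pgs" %in% spec$covariates) spec$covariates <- c(spec$covariates, "pgs")
  design <- build_design(pheno, spec, standardizer, pgs = pgs)
  reml_fit(design, grm = grm, ...)
}

#' Fit the heterogeneous-residual model
#'
#' Replaces the single residual variance with one residual variance per whole
#' year of age (17 bins on the default 1-18 window); the homogeneous model is
#' the equal-variance special case. Bins with no records are merged into
#' their lower neighbour with a warning.
#'
#' @param pheno Cleaned long phenotype table.
#' @param grm GRM covering the phenotyped individuals.
#' @param spec An \code{\link{rrm_spec}}; residual structure is forced to
#'   \code{"per_year"}.
#' @param standardizer Age standardizer.
#' @param ... Passed to \code{\link{reml_fit}}.
#' @return An \code{rrm_fit} whose \code{varparams$sigma2_e} is a vector.
#' @export
fit_heterogeneous_residual <- function(pheno, grm, spec = rrm_spec(),
                                       standardizer = age_standardizer(), ...) {
  spec$residual <- "per_year"
  design <- build_design(pheno, spec, standardizer)
  reml_fit(design, grm = grm, ...)
}
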