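#' Covariance function evaluated on an age grid
#'
#' Back-transforms a coefficient-scale covariance matrix K (genetic Kg or
#' individual Ki, estimated on the Legendre basis) onto the observed age
#' scale: \eqn{V = \Phi K \Phi'}, where \eqn{\Phi} is the basis matrix at the
#' grid of standardized ages. Because the covariance function is continuous
#' in age, any grid may be used; values at shared ages do not depend on the
#' grid.
#'
#' @param K k x k symmetric coefficient covariance matrix.
#' @param Phi t x k basis matrix from \code{\link{basis_matrix}}.
#' @return t x t symmetric PSD matrix of covariances between grid ages.
#' @export
covariance_surface <- function(K, Phi) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  if (ncol(Phi) != nrow(K)) stop("basis order does not match covariance order")
  if (max(abs(K - t(K))) > 1e-8 * max(abs(K), 1)) stop("K must be symmetric")
  V <- Phi %*% K %*% t(Phi)
  (V + t(V)) / 2
}

#' Heritability curve over an age grid
#'
#' Computes per-age SNP heritability \eqn{h^2(t) = V_g(t,t) / V_P(t,t)} with
#' \eqn{V_P = V_g + V_i + \sigma^2_e} (the residual variance enters only the
#' phenotypic diagonal). For a heterogeneous-residual fit supply a vector
#' \code{sigma2_e} with one value per grid age.
#'
#' @param Vg,Vi t x t age-scale genetic and individual covariance matrices.
#' @param sigma2_e Residual variance: scalar, or length-t vector (per-age).
#' @return List with \code{h2} (length t), \code{vp} (phenotypic diagonal),
#'   \code{vg}, \code{vi} (diagonals).
#' @export
heritability_curve <- function(Vg, Vi, sigma2_e) {
  stopifnot(all(dim(Vg) == dim(Vi)))
  t_n <- nrow(Vg)
  if (!length(sigma2_e) %in% c(1L, t_n)) {
    stop("sigma2_e must be a scalar or have one value per grid age")
  }
  vg <- diag(Vg); vi <- diag(Vi)
  vp <- vg + vi + sigma2_e
  if (any(vp <= 0)) stop("zero or negative phenotypic variance on the grid")
  list(h2 = vg / vp, vp = vp, vg = vg, vi = vi)
}

#' Correlation surface from a covariance surface
#'
#' \eqn{r(t_1, t_2) = V(t_1,t_2) / \sqrt{V(t_1,t_1) V(t_2,t_2)}}; diagonal is
#' exactly 1.
#'
#' @param V t x t covariance matrix with strictly positive diagonal.
#' @return t x t correlation matrix.
#' @export
correlation_surface <- function(V) {
  d <- diag(V)
  if (any(d <= 0)) stop("covariance surface has non-positive diagonal")
  R <- V / sqrt(outer(d, d))
  diag(R) <- 1
  R
}

#' Delta-method standard error of a function of variance parameters
#'
#' Standard error of a scalar function f(theta) of the variance parameters via
#' a first-order Taylor expansion: \eqn{SE = \sqrt{\nabla f' S \nabla f}},
#' with the gradient computed by central differences (relative step 1e-6) and
#' S the REML sampling covariance of the parameters. The parameter vector
#' follows the package vectorization: vech(Kg), vech(Ki), residual term(s)
#' (see \code{\link{vech}}).
#'
#' @param f Function taking the numeric parameter vector, returning a scalar.
#' @param theta Numeric parameter vector at which to evaluate.
#' @param sampling_cov PSD sampling covariance matrix of theta.
#' @return Standard error (scalar).
#' @export
delta_method_se <- function(f, theta, sampling_cov) {
  p <- length(theta)
  stopifnot(all(dim(sampling_cov) == c(p, p)))
  g <- numeric(p)
  for (j in seq_len(p)) {
    h <- 1e-6 * max(abs(theta[j]), 1e-8)
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    g[j] <- (f(tp) - f(tm)) / (2 * h)
  }
  if (any(!is.finite(g))) stop("non-finite gradient in delta method")
  v <- drop(t(g) %*% sampling_cov %*% g)
  sqrt(max(v, 0))
}

#' Age-scale variance, heritability and correlation surfaces
#'
#' Transforms a fitted random regression model (or raw coefficient covariance
#' matrices) onto the observed age scale over a grid of ages, producing the
#' genetic, individual and phenotypic covariance surfaces, the heritability
#' curve, and genetic/phenotypic correlation matrices, each with delta-method
#' standard errors when a sampling covariance is available.
#'
#' @param fit An \code{rrm_fit} from \code{\link{reml_fit}}; or NULL if the
#'   component matrices are given directly.
#' @param ages Numeric vector of grid ages in years (default 1:18, yearly).
#' @param Kg,Ki,sigma2_e Coefficient-scale components; taken from \code{fit}
#'   when supplied.
#' @param standardizer Age standardizer; taken from \code{fit} when supplied.
#' @param sampling_cov Sampling covariance over (vech(Kg), vech(Ki), residual
#'   terms); taken from \code{fit} when supplied. When NULL, SEs are NA.
#' @return An object of class \code{age_scale_surfaces}: list with
#'   \code{ages}, \code{Vg}, \code{Vi}, \code{Vp}, \code{h2}, \code{rg},
#'   \code{rp} and standard errors \code{se_vg}, \code{se_h2}, \code{se_rg},
#'   \code{se_rp} (matrix SEs for surfaces, vector for curves).
#' @export
age_scale_surfaces <- function(fit = NULL, ages = 1:18,
                               Kg = NULL, Ki = NULL, sigma2_e = NULL,
                               standardizer = age_standardizer(),
                               sampling_cov = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "rrm_fit"))
    Kg <- fit$varparams$Kg
    Ki <- fit$varparams$Ki
    sigma2_e <- fit$varparams$sigma2_e
    standardizer <- fit$standardizer
    if (is.null(sampling_cov)) sampling_cov <- fit$sampling_cov
  }
  if (is.null(Kg) || is.null(Ki) || is.null(sigma2_e)) {
    stop("supply either a fit or Kg, Ki and sigma2_e")
  }
  kg <- nrow(Kg); ki <- nrow(Ki)
  m <- standardize_age(ages, standardizer)
  Phig <- basis_matrix(m, kg)
  Phii <- basis_matrix(m, ki)
  t_n <- length(ages)

  # per-age residual variance: map yearly bins onto grid ages for the
  # heterogeneous model, else recycle the scalar
  s2_grid <- residual_at_ages(sigma2_e, ages, standardizer)

  Vg <- covariance_surface(Kg, Phig)
  Vi <- covariance_surface(Ki, Phii)
  Vp <- Vg + Vi + diag(s2_grid, nrow = t_n)
  hc <- heritability_curve(Vg, Vi, s2_grid)
  rg <- correlation_surface(Vg)
  rp <- correlation_surface(Vp)

  out <- list(ages = ages, standardizer = standardizer,
              Vg = Vg, Vi = Vi, Vp = Vp, h2 = hc$h2, rg = rg, rp = rp,
              Kg = Kg, Ki = Ki, sigma2_e = sigma2_e,
              se_vg = NULL, se_h2 = NULL, se_rg = NULL, se_rp = NULL)

  if (!is.null(sampling_cov)) {
    nkg <- kg * (kg + 1) / 2
    nki <- ki * (ki + 1) / 2
    ns <- length(sigma2_e)
    theta <- c(vech(Kg), vech(Ki), sigma2_e)
    stopifnot(all(dim(sampling_cov) == length(theta)))
    split_theta <- function(th) {
      list(Kg = unvech(th[seq_len(nkg)], kg),
           Ki = unvech(th[nkg + seq_len(nki)], ki),
           s2 = th[nkg + nki + seq_len(ns)])
    }
    se_vg <- matrix(NA_real_, t_n, t_n)
    se_rg <- matrix(NA_real_, t_n, t_n)
    se_rp <- matrix(NA_real_, t_n, t_n)
    se_h2 <- numeric(t_n)
    for (a in seq_len(t_n)) {
      se_h2[a] <- delta_method_se(function(th) {
        p <- split_theta(th)
        s2g <- residual_at_ages(p$s2, ages[a], standardizer)
        vg <- drop(Phig[a, ] %*% p$Kg %*% Phig[a, ])
        vg / (vg + drop(Phii[a, ] %*% p$Ki %*% Phii[a, ]) + s2g)
      }, theta, sampling_cov)
      for (b in a:t_n) {
        se_vg[a, b] <- se_vg[b, a] <- delta_method_se(function(th) {
          p <- split_theta(th)
          drop(Phig[a, ] %*% p$Kg %*% Phig[b, ])
        }, theta, sampling_cov)
        if (b > a) {
          se_rg[a, b] <- se_rg[b, a] <- delta_method_se(function(th) {
            p <- split_theta(th)
            num <- drop(Phig[a, ] %*% p$Kg %*% Phig[b, ])
            num / sqrt(drop(Phig[a, ] %*% p$Kg %*% Phig[a, ]) *
                       drop(Phig[b, ] %*% p$Kg %*% Phig[b, ]))
          }, theta, sampling_cov)
          se_rp[a, b] <- se_rp[b, a] <- delta_method_se(function(th) {
            p <- split_theta(th)
            s2ab <- residual_at_ages(p$s2, ages[c(a, b)], standardizer)
            vab <- drop(Phig[a, ] %*% p$Kg %*% Phig[b, ]) +
              drop(Phii[a, ] %*% p$Ki %*% Phii[b, ])
            vaa <- drop(Phig[a, ] %*% p$Kg %*% Phig[a, ]) +
              drop(Phii[a, ] %*% p$Ki %*% Phii[a, ]) + s2ab[1]
            vbb <- drop(Phig[b, ] %*% p$Kg %*% Phig[b, ]) +
              drop(Phii[b, ] %*% p$Ki %*% Phii[b, ]) + s2ab[2]
            vab / sqrt(vaa * vbb)
          }, theta, sampling_cov)
        }
      }
    }
    se_rg[cbind(seq_len(t_n), seq_len(t_n))] <- 0
    se_rp[cbind(seq_len(t_n), seq_len(t_n))] <- 0
    out$se_vg <- se_vg; out$se_h2 <- se_h2; out$se_rg <- se_rg; out$se_rp <- se_rp
  }
  class(out) <- "age_scale_surfaces"
  out
}

# Residual variance at given ages: scalar recycled, or per-year bins
# (floor(age) - min_age + 1 indexes the bin vector; ages at the upper window
# edge fall in the last bin).
residual_at_ages <- function(sigma2_e, ages, standardizer) {
  if (length(sigma2_e) == 1) return(rep(sigma2_e, length(ages)))
  bin <- pmin(floor(ages) - floor(standardizer$min_age) + 1L, length(sigma2_e))
  bin <- pmax(bin, 1L)
  sigma2_e[bin]
}

#' @export
print.age_scale_surfaces <- function(x, ...) {
  cat(sprintf("age_scale_surfaces over %d ages [%g, %g]\n",
              length(x$ages), min(x$ages), max(x$ages)))
  cat("h2 range:", sprintf("%.3f", min(x$h2)), "-",
      sprintf("%.3f", max(x$h2)), "\n")
  invisible(x)
}

#' Write age-scale surfaces as tab-delimited tables
#'
#' Writes a per-age table (age, vg, vi, vp, h2, se_h2, se_vg) and a long-format
#' pairwise table (age1, age2, rg, se_rg, rp, se_rp).
#'
#' @param surfaces An \code{age_scale_surfaces} object.
#' @param per_age_file,pairwise_file Output paths.
#' @return Invisibly, the two data frames.
#' @export
write_surfaces <- function(surfaces, per_age_file, pairwise_file) {
  s <- surfaces
  t_n <- length(s$ages)
  per_age <- data.frame(
    age = s$ages, vg = diag(s$Vg), vi = diag(s$Vi), vp = diag(s$Vp),
    h2 = s$h2,
    se_vg = if (is.null(s$se_vg)) NA_real_ else diag(s$se_vg),
    se_h2 = if (is.null(s$se_h2)) NA_real_ else s$se_h2)
  pairs <- which(upper.tri(s$rg, diag = FALSE), arr.ind = TRUE)
  pw <- data.frame(
    age1 = s$ages[pairs[, 1]], age2 = s$ages[pairs[, 2]],
    rg = s$rg[pairs], rp = s$rp[pairs],
    se_rg = if (is.null(s$se_rg)) NA_real_ else s$se_rg[pairs],
    se_rp = if (is.null(s$se_rp)) NA_real_ else s$se_rp[pairs])
  utils::write.table(per_age, per_age_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(pw, pairwise_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(list(per_age = per_age, pairwise = pw))
}
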