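#' Age standardizer for the random regression basis
#'
#' Creates an affine map from the analysis age window \code{[min_age, max_age]}
#' (years) onto the Legendre interval \eqn{[-1, 1]}. The standardizer is stored
#' with every model fit so that downstream transforms are self-describing.
#'
#' @param min_age Youngest age (years) in the analysis window. Default 1.
#' @param max_age Oldest age (years) in the analysis window. Default 18.
#' @return An object of class \code{age_standardizer} with elements
#'   \code{min_age} and \code{max_age}.
#' @examples
#' std <- age_standardizer(1, 18)
#' standardize_age(9.5, std)  # 0: the window midpoint
#' @export
age_standardizer <- function(min_age = 1, max_age = 18) {
  if (!is.numeric(min_age) || !is.numeric(max_age) ||
      !is.finite(min_age) || !is.finite(max_age)) {
    stop("min_age and max_age must be finite numerics")
  }
  if (min_age >= max_age) stop("min_age must be strictly less than max_age")
  structure(list(min_age = as.numeric(min_age), max_age = as.numeric(max_age)),
            class = "age_standardizer")
}

#' @export
print.age_standardizer <- function(x, ...) {
  cat(sprintf("age_standardizer: [%g, %g] years -> [-1, 1]\n",
              x$min_age, x$max_age))
  invisible(x)
}

#' Standardize age onto [-1, 1]
#'
#' Maps age in years onto standardized age
#' \eqn{m = -1 + 2 (age - min) / (max - min)}, the domain of the Legendre
#' polynomials. Exact at the window endpoints. Ages outside the window are the
#' caller's filtering responsibility (see \code{\link{apply_inclusion_filters}});
#' they map outside \eqn{[-1, 1]} and \code{\link{basis_matrix}} will refuse them.
#'
#' @param age Numeric vector of ages in years.
#' @param standardizer An \code{\link{age_standardizer}}.
#' @return Numeric vector of standardized ages.
#' @export
standardize_age <- function(age, standardizer = age_standardizer()) {
  stopifnot(inherits(standardizer, "age_standardizer"))
  if (!is.numeric(age) || any(!is.finite(age))) stop("age must be finite numeric")
  -1 + 2 * (age - standardizer$min_age) /
    (standardizer$max_age - standardizer$min_age)
}

#' Invert age standardization
#'
#' @param m Numeric vector of standardized ages in [-1, 1].
#' @param standardizer An \code{\link{age_standardizer}}.
#' @return Ages in years.
#' @export
unstandardize_age <- function(m, standardizer = age_standardizer()) {
  stopifnot(inherits(standardizer, "age_standardizer"))
  standardizer$min_age +
    (m + 1) * (standardizer$max_age - standardizer$min_age) / 2
}

#' Normalized Legendre polynomial coefficient matrix
#'
#' Builds the k x k upper-triangular matrix Lambda whose column j holds the
#' monomial coefficients (powers m^0 ... m^(k-1)) of the degree-(j-1) Legendre
#' polynomial scaled by \eqn{\sqrt{(2(j-1)+1)/2}} so that the scaled
#' polynomials are orthonormal on \eqn{[-1, 1]}. Coefficients come from the
#' Bonnet recurrence \eqn{(n+1) P_{n+1}(m) = (2n+1) m P_n(m) - n P_{n-1}(m)},
#' computed analytically (not hard-coded), so any order is available.
#'
#' Entries whose row parity differs from the column parity are exactly zero
#' (Legendre polynomials have pure parity).
#'
#' @param k Order: number of basis functions (polynomial degree + 1). Must be
#'   a positive integer.
#' @return A k x k numeric matrix of class \code{legendre_coefficients} with
#'   attribute \code{order}.
#' @examples
#' lambda_matrix(4)
#' @export
lambda_matrix <- function(k) {
  if (length(k) != 1 || !is.numeric(k) || !is.finite(k) || k < 1 || k != round(k)) {
    stop("k must be a positive integer")
  }
  k <- as.integer(k)
  coeffs <- vector("list", k)        # coeffs[[j]]: monomial coefficients of P_{j-1}
  coeffs[[1]] <- 1
  if (k >= 2) coeffs[[2]] <- c(0, 1)
  if (k >= 3) {
    for (j in 3:k) {
      n <- j - 2L
      a <- (2 * n + 1) * c(0, coeffs[[j - 1]])   # (2n+1) m P_n
      b <- n * c(coeffs[[j - 2]], 0, 0)          # n P_{n-1}, zero-padded
      coeffs[[j]] <- (a - b[seq_along(a)]) / (n + 1)
    }
  }
  L <- matrix(0, k, k)
  for (j in seq_len(k)) {
    cj <- coeffs[[j]] * sqrt((2 * (j - 1) + 1) / 2)
    L[seq_along(cj), j] <- cj
  }
  dimnames(L) <- list(paste0("m^", 0:(k - 1)), paste0("phi", 0:(k - 1)))
  structure(L, order = k, class = c("legendre_coefficients", "matrix", "array"))
}

#' Legendre basis matrix at standardized ages
#'
#' Evaluates the scaled Legendre polynomials at a vector of standardized ages:
#' \eqn{\Phi = M \Lambda}, where M is the t x k matrix of monomial powers
#' \eqn{m^0, \ldots, m^{k-1}} and Lambda is \code{\link{lambda_matrix}(k)}.
#' Row r of the result holds \eqn{(\phi_0(m_r), \ldots, \phi_{k-1}(m_r))}.
#'
#' @param ages_std Numeric vector of standardized ages, all within
#'   \eqn{[-1 - 10^{-12}, 1 + 10^{-12}]}.
#' @param k Order (number of basis functions).
#' @return A t x k numeric matrix with attribute \code{ages_std}.
#' @export
basis_matrix <- function(ages_std, k) {
  if (length(ages_std) == 0) stop("ages_std must be non-empty")
  if (any(!is.finite(ages_std))) stop("ages_std must be finite")
  if (any(abs(ages_std) > 1 + 1e-12)) {
    stop("standardized ages must lie in [-1, 1]; filter ages to the analysis window first")
  }
  L <- lambda_matrix(k)
  M <- outer(ages_std, 0:(k - 1), `^`)
  Phi <- M %*% L
  attr(Phi, "ages_std") <- ages_std
  Phi
}
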