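#' Trajectory phenotypes from the reduced-model BLUPs
#'
#' Builds the five GWAS phenotypes from a reduced fit (individual effects
#' only, \code{k_g = 0}, \code{k_i >= 3}): the per-individual intercept,
#' linear slope and quadratic coefficient BLUPs, plus their projections onto
#' the first two eigenvectors of the genetic covariance function (PC1, PC2
#' scores as linear combinations of the three coefficients).
#'
#' @param reduced_fit An \code{rrm_fit} with \code{k_g = 0} and
#'   \code{k_i >= 3}.
#' @param E Eigenvector matrix of Kg (3 x 3), e.g.
#'   \code{decompose_kg(Kg)$E}.
#' @return Data frame (one row per analyzed individual): \code{iid},
#'   \code{intercept}, \code{slope}, \code{quadratic}, \code{pc1},
#'   \code{pc2}.
#' @export
derive_phenotypes <- function(reduced_fit, E) {
  stopifnot(inherits(reduced_fit, "rrm_fit"))
  if (nrow(reduced_fit$varparams$Kg) != 0) {
    stop("derive_phenotypes expects a reduced fit (k_g = 0)")
  }
  B <- reduced_fit$blup_i
  if (is.null(B) || ncol(B) < 3) stop("reduced fit must have k_i >= 3")
  B3 <- B[, 1:3, drop = FALSE]
  stopifnot(all(dim(E) >= c(3, 2)))
  S <- B3 %*% E[1:3, 1:2, drop = FALSE]
  data.frame(iid = rownames(B), intercept = B3[, 1], slope = B3[, 2],
             quadratic = B3[, 3], pc1 = S[, 1], pc2 = S[, 2],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-SNP association of a derived phenotype
#'
#' Ordinary least squares of the phenotype on each SNP's allele count with
#' fixed covariates (typically the top 10 GRM principal components plus an
#' intercept, which is added automatically). This is the two-step design:
#' the mixed model enters only through the derivation of the phenotype, and
#' the GRM only through the PC covariates. Two-sided p-values from the t
#' statistic; genome-wide significance annotated at 5e-8.
#'
#' @param panel A QC'd \code{genotype_panel}.
#' @param phenotype Named numeric vector (names = iid) or unnamed vector
#'   aligned with the panel's individuals.
#' @param covariates N x c numeric matrix (rownames = iid optional). An
#'   intercept column is added; supplying your own constant column is an
#'   error, not silently dropped.
#' @return Object of class \code{gwas_results}: data frame with snp, a1, a2,
#'   freq, beta, se, stat, p, genome_wide (logical); attributes \code{n} and
#'   \code{lambda_gc}.
#' @export
gwas <- function(panel, phenotype, covariates = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  G <- panel$geno
  n <- nrow(G)
  y <- if (!is.null(names(phenotype))) {
    pos <- match(panel$iids, names(phenotype))
    if (any(is.na(pos))) stop("phenotype missing for some panel individuals")
    as.numeric(phenotype[pos])
  } else {
    stopifnot(length(phenotype) == n)
    as.numeric(phenotype)
  }
  if (stats::sd(y) == 0) stop("constant phenotype")
  C <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    if (any(apply(covariates, 2, stats::sd) == 0)) {
      stop("constant covariate column supplied; remove it (an intercept is added automatically)")
    }
    C <- cbind(C, covariates)
  }
  qc <- qr(C)
  if (qc$rank < ncol(C)) stop("collinear covariates")
  # residualize phenotype and genotypes against covariates once
  y_r <- stats::residuals(stats::lm.fit(C, y))
  p_hat <- colMeans(G, na.rm = TRUE) / 2
  Gi <- G
  if (anyNA(Gi)) {
    for (j in which(colSums(is.na(Gi)) > 0)) {
      Gi[is.na(Gi[, j]), j] <- 2 * p_hat[j]
    }
  }
  G_r <- Gi - C %*% qr.coef(qc, Gi)
  gtg <- colSums(G_r^2)
  gty <- drop(crossprod(G_r, y_r))
  ok <- gtg > 1e-10
  beta <- ifelse(ok, gty / gtg, NA_real_)
  df <- n - ncol(C) - 1
  rss <- sum(y_r^2) - beta^2 * gtg
  se <- sqrt(pmax(rss / df, 0) / gtg)
  stat <- beta / se
  p <- 2 * stats::pt(abs(stat), df = df, lower.tail = FALSE)
  res <- data.frame(
    snp = panel$snp_ids,
    a1 = if (!is.null(panel$bim)) panel$bim$a1 else "A",
    a2 = if (!is.null(panel$bim)) panel$bim$a2 else "G",
    freq = p_hat, beta = beta, se = se, stat = stat, p = p,
    genome_wide = !is.na(p) & p < 5e-8,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "n") <- n
  attr(res, "lambda_gc") <- lambda_gc(p[!is.na(p)])
  class(res) <- c("gwas_results", "data.frame")
  res
}

#' Genomic-control inflation factor
#'
#' Lambda GC: the median of the 1-df chi-squared statistics implied by the
#' p-values, divided by the null median 0.45494 (qchisq(0.5, 1)).
#'
#' @param p Numeric vector of p-values in (0, 1]; at least 100 required.
#' @return Scalar lambda.
#' @export
lambda_gc <- function(p) {
  if (length(p) < 100) stop("need at least 100 p-values")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Lead SNPs by positional clumping
#'
#' Annotation-free clumping: SNPs below the significance threshold are
#' greedily assigned to the lowest-p SNP within a fixed window (default 1 Mb)
#' on the same chromosome; one lead SNP is reported per clump. Requires a
#' panel with map information (chr, bp).
#'
#' @param results A \code{gwas_results} data frame.
#' @param bim SNP map (chr, id, bp columns) aligned with \code{results$snp}.
#' @param p_threshold Significance threshold (default 5e-8).
#' @param window_bp Clump window in base pairs (default 1e6).
#' @return Data frame of lead SNPs (subset of \code{results}).
#' @export
clump_lead_snps <- function(results, bim, p_threshold = 5e-8, window_bp = 1e6) {
  sig <- which(!is.na(results$p) & results$p < p_threshold)
  if (!length(sig)) return(results[integer(0), ])
  sig <- sig[order(results$p[sig])]
  lead <- integer(0)
  for (i in sig) {
    if (!any(bim$chr[lead] == bim$chr[i] &
             abs(bim$bp[lead] - bim$bp[i]) <= window_bp)) {
      lead <- c(lead, i)
    }
  }
  results[lead, , drop = FALSE]
}

#' Read / write GWAS summary statistics
#'
#' Tab-delimited summary statistics in the common exchange layout: SNP, CHR,
#' BP, A1, A2, FREQ, BETA, SE, P, N. Numeric columns are written with full
#' precision (17 significant digits) so the reader round-trips exactly.
#'
#' @param results A \code{gwas_results} data frame.
#' @param bim SNP map aligned with \code{results} (chr, bp per SNP); defaults
#'   to chromosome 1 with index positions.
#' @param path Output file.
#' @return \code{write_sumstats}: the path, invisibly;
#'   \code{read_sumstats}: a data frame.
#' @export
write_sumstats <- function(results, path, bim = NULL) {
  m <- nrow(results)
  if (is.null(bim)) bim <- data.frame(chr = rep(1, m), bp = seq_len(m))
  out <- data.frame(SNP = results$snp, CHR = bim$chr, BP = bim$bp,
                    A1 = results$a1, A2 = results$a2,
                    FREQ = sprintf("%.17g", results$freq),
                    BETA = sprintf("%.17g", results$beta),
                    SE = sprintf("%.17g", results$se),
                    P = sprintf("%.17g", results$p),
                    N = attr(results, "n"))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(SNP = "character", A1 = "character",
                                   A2 = "character"))
}
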