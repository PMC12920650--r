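#' Genotype panel container
#'
#' Bundles a hard-call (or dosage) genotype matrix with its identifiers and
#' optional per-SNP imputation INFO scores. Values must lie in [0, 2] or be
#' NA (missing).
#'
#' @param geno N x M numeric matrix, individuals in rows.
#' @param iids Individual ids (default rownames or 1:N).
#' @param snp_ids SNP ids (default colnames or snp1..snpM).
#' @param info Optional numeric vector of imputation INFO scores per SNP.
#' @param bim Optional data frame of SNP map information (chr, id, cm, bp,
#'   a1, a2), as read from a PLINK .bim file.
#' @return Object of class \code{genotype_panel}.
#' @export
genotype_panel <- function(geno, iids = NULL, snp_ids = NULL, info = NULL,
                           bim = NULL) {
  stopifnot(is.matrix(geno))
  rng <- range(geno, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("genotype values must lie in [0, 2]")
  if (is.null(iids)) iids <- rownames(geno)
  if (is.null(iids)) iids <- paste0("id", seq_len(nrow(geno)))
  if (is.null(snp_ids)) snp_ids <- colnames(geno)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(geno)))
  if (!is.null(info)) stopifnot(length(info) == ncol(geno))
  structure(list(geno = geno, iids = as.character(iids),
                 snp_ids = as.character(snp_ids), info = info, bim = bim),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d individuals x %d SNPs\n",
              nrow(x$geno), ncol(x$geno)))
  invisible(x)
}

#' Per-SNP quality control
#'
#' Removes SNPs failing, in order: missingness > \code{miss_max}; exact-test
#' Hardy-Weinberg equilibrium P < \code{hwe_p_min}; imputation INFO <
#' \code{info_min} (skipped when the panel carries no INFO scores, e.g. for
#' hard-call synthetic data where the filter is inert); minor allele frequency
#' < \code{maf_min}. Counts removed are reported per filter in application
#' order.
#'
#' @param panel A \code{\link{genotype_panel}}.
#' @param miss_max Maximum missing fraction (default 0.05).
#' @param hwe_p_min Minimum HWE exact-test P (default 1e-6).
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param info_min Minimum INFO score (default 0.8).
#' @return List with \code{panel} (filtered) and \code{counts} (removed per
#'   filter plus SNPs in/out).
#' @export
snp_qc <- function(panel, miss_max = 0.05, hwe_p_min = 1e-6, maf_min = 0.01,
                   info_min = 0.8) {
  stopifnot(inherits(panel, "genotype_panel"))
  G <- panel$geno
  m_in <- ncol(G)
  keep <- rep(TRUE, m_in)

  miss <- colMeans(is.na(G))
  fail_miss <- miss > miss_max
  keep[fail_miss] <- FALSE

  hwe_p <- rep(NA_real_, m_in)
  idx <- which(keep)
  for (j in idx) hwe_p[j] <- hwe_exact_p(G[, j])
  fail_hwe <- keep & !is.na(hwe_p) & hwe_p < hwe_p_min
  keep[fail_hwe] <- FALSE

  fail_info <- rep(FALSE, m_in)
  if (!is.null(panel$info)) {
    fail_info <- keep & panel$info < info_min
    keep[fail_info] <- FALSE
  }

  p <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  fail_maf <- keep & (is.na(maf) | maf < maf_min)
  keep[fail_maf] <- FALSE

  if (!any(keep)) stop("all SNPs removed by QC")
  out <- genotype_panel(G[, keep, drop = FALSE], iids = panel$iids,
                        snp_ids = panel$snp_ids[keep],
                        info = panel$info[keep],
                        bim = if (!is.null(panel$bim)) panel$bim[keep, , drop = FALSE])
  list(panel = out,
       counts = list(snps_in = m_in,
                     removed_missingness = sum(fail_miss),
                     removed_hwe = sum(fail_hwe),
                     removed_info = sum(fail_info),
                     removed_maf = sum(fail_maf),
                     snps_out = sum(keep)))
}

# Exact Hardy-Weinberg test on hard calls (two-sided, conditional on allele
# counts; Wigginton et al. style mid-less tail sum). Dosages are rounded to
# the nearest hard call.
hwe_exact_p <- function(g) {
  g <- round(g[!is.na(g)])
  n <- length(g)
  if (n == 0) return(NA_real_)
  n_het <- sum(g == 1)
  n_hom_min <- min(sum(g == 0), sum(g == 2))
  rare <- 2 * n_hom_min + n_het
  if (rare == 0) return(1)
  # enumerate het counts compatible with the observed allele counts
  het_range <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(het_range, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_r + 1) - lgamma(hom_c + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p_all <- exp(logp - max(logp))
  p_all <- p_all / sum(p_all)
  p_obs <- p_all[het_range == n_het]
  sum(p_all[p_all <= p_obs + 1e-12])
}

#' Build a genomic relationship matrix
#'
#' Computes the N x N GRM from a QC'd panel:
#' \deqn{A_{jk} = \frac{1}{M} \sum_i \frac{(x_{ij} - 2 p_i)(x_{ik} - 2 p_i)}
#'   {2 p_i (1 - p_i)}}
#' with \eqn{p_i} the in-sample allele frequency. The diagonal uses the same
#' standardized cross-product as the off-diagonals. Missing genotypes are
#' mean-imputed to \eqn{2 p_i} before standardization (so they contribute
#' zero).
#'
#' @param panel A \code{\link{genotype_panel}} after QC.
#' @return Object of class \code{grm}: list with \code{A} (N x N), \code{iids},
#'   \code{n_snps}.
#' @export
build_grm <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  G <- panel$geno
  p <- colMeans(G, na.rm = TRUE) / 2
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic SNP encountered; run snp_qc first")
  }
  W <- sweep(G, 2, 2 * p)
  W[is.na(W)] <- 0
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), `/`)
  A <- tcrossprod(W) / ncol(G)
  dimnames(A) <- list(panel$iids, panel$iids)
  structure(list(A = A, iids = panel$iids, n_snps = ncol(G)), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d individuals, %d SNPs; mean diagonal %.3f\n",
              length(x$iids), x$n_snps, mean(diag(x$A))))
  invisible(x)
}

#' Prune related individuals from a GRM
#'
#' Greedy relatedness pruning: while any kept pair has relatedness above
#' \code{cutoff}, remove the individual participating in the largest number of
#' such pairs (ties broken by a seeded random draw). The kept set has no
#' off-diagonal above the cutoff.
#'
#' @param grm A \code{\link{build_grm}} result.
#' @param cutoff Relatedness threshold (default 0.05).
#' @param seed Integer seed for tie-breaking.
#' @return Character vector of kept iids.
#' @export
prune_related <- function(grm, cutoff = 0.05, seed = 1) {
  stopifnot(inherits(grm, "grm"))
  if (cutoff <= 0) stop("cutoff must be positive")
  A <- grm$A
  n <- nrow(A)
  adj <- abs(A) > cutoff
  # only off-diagonal exceedances count
  diag(adj) <- FALSE
  adj[upper.tri(adj)] <- t(adj)[upper.tri(adj)]
  keep <- rep(TRUE, n)
  set.seed(seed)
  repeat {
    deg <- rowSums(adj[, keep, drop = FALSE]) * keep
    if (max(deg) == 0) break
    worst <- which(deg == max(deg))
    drop_i <- if (length(worst) > 1) sample(worst, 1) else worst
    keep[drop_i] <- FALSE
    adj[drop_i, ] <- FALSE
    adj[, drop_i] <- FALSE
  }
  grm$iids[keep]
}

#' Principal components of a GRM
#'
#' Eigenvectors of A scaled by the square root of their eigenvalues, in
#' descending eigenvalue order, with each component's sign fixed so its
#' largest-magnitude loading is positive. These are the ancestry PCs used as
#' GWAS covariates.
#'
#' @param grm A \code{\link{build_grm}} result.
#' @param n_components Number of PCs (default 10).
#' @return N x n_components matrix of PC scores (rownames = iids).
#' @export
grm_pca <- function(grm, n_components = 10) {
  stopifnot(inherits(grm, "grm"))
  n <- nrow(grm$A)
  if (n_components > n) stop("n_components exceeds the number of individuals")
  e <- eigen(grm$A, symmetric = TRUE)
  V <- e$vectors[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(V))) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) V[, j] <- -V[, j]
  }
  scores <- sweep(V, 2, sqrt(pmax(e$values[seq_len(n_components)], 0)), `*`)
  dimnames(scores) <- list(grm$iids, paste0("PC", seq_len(n_components)))
  scores
}

#' GCTA binary GRM I/O
#'
#' Writes/reads the GCTA triplet: \code{<prefix>.grm.bin} (float32 lower
#' triangle including the diagonal, row-wise), \code{<prefix>.grm.N.bin}
#' (float32 per-pair SNP counts) and \code{<prefix>.grm.id} (tab-delimited
#' FID/IID). Values round-trip exactly at float32 precision.
#'
#' @param grm A \code{grm} object.
#' @param prefix Path prefix.
#' @return \code{write_grm_gcta}: the prefix, invisibly. \code{read_grm_gcta}:
#'   a \code{grm} object.
#' @export
write_grm_gcta <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  n <- length(grm$iids)
  lower <- grm$A[lower_tri_rowwise_index(n)]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lower), con, size = 4)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(rep(grm$n_snps, length(lower))), con, size = 4)
  close(con)
  utils::write.table(data.frame(fid = grm$iids, iid = grm$iids),
                     paste0(prefix, ".grm.id"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname write_grm_gcta
#' @export
read_grm_gcta <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"), header = FALSE,
                           sep = "\t", stringsAsFactors = FALSE)
  n <- nrow(ids)
  n_pairs <- n * (n + 1) / 2
  con <- file(paste0(prefix, ".grm.bin"), "rb")
  lower <- readBin(con, "numeric", n = n_pairs, size = 4)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "rb")
  nsnp <- readBin(con, "numeric", n = n_pairs, size = 4)
  close(con)
  A <- matrix(0, n, n)
  idx <- lower_tri_rowwise_index(n)
  A[idx] <- lower
  A[upper.tri(A)] <- t(A)[upper.tri(A)]
  dimnames(A) <- list(ids[, 2], ids[, 2])
  structure(list(A = A, iids = as.character(ids[, 2]),
                 n_snps = round(nsnp[1])), class = "grm")
}

# Linear indices of the lower triangle (incl. diagonal) in GCTA row-wise
# order: (1,1), (2,1), (2,2), (3,1), ...
lower_tri_rowwise_index <- function(n) {
  ij <- do.call(rbind, lapply(seq_len(n), function(r) cbind(r, seq_len(r))))
  (ij[, 2] - 1) * n + ij[, 1]
}

#' PLINK bed/bim/fam I/O
#'
#' Reads/writes hard-call genotypes in PLINK 1 binary format (SNP-major .bed
#' with magic bytes 0x6c 0x1b 0x01; two bits per genotype). Dosage convention:
#' the stored value counts A1 alleles (bed code 00 = two A1 copies, 10 = one,
#' 11 = zero, 01 = missing).
#'
#' @param prefix Path prefix (without extension).
#' @return \code{read_plink}: a \code{\link{genotype_panel}} with the .bim
#'   table attached. \code{write_plink}: the prefix, invisibly.
#' @export
read_plink <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE)
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE)
  names(bim) <- c("chr", "id", "cm", "bp", "a1", "a2")
  n <- nrow(fam); m <- nrow(bim)
  bpl <- ceiling(n / 4)   # bytes per SNP
  con <- file(paste0(prefix, ".bed"), "rb")
  magic <- readBin(con, "raw", n = 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L))) {
    close(con)
    stop("not a SNP-major PLINK .bed file")
  }
  raw <- readBin(con, "raw", n = bpl * m)
  close(con)
  # decode 2-bit fields, LSB first
  bits <- matrix(as.integer(rawToBits(raw)), nrow = 8)
  codes <- bits[seq(1, 8, 2), , drop = FALSE] +
    2L * bits[seq(2, 8, 2), , drop = FALSE]   # 4 codes per byte
  codes <- matrix(as.vector(codes), nrow = 4 * bpl)[seq_len(n), , drop = FALSE]
  G <- matrix(NA_real_, n, m)
  G[codes == 0L] <- 2   # hom A1
  G[codes == 2L] <- 1   # het
  G[codes == 3L] <- 0   # hom A2
  dimnames(G) <- list(fam[, 2], bim$id)
  genotype_panel(G, iids = fam[, 2], snp_ids = bim$id, bim = bim)
}

#' @param panel A \code{genotype_panel} (hard calls; values are rounded).
#' @param fam Optional fam data frame (FID, IID, PAT, MAT, SEX, PHENO).
#' @rdname read_plink
#' @export
write_plink <- function(panel, prefix, fam = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  G <- round(panel$geno)
  n <- nrow(G); m <- ncol(G)
  if (is.null(fam)) {
    fam <- data.frame(fid = panel$iids, iid = panel$iids, pat = 0, mat = 0,
                      sex = 0, pheno = -9)
  }
  bim <- panel$bim
  if (is.null(bim)) {
    bim <- data.frame(chr = 1, id = panel$snp_ids, cm = 0, bp = seq_len(m),
                      a1 = "A", a2 = "G")
  }
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  codes <- matrix(1L, 4 * ceiling(n / 4), m)     # pad with "missing"
  gc <- matrix(1L, n, m)
  gc[G == 2] <- 0L; gc[G == 1] <- 2L; gc[G == 0] <- 3L
  gc[is.na(G)] <- 1L
  codes[seq_len(n), ] <- gc
  # pack 4 two-bit codes per byte, LSB first
  c1 <- codes[seq(1, nrow(codes), 4), , drop = FALSE]
  c2 <- codes[seq(2, nrow(codes), 4), , drop = FALSE]
  c3 <- codes[seq(3, nrow(codes), 4), , drop = FALSE]
  c4 <- codes[seq(4, nrow(codes), 4), , drop = FALSE]
  bytes <- c1 + 4L * c2 + 16L * c3 + 64L * c4
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  close(con)
  invisible(prefix)
}
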