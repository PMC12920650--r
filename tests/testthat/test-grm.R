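test_that("snp_qc applies the thresholds in order on a hand-set toy panel", {
  # 5 SNPs: 1 fails missingness (6%), 2 monomorphic (MAF), 3 gross HWE
  # violation, 4 and 5 clean
  set.seed(4)
  n <- 200
  g1 <- rbinom(n, 2, 0.3); g1[sample(n, 12)] <- NA         # 6% missing
  g2 <- rep(0, n)                                          # monomorphic
  g3 <- sample(c(0, 2), n, TRUE)                           # no hets at p~0.5
  g4 <- rbinom(n, 2, 0.25)
  g5 <- rbinom(n, 2, 0.45)
  panel <- genotype_panel(cbind(g1, g2, g3, g4, g5))
  res <- snp_qc(panel)
  expect_equal(res$counts$removed_missingness, 1)
  expect_equal(res$counts$removed_hwe, 1)
  expect_equal(res$counts$removed_maf, 1)
  expect_equal(res$counts$snps_out, 2)
  expect_equal(res$panel$snp_ids, c("g4", "g5"))
  # INFO filter applies only when scores exist
  panel_i <- genotype_panel(cbind(g4, g5), info = c(0.9, 0.5))
  res_i <- snp_qc(panel_i)
  expect_equal(res_i$counts$removed_info, 1)
  expect_error(snp_qc(genotype_panel(cbind(g2))), "all SNPs removed")
})

test_that("hwe exact test agrees with chi-square intuition on extremes", {
  # perfect HWE proportions: p not small
  set.seed(9)
  g <- c(rep(0, 25), rep(1, 50), rep(2, 25))
  expect_gt(longrrm:::hwe_exact_p(g), 0.5)
  # total heterozygote deficit at p = 0.5 is essentially impossible
  g2 <- c(rep(0, 50), rep(2, 50))
  expect_lt(longrrm:::hwe_exact_p(g2), 1e-10)
})

test_that("build_grm matches the standardized cross-product formula by hand", {
  # one SNP, genotypes {0, 2}: p = 0.5, denominator 2p(1-p) = 0.5
  panel <- genotype_panel(matrix(c(0, 2), 2, 1))
  A <- build_grm(panel)$A
  expect_equal(A[1, 2], (0 - 1) * (2 - 1) / 0.5, ignore_attr = TRUE)  # -2
  expect_equal(A[1, 1], (0 - 1)^2 / 0.5, ignore_attr = TRUE)          #  2
  expect_equal(A[1, 2], -2, ignore_attr = TRUE)
  # mean-imputed missing genotypes contribute zero
  g <- matrix(rbinom(60, 2, 0.4), 20, 3)
  g_na <- g; g_na[1, 2] <- NA
  A1 <- build_grm(genotype_panel(g_na))$A
  expect_true(all(is.finite(A1)))
  expect_error(build_grm(genotype_panel(matrix(0, 5, 1))), "monomorphic")
})

test_that("GRM of simulated unrelateds is near identity; duplicates are visible", {
  panel <- simulate_genotypes(60, 5000, seed = 21)
  A <- build_grm(panel)$A
  expect_lt(abs(mean(diag(A)) - 1), 0.05)
  off <- A[upper.tri(A)]
  expect_lt(abs(mean(off)), 3 / sqrt(5000))
  # a duplicated individual shows relatedness ~1
  g2 <- rbind(panel$geno, panel$geno[1, ])
  A2 <- build_grm(genotype_panel(g2))$A
  expect_gt(A2[1, 61], 0.9)
})

test_that("build_grm is invariant under SNP column permutation", {
  panel <- simulate_genotypes(30, 400, seed = 33)
  A1 <- build_grm(panel)$A
  perm <- sample(400)
  A2 <- build_grm(genotype_panel(panel$geno[, perm]))$A
  expect_equal(A1, A2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("prune_related removes the minimum necessary individuals", {
  # GRM with one related pair: exactly one of the two goes
  A <- diag(6)
  A[1, 2] <- A[2, 1] <- 0.3
  g <- structure(list(A = A, iids = letters[1:6], n_snps = 100), class = "grm")
  kept <- prune_related(g, cutoff = 0.05, seed = 1)
  expect_equal(length(kept), 5)
  expect_false(all(c("a", "b") %in% kept))
  # clique of 3 mutually related: 2 removed
  A3 <- diag(6)
  A3[1:3, 1:3] <- 0.5; diag(A3) <- 1
  g3 <- structure(list(A = A3, iids = letters[1:6], n_snps = 100), class = "grm")
  kept3 <- prune_related(g3, cutoff = 0.05, seed = 1)
  expect_equal(length(kept3), 4)
  expect_equal(sum(c("a", "b", "c") %in% kept3), 1)
})

test_that("pruning a cohort with planted duplicates leaves no pair above cutoff", {
  set.seed(5)
  panel <- simulate_genotypes(80, 3000, seed = 8)
  G <- panel$geno
  dup <- G[sample(80, 20), ]                 # 20 planted duplicate rows
  Gall <- rbind(G, dup)
  grm <- build_grm(genotype_panel(Gall))
  kept <- prune_related(grm, cutoff = 0.05, seed = 3)
  Ak <- grm$A[kept, kept]
  diag(Ak) <- 0
  expect_lt(max(abs(Ak)), 0.05 + 1e-12)
})

test_that("grm_pca separates two planted populations and returns orthogonal scores", {
  set.seed(14)
  n <- 100; m <- 800
  p1 <- runif(m, 0.1, 0.9)
  shift <- rnorm(m, 0, 0.12)
  p2 <- pmin(pmax(p1 + shift, 0.02), 0.98)
  G <- rbind(
    matrix(rbinom(50 * m, 2, rep(p1, each = 50)), 50, m),
    matrix(rbinom(50 * m, 2, rep(p2, each = 50)), 50, m))
  grm <- build_grm(genotype_panel(G))
  pcs <- grm_pca(grm, n_components = 10)
  expect_equal(dim(pcs), c(100, 10))
  # columns orthogonal (eigenvectors scaled by sqrt eigenvalue)
  cp <- crossprod(pcs)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8 * max(diag(cp)))
  # PC1 separates the groups
  grp <- rep(c(1, 2), each = 50)
  expect_gt(abs(mean(pcs[grp == 1, 1]) - mean(pcs[grp == 2, 1])),
            2 * (sd(pcs[grp == 1, 1]) + sd(pcs[grp == 2, 1])) / 2)
  expect_error(grm_pca(grm, n_components = 101), "exceeds")
})

test_that("GCTA binary GRM round-trips bit-exactly at float32 precision", {
  panel <- snp_qc(simulate_genotypes(25, 500, seed = 2), hwe_p_min = 0)$panel
  grm <- build_grm(panel)
  prefix <- tempfile()
  write_grm_gcta(grm, prefix)
  back <- read_grm_gcta(prefix)
  # values equal the float32-rounded originals, and a second write is
  # byte-identical
  expect_equal(back$A, grm$A, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$iids, grm$iids)
  expect_equal(back$n_snps, grm$n_snps)
  prefix2 <- tempfile()
  write_grm_gcta(back, prefix2)
  expect_identical(readBin(paste0(prefix, ".grm.bin"), "raw", 1e6),
                   readBin(paste0(prefix2, ".grm.bin"), "raw", 1e6))
})

test_that("PLINK bed/bim/fam round-trips hard calls including missing", {
  set.seed(6)
  G <- matrix(rbinom(35 * 11, 2, 0.4), 35, 11)
  G[sample(length(G), 10)] <- NA
  panel <- genotype_panel(G)
  prefix <- tempfile()
  write_plink(panel, prefix)
  back <- read_plink(prefix)
  expect_equal(unname(back$geno), unname(G))
  expect_equal(back$iids, panel$iids)
  expect_equal(back$snp_ids, panel$snp_ids)
})
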