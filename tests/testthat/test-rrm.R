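# REML engine: design construction, likelihood against the dense oracle,
# model comparison, and the model variants. The heavier parameter-recovery
# and oracle-equivalence checks at their stated scales live in
# test-acceptance.R.

small_sim <- function(N = 30, M = 300, seed = 1, cfg = NULL) {
  panel <- simulate_genotypes(N, M, seed = seed)
  if (is.null(cfg)) {
    cfg <- sim_config(n_individuals = N, n_snps = M,
                      Kg = cov_from_correlations(c(0.3, 0.15, 0.05),
                                                 c(0.4, -0.3, -0.2)),
                      Ki = diag(c(0.5, 0.2, 0.1)), sigma2_e = 0.3,
                      mean_measures = 8, sd_measures = 2)
  }
  sim <- simulate_cohort(panel, cfg, seed = seed + 1)
  list(sim = sim, cfg = cfg)
}

test_that("build_design produces the documented fixed-effect layout", {
  s <- small_sim()
  des <- build_design(s$sim$pheno, rrm_spec())
  expect_equal(des$p, 9)  # 2 x 4 sex-specific polynomial terms + source
  expect_equal(colnames(des$X)[1:4], paste0("poly", 0:3))
  # a record at age 9.5 has basis row phi(0)
  ph <- s$sim$pheno[1, ]
  ph$age <- 9.5
  d1 <- build_design(rbind(ph, s$sim$pheno), rrm_spec())
  r <- which(d1$ages == 9.5)[1]
  expect_equal(d1$Phig[r, ], drop(basis_matrix(0, 3)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # all-female table with a sex covariate is rank deficient
  phF <- s$sim$pheno
  phF$sex <- "F"
  expect_error(build_design(phF, rrm_spec()), "rank deficient")
  expect_error(build_design(s$sim$pheno[, c("iid", "age")], rrm_spec()),
               "columns")
})

test_that("row permutation of the phenotype table leaves the fit unchanged", {
  s <- small_sim(N = 25, M = 200, seed = 3)
  grm <- bend_grm(s$sim$truth$grm)
  des1 <- build_design(s$sim$pheno, rrm_spec())
  perm <- sample(nrow(s$sim$pheno))
  des2 <- build_design(s$sim$pheno[perm, ], rrm_spec())
  vp <- variance_params(s$cfg$Kg, s$cfg$Ki, s$cfg$sigma2_e)
  expect_equal(reml_loglik(vp, des1, grm),
               reml_loglik(vp, des2, grm), tolerance = 1e-9)
})

test_that("reml_loglik matches the dense oracle on random small instances", {
  # fuller 20-instance sweep in test-acceptance.R; here a quick spot check
  for (seed in 1:5) {
    s <- small_sim(N = 8, M = 120, seed = seed)
    grm <- bend_grm(s$sim$truth$grm)
    des <- build_design(s$sim$pheno, rrm_spec())
    vp <- variance_params(s$cfg$Kg, s$cfg$Ki, s$cfg$sigma2_e)
    l_mme <- reml_loglik(vp, des, grm)
    l_oracle <- dense_reml_oracle(s$cfg$Kg, s$cfg$Ki,
                                  rep(s$cfg$sigma2_e, des$n), des, grm$A)
    expect_lt(abs(l_mme - l_oracle), 1e-6)
  }
})

test_that("reml_loglik degenerates to the OLS residual likelihood without random terms", {
  s <- small_sim(N = 20, M = 100, seed = 9)
  des <- build_design(s$sim$pheno, rrm_spec(k_g = 0, k_i = 0))
  s2 <- 0.4
  l <- reml_loglik(variance_params(matrix(0, 0, 0), matrix(0, 0, 0), s2), des)
  X <- des$X; y <- des$y
  n <- des$n; p <- des$p
  rss <- sum(stats::lm.fit(X, y)$residuals^2)
  l_ols <- -0.5 * ((n - p) * log(s2) +
                     determinant(crossprod(X))$modulus + rss / s2 +
                     (n - p) * log(2 * pi))
  expect_equal(l, as.numeric(l_ols), tolerance = 1e-8)
})

test_that("REML is scale equivariant: logL(cy; c^2 theta) = logL(y; theta) - (n-p) log c", {
  s <- small_sim(N = 12, M = 120, seed = 5)
  grm <- bend_grm(s$sim$truth$grm)
  des1 <- build_design(s$sim$pheno, rrm_spec())
  vp1 <- variance_params(s$cfg$Kg, s$cfg$Ki, s$cfg$sigma2_e)
  cc <- 3.7
  ph2 <- s$sim$pheno
  ph2$log_bmi <- cc * ph2$log_bmi
  des2 <- build_design(ph2, rrm_spec())
  vp2 <- variance_params(cc^2 * s$cfg$Kg, cc^2 * s$cfg$Ki, cc^2 * s$cfg$sigma2_e)
  l1 <- reml_loglik(vp1, des1, grm)
  l2 <- reml_loglik(vp2, des2, grm)
  expect_equal(l2, l1 - (des1$n - des1$p) * log(cc), tolerance = 1e-7)
})

test_that("adding a constant to y moves only the intercept coefficient", {
  s <- small_sim(N = 25, M = 200, seed = 7)
  des1 <- build_design(s$sim$pheno, rrm_spec())
  fit1 <- suppressWarnings(reml_fit(des1, s$sim$truth$grm))
  ph2 <- s$sim$pheno
  ph2$log_bmi <- ph2$log_bmi + 5
  des2 <- build_design(ph2, rrm_spec())
  fit2 <- suppressWarnings(reml_fit(des2, s$sim$truth$grm))
  # intercept column is the constant phi0 = sqrt(1/2)
  expect_equal(unname(fit2$b[1] - fit1$b[1]), 5 / sqrt(0.5), tolerance = 1e-3)
  expect_equal(fit2$b[-1], fit1$b[-1], tolerance = 1e-2)
  expect_equal(fit2$varparams$Kg, fit1$varparams$Kg, tolerance = 0.02)
  expect_equal(fit2$varparams$sigma2_e, fit1$varparams$sigma2_e,
               tolerance = 1e-2)
})

test_that("compare_models: LRT bookkeeping and hard error on differing fixed effects", {
  s <- small_sim(N = 30, M = 250, seed = 11)
  des3 <- build_design(s$sim$pheno, rrm_spec(k_g = 3))
  des2 <- build_design(s$sim$pheno, rrm_spec(k_g = 2))
  fit3 <- suppressWarnings(reml_fit(des3, s$sim$truth$grm))
  fit2 <- suppressWarnings(reml_fit(des2, s$sim$truth$grm))
  res <- compare_models(fit3, fit2)
  expect_equal(res$df, 3)   # one variance + two covariances
  expect_gte(res$lrt, 0)
  expect_true(res$boundary_caveat)
  # identical fits
  same <- compare_models(fit3, fit3)
  expect_equal(same$lrt, 0)
  expect_equal(same$p_value, 1)
  # nesting: reduced cannot beat full
  expect_lte(fit2$logL_reml, fit3$logL_reml + 1e-6)
  # different fixed effects are not comparable
  des_nosex <- build_design(s$sim$pheno, rrm_spec(covariates = "source"))
  fit_nosex <- suppressWarnings(reml_fit(des_nosex, s$sim$truth$grm,
                                         max_iter = 15))
  expect_error(compare_models(fit3, fit_nosex), "not comparable")
})

test_that("reduced model: nesting, deterministic BLUPs, intercept sanity", {
  s <- small_sim(N = 40, M = 300, seed = 13)
  desf <- build_design(s$sim$pheno, rrm_spec())
  fitf <- suppressWarnings(reml_fit(desf, s$sim$truth$grm, max_iter = 25))
  fitr1 <- suppressWarnings(fit_reduced(desf))
  fitr2 <- suppressWarnings(fit_reduced(desf))
  expect_lte(fitr1$logL_reml, fitf$logL_reml + 1e-6)
  expect_identical(fitr1$blup_i, fitr2$blup_i)
  expect_null(fitr1$blup_g)
  means <- tapply(s$sim$pheno$log_bmi, s$sim$pheno$iid, mean)
  expect_gt(cor(fitr1$blup_i[, 1], means[rownames(fitr1$blup_i)]), 0.8)
})

test_that("PGS-adjusted fit with zero weights equals the unadjusted fit", {
  s <- small_sim(N = 30, M = 250, seed = 17)
  zero_pgs <- stats::setNames(rep(0, 30), unique(s$sim$pheno$iid))
  expect_warning(
    fit0 <- fit_pgs_adjusted(s$sim$pheno, s$sim$truth$grm, zero_pgs,
                             max_iter = 20),
    "zero variance")
  des <- build_design(s$sim$pheno, rrm_spec())
  fit <- suppressWarnings(reml_fit(des, s$sim$truth$grm, max_iter = 20))
  expect_equal(fit0$logL_reml, fit$logL_reml, tolerance = 1e-6)
  expect_equal(fit0$varparams$Kg, fit$varparams$Kg, tolerance = 1e-6)
})

test_that("heterogeneous residual model uses 17 yearly bins on the default window", {
  s <- small_sim(N = 40, M = 300, seed = 19)
  des <- build_design(s$sim$pheno, rrm_spec(residual = "per_year"))
  expect_equal(des$n_bins, 17)
  fith <- suppressWarnings(
    fit_heterogeneous_residual(s$sim$pheno, s$sim$truth$grm, max_iter = 15))
  expect_true(length(fith$varparams$sigma2_e) >= 2)
  expect_true(all(fith$varparams$sigma2_e > 0))
})

test_that("heterogeneous residual recovers a planted step in sigma2", {
  set.seed(23)
  # constant-vs-doubled residual after age 9, strong contrast, no genetics
  N <- 120
  panel <- simulate_genotypes(N, 100, seed = 29)
  cfg <- sim_config(n_individuals = N, n_snps = 100,
                    Kg = diag(1e-8, 3), Ki = diag(c(0.02, 0.01, 0.005)),
                    sigma2_e = 0.01)
  sim <- simulate_cohort(panel, cfg, seed = 31)
  ph <- sim$pheno
  late <- ph$age > 9
  ph$log_bmi[late] <- ph$log_bmi[late] + rnorm(sum(late), 0, sqrt(0.01))
  # late-age residual variance is now ~0.02 vs 0.01 before age 9
  spec <- rrm_spec(k_g = 0, residual = "per_year")
  des <- build_design(ph, spec)
  fit <- suppressWarnings(reml_fit(des, max_iter = 30))
  s2 <- fit$varparams$sigma2_e
  early_bins <- 1:8
  late_bins <- 10:min(17, length(s2))
  expect_gt(mean(s2[late_bins]) / mean(s2[early_bins]), 1.4)
})

test_that("sampling covariance is PSD and sized by the parameter count", {
  s <- small_sim(N = 30, M = 250, seed = 37)
  des <- build_design(s$sim$pheno, rrm_spec())
  fit <- suppressWarnings(reml_fit(des, s$sim$truth$grm, max_iter = 25))
  nv <- 6 + 6 + 1
  expect_equal(dim(fit$sampling_cov), c(nv, nv))
  ev <- eigen(fit$sampling_cov, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10 * max(ev))
  expect_equal(fit$aic, -2 * fit$logL_reml + 2 * nv)
  expect_equal(rownames(fit$sampling_cov)[1:3], c("Kg11", "Kg22", "Kg33"))
})
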