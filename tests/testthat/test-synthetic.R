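test_that("simulate_genotypes is reproducible and respects the MAF range", {
  p1 <- simulate_genotypes(50, 200, seed = 4)
  p2 <- simulate_genotypes(50, 200, seed = 4)
  expect_identical(p1$geno, p2$geno)
  expect_true(all(p1$geno %in% 0:2))
  # fixed p = 0.5: mean dosage 1 within 3 binomial SEs
  pf <- simulate_genotypes(2000, 50, maf_range = c(0.5, 0.5), seed = 6)
  se <- sqrt(2 * 0.25 / 2000)
  expect_true(all(abs(colMeans(pf$geno) - 1) < 3 * se))
  expect_error(simulate_genotypes(10, 10, maf_range = c(0, 0.6)), "maf_range")
})

test_that("empirical allele frequencies track the drawn frequencies", {
  panel <- simulate_genotypes(1000, 2000, seed = 8)
  p <- attr(panel, "freqs")
  p_hat <- colMeans(panel$geno) / 2
  se <- sqrt(p * (1 - p) / (2 * 1000))
  expect_gt(mean(abs(p_hat - p) < 3 * se), 0.99)
})

test_that("simulated genetic coefficients have covariance A x Kg", {
  panel <- simulate_genotypes(5000, 1000, seed = 10)
  cfg <- sim_config(n_individuals = 5000, n_snps = 1000)
  sim <- simulate_cohort(panel, cfg, seed = 11)
  emp <- stats::cov(sim$truth$alpha_g)
  Kg <- cfg$Kg
  # Wishart-type MC standard errors at N = 5000
  for (a in 1:3) for (b in a:3) {
    se <- sqrt((Kg[a, a] * Kg[b, b] + Kg[a, b]^2) / 5000)
    expect_lt(abs(emp[a, b] - Kg[a, b]), 3.5 * se)
  }
  # individual coefficients
  empi <- stats::cov(sim$truth$alpha_i)
  for (a in 1:3) {
    se <- sqrt(2 * cfg$Ki[a, a]^2 / 5000)
    expect_lt(abs(empi[a, a] - cfg$Ki[a, a]), 3.5 * se)
  }
})

test_that("SNP-effect construction agrees with a direct Cholesky of A x Kg", {
  # hold the genotypes (hence A) fixed; compare element-wise variances of
  # alpha_g across replicate effect draws with the theoretical A_ii * Kg_jj
  panel <- simulate_genotypes(50, 400, seed = 12)
  cfg <- sim_config(n_individuals = 50, n_snps = 400)
  nrep <- 250
  acc <- array(0, c(nrep, 50, 3))
  for (r in seq_len(nrep)) {
    sim <- simulate_cohort(panel, cfg, seed = 1000 + r)
    acc[r, , ] <- sim$truth$alpha_g
  }
  A <- build_grm(panel)$A
  v_emp <- apply(acc, c(2, 3), stats::var)
  v_theory <- outer(diag(A), diag(cfg$Kg))
  se <- v_theory * sqrt(2 / nrep)
  expect_gt(mean(abs(v_emp - v_theory) < 3.5 * se), 0.98)
  # direct-Cholesky reference path has the same element variances
  direct <- vapply(seq_len(nrep), function(r) {
    longrrm:::simulate_alpha_g_direct(A, cfg$Kg, seed = 2000 + r)
  }, matrix(0, 50, 3))
  v_dir <- apply(direct, c(1, 2), stats::var)
  expect_gt(mean(abs(v_dir - v_theory) < 3.5 * se), 0.98)
})

test_that("cohort structure: counts, window, sources, log transform", {
  panel <- simulate_genotypes(300, 200, seed = 14)
  cfg <- sim_config(n_individuals = 300, n_snps = 200)
  sim <- simulate_cohort(panel, cfg, seed = 15)
  ph <- sim$pheno
  counts <- table(ph$iid)
  expect_gte(min(counts), 4)
  expect_lte(max(counts), length(cfg$wave_ages))
  expect_equal(mean(counts), 10.5, tolerance = 0.1)
  expect_true(all(ph$age >= 1 & ph$age <= 18))
  expect_setequal(unique(ph$source), c("questionnaire", "clinic"))
  expect_equal(ph$log_bmi, log(ph$bmi), tolerance = 1e-12)
  # same seed reproduces
  sim2 <- simulate_cohort(panel, cfg, seed = 15)
  expect_identical(sim2$pheno, ph)
})

test_that("population heritability at the mean age matches the stated defaults", {
  # h2(m=0) under the default generative parameters; the analytic value from
  # the default Kg/Ki/sigma2 is ~0.278 (back-solved from published
  # heritabilities of 28.4/23.8/9.8%)
  cfg <- sim_config()
  phi0g <- drop(basis_matrix(0, 3))
  vg0 <- drop(t(phi0g) %*% cfg$Kg %*% phi0g)
  vi0 <- drop(t(phi0g) %*% cfg$Ki %*% phi0g)
  h2_true <- vg0 / (vg0 + vi0 + cfg$sigma2_e)
  expect_equal(h2_true, 0.284, tolerance = 0.025)
  # sample-variance oracle at N = 5000
  panel <- simulate_genotypes(5000, 800, seed = 16)
  sim <- simulate_cohort(panel, cfg, seed = 17)
  g0 <- drop(sim$truth$alpha_g %*% phi0g)
  i0 <- drop(sim$truth$alpha_i %*% phi0g)
  h2_emp <- stats::var(g0) / (stats::var(g0) + stats::var(i0) + cfg$sigma2_e)
  expect_equal(h2_emp, h2_true, tolerance = 0.1)
})

test_that("null genetic model yields near-zero genetic variance downstream", {
  panel <- simulate_genotypes(80, 300, seed = 18)
  cfg <- sim_config(n_individuals = 80, n_snps = 300, Kg = diag(1e-10, 3))
  sim <- simulate_cohort(panel, cfg, seed = 19)
  expect_lt(max(abs(stats::cov(sim$truth$alpha_g))), 1e-9)
})

test_that("adult PGS weights hit the target R2 on the age-18 phenotype", {
  panel <- simulate_genotypes(5000, 1000, seed = 20)
  cfg <- sim_config(n_individuals = 5000, n_snps = 1000)
  sim <- simulate_cohort(panel, cfg, seed = 21)
  tr <- sim$truth
  phi18g <- drop(basis_matrix(1, 3))
  g18 <- drop(tr$alpha_g %*% phi18g)
  i18 <- drop(tr$alpha_i %*% drop(basis_matrix(1, 3)))
  set.seed(22)
  y18 <- g18 + i18 + rnorm(5000, 0, sqrt(cfg$sigma2_e))
  # default 16% target
  w <- simulate_adult_pgs_weights(tr, seed = 23)
  score <- polygenic_score(panel, w)
  r2 <- cor(score, y18)^2
  expect_equal(r2, 0.16, tolerance = 0.03 / 0.16)
  # permuted weights carry no signal
  wp <- w
  set.seed(24)
  wp$weight <- sample(wp$weight)
  r2p <- cor(polygenic_score(panel, wp), y18)^2
  expect_lt(r2p, 0.01)
  expect_error(simulate_adult_pgs_weights(tr, target_r2 = 0.9), "exceeds")
})

test_that("noise-free weights correlate ~1 with the true age-18 genetic value", {
  panel <- simulate_genotypes(800, 500, seed = 26)
  cfg <- sim_config(n_individuals = 800, n_snps = 500)
  sim <- simulate_cohort(panel, cfg, seed = 27)
  phi18g <- drop(basis_matrix(1, 3))
  g18 <- drop(sim$truth$alpha_g %*% phi18g)
  vg18 <- drop(t(phi18g) %*% cfg$Kg %*% phi18g)
  vi18 <- drop(t(phi18g) %*% cfg$Ki %*% phi18g)
  r2max <- vg18 / (vg18 + vi18 + cfg$sigma2_e)
  w <- simulate_adult_pgs_weights(sim$truth, target_r2 = r2max, seed = 28)
  expect_gt(cor(polygenic_score(panel, w), g18), 0.999)
})

test_that("likelihood at the truth beats strongly perturbed parameters on average", {
  diffs <- vapply(1:5, function(r) {
    panel <- simulate_genotypes(60, 300, seed = 100 + r)
    cfg <- sim_config(n_individuals = 60, n_snps = 300)
    sim <- simulate_cohort(panel, cfg, seed = 200 + r)
    des <- build_design(sim$pheno, rrm_spec())
    l_true <- reml_loglik(variance_params(cfg$Kg, cfg$Ki, cfg$sigma2_e),
                          des, sim$truth$grm)
    l_pert <- reml_loglik(variance_params(4 * cfg$Kg, 4 * cfg$Ki,
                                          4 * cfg$sigma2_e),
                          des, sim$truth$grm)
    l_true - l_pert
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("informative dropout thins late waves for high genetic values", {
  panel <- simulate_genotypes(600, 300, seed = 30)
  cfg <- sim_config(n_individuals = 600, n_snps = 300, dropout_beta = 2)
  sim <- simulate_cohort(panel, cfg, seed = 31)
  phi18g <- drop(basis_matrix(1, 3))
  g18 <- drop(sim$truth$alpha_g %*% phi18g)
  late_count <- tapply(sim$pheno$age > 7, sim$pheno$iid, sum)
  ids <- unique(sim$pheno$iid)
  expect_lt(cor(g18[match(names(late_count), ids)], late_count), 0)
})
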