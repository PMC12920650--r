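#' Default genetic covariance matrix for simulations
#'
#' The published point estimates of the additive-genetic covariance function
#' for childhood log-BMI on a cubic-fixed / quadratic-random Legendre basis:
#' component variances 0.0073 (intercept), 0.0017 (linear), 0.0004
#' (quadratic), with correlations 0.682 (intercept-linear), -0.678
#' (intercept-quadratic) and -0.473 (linear-quadratic).
#'
#' @return 3 x 3 symmetric PSD matrix (log-BMI^2 units).
#' @export
default_kg <- function() {
  cov_from_correlations(c(0.0073, 0.0017, 0.0004), c(0.682, -0.678, -0.473))
}

#' Simulation configuration for the synthetic cohort
#'
#' Describes the generative model of the synthetic cohort: a random
#' regression model run forwards. Defaults state the emulated study
#' conditions: 1-18 year window, genetic covariance Kg at the published point
#' estimates (\code{\link{default_kg}}), an individual-effect covariance Ki
#' back-solved from the published per-component heritabilities
#' (diag 0.0144, 0.0054, 0.0037), residual variance 0.004, sex-specific cubic
#' mean curves, a questionnaire/clinic source offset, and a measurement
#' schedule averaging 10.5 (SD 3.8) records per individual on waves that are
#' dense in infancy (1-2 y) and from mid-childhood (7-18 y) but sparse at
#' 3-6 y.
#'
#' @param n_individuals Cohort size.
#' @param n_snps Number of independent SNPs.
#' @param maf_range Allele frequency range, within (0, 0.5].
#' @param Kg Genetic coefficient covariance (k_g x k_g PSD).
#' @param Ki Individual coefficient covariance (k_i x k_i PSD).
#' @param sigma2_e Residual variance (> 0).
#' @param fixed_curve List with \code{female} and \code{male} coefficient
#'   vectors on the k_f = 4 Legendre basis and \code{source_offset}
#'   (log-BMI added to clinic measurements).
#' @param wave_ages Ages (years) of the measurement waves.
#' @param mean_measures,sd_measures Mean and SD of the per-individual
#'   measurement count (rounded normal, truncated to
#'   [\code{min_measures}, number of waves]).
#' @param min_measures Minimum retained measurements per individual.
#' @param jitter_sd SD (years) of the age jitter around each wave.
#' @param dropout_beta Informative-dropout coefficient: probability of losing
#'   each post-childhood (age > 7) wave is
#'   \code{plogis(qlogis(base) + dropout_beta * scaled genetic value)};
#'   0 (default) is missing completely at random.
#' @param standardizer Age window.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(n_individuals = 500, n_snps = 2000,
                       maf_range = c(0.05, 0.5),
                       Kg = default_kg(),
                       Ki = diag(c(0.0144, 0.0054, 0.0037)),
                       sigma2_e = 0.004,
                       fixed_curve = default_fixed_curve(),
                       wave_ages = default_wave_ages(),
                       mean_measures = 10.5, sd_measures = 3.8,
                       min_measures = 4, jitter_sd = 0.1,
                       dropout_beta = 0,
                       standardizer = age_standardizer()) {
  Kg <- as.matrix(Kg); Ki <- as.matrix(Ki)
  if (!is_psd(Kg, tol = 1e-8)) stop("Kg must be symmetric PSD")
  if (!is_psd(Ki, tol = 1e-8)) stop("Ki must be symmetric PSD")
  if (sigma2_e <= 0) stop("sigma2_e must be positive")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]")
  }
  if (mean_measures < min_measures) {
    stop("schedule cannot satisfy the minimum number of measurements")
  }
  if (length(wave_ages) < min_measures) {
    stop("fewer waves than the minimum number of measurements")
  }
  structure(list(n_individuals = n_individuals, n_snps = n_snps,
                 maf_range = maf_range, Kg = Kg, Ki = Ki,
                 sigma2_e = sigma2_e, fixed_curve = fixed_curve,
                 wave_ages = sort(wave_ages), mean_measures = mean_measures,
                 sd_measures = sd_measures, min_measures = min_measures,
                 jitter_sd = jitter_sd, dropout_beta = dropout_beta,
                 standardizer = standardizer),
            class = "sim_config")
}

#' Default sex-specific mean log-BMI curves
#'
#' Coefficients on the k = 4 scaled Legendre basis of standardized age chosen
#' to reproduce a realistic childhood BMI trajectory: BMI about 17 kg/m^2 at
#' age 1, a nadir near 15.5 around the adiposity rebound (age 5-6), rising to
#' about 21.5 by 18 years; boys run slightly below girls in BMI through
#' mid-childhood. The clinic source offset is a small positive shift relative
#' to questionnaire reports (self-report tends to understate weight).
#'
#' @return List with \code{female}, \code{male} (length-4 coefficient
#'   vectors) and \code{source_offset}.
#' @export
default_fixed_curve <- function() {
  # least-squares projection of anchor curves onto the basis, precomputed:
  # ages  1    3    5.5  9    13    18
  # F bmi 17.0 15.8 15.6 16.8 19.0  21.6
  # M bmi 17.2 15.9 15.5 16.6 18.6  21.3
  list(female = c(4.0596, 0.1445, 0.0511, -0.0301),
       male = c(4.0446, 0.1319, 0.0571, -0.0289),
       source_offset = 0.01)
}

#' Default measurement wave ages
#'
#' Dense waves in infancy (1-2 years) and from age 7 to 18, sparse coverage
#' at 3-6 years, mimicking a birth cohort with questionnaire-heavy early
#' follow-up and clinic visits through adolescence.
#'
#' @return Numeric vector of wave ages in years.
#' @export
default_wave_ages <- function() {
  c(1, 1.25, 1.5, 2, 3.5, 5, 6.5, 7, 7.5, 8, 8.5, 9, 9.75, 10.5,
    11.75, 12.75, 13.75, 15, 16, 17, 17.75)
}

#' Simulate unlinked SNP genotypes
#'
#' Hard-call genotypes in \{0, 1, 2\}: SNP i is Binomial(2, p_i) with
#' p_i ~ Uniform(maf_range), independent across SNPs (no linkage
#' disequilibrium) and individuals (no structure).
#'
#' @param n Number of individuals (>= 2).
#' @param m_snps Number of SNPs (>= 1).
#' @param maf_range Allele frequency range within (0, 0.5].
#' @param seed Integer RNG seed.
#' @return A \code{\link{genotype_panel}} with attribute \code{"freqs"}
#'   holding the drawn allele frequencies.
#' @export
simulate_genotypes <- function(n, m_snps, maf_range = c(0.05, 0.5), seed = 1) {
  if (n < 2 || m_snps < 1) stop("need n >= 2 individuals and m_snps >= 1")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop("maf_range must lie within (0, 0.5]")
  }
  set.seed(seed)
  p <- stats::runif(m_snps, maf_range[1], maf_range[2])
  G <- matrix(stats::rbinom(n * m_snps, 2, rep(p, each = n)), n, m_snps)
  panel <- genotype_panel(G, iids = sprintf("ind%04d", seq_len(n)),
                          snp_ids = sprintf("snp%05d", seq_len(m_snps)))
  attr(panel, "freqs") <- p
  panel
}

#' Simulate a longitudinal cohort from the generative random regression model
#'
#' Runs the random regression model forwards. Genetic coefficients are built
#' from per-SNP effects: \eqn{\alpha_g = W U}, where W is the
#' column-standardized genotype matrix and U holds i.i.d. per-SNP effect
#' vectors drawn MVN(0, Kg / M); their covariance across individuals is then
#' exactly \eqn{A \otimes K_g} for the realized GRM A. Individual
#' coefficients are i.i.d. MVN(0, Ki). Each measurement is
#' \deqn{y = \mathrm{curve}_{sex}(m) + \mathrm{source} +
#'   \phi(m)'\alpha_g + \phi(m)'\alpha_i + e,\quad e \sim N(0, \sigma^2_e).}
#' Measurement counts are rounded Normal(10.5, 3.8) truncated to
#' [min_measures, n_waves]; each individual attends a random subset of waves
#' of that size; optional informative dropout removes post-childhood waves
#' with probability increasing in the individual's age-18 genetic value.
#'
#' @param panel Genotypes from \code{\link{simulate_genotypes}} (or any
#'   \code{genotype_panel}).
#' @param config A \code{\link{sim_config}}.
#' @param seed Integer RNG seed.
#' @return List with \code{pheno} (long table: iid, sex, age, source, bmi,
#'   log_bmi) and \code{truth} (class \code{sim_truth}): \code{alpha_g}
#'   (N x k_g), \code{alpha_i} (N x k_i), \code{snp_effects} (M x k_g),
#'   \code{grm} (realized), \code{config}.
#' @export
simulate_cohort <- function(panel, config, seed = 1) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "sim_config"))
  set.seed(seed)
  G <- panel$geno
  n <- nrow(G); m <- ncol(G)
  kg <- nrow(config$Kg); ki <- nrow(config$Ki)

  p <- colMeans(G) / 2
  keep <- p > 0 & p < 1
  W <- sweep(G[, keep, drop = FALSE], 2, 2 * p[keep])
  W <- sweep(W, 2, sqrt(2 * p[keep] * (1 - p[keep])), `/`)
  M_used <- ncol(W)

  U <- rmvnorm_chol(M_used, rep(0, kg), config$Kg / M_used)
  alpha_g <- W %*% U
  alpha_i <- rmvnorm_chol(n, rep(0, ki), config$Ki)
  A <- tcrossprod(W) / M_used
  dimnames(A) <- list(panel$iids, panel$iids)

  sex <- sample(c("F", "M"), n, replace = TRUE)
  n_waves <- length(config$wave_ages)
  counts <- pmin(pmax(round(stats::rnorm(n, config$mean_measures,
                                         config$sd_measures)),
                      config$min_measures), n_waves)

  # informative dropout: each post-childhood wave lost with probability
  # rising in the individual's age-18 genetic value (standardized)
  m18 <- 1
  phi18 <- basis_matrix(m18, kg)
  g18 <- drop(alpha_g %*% t(phi18))
  g18s <- if (stats::sd(g18) > 0) (g18 - mean(g18)) / stats::sd(g18) else g18 * 0

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    waves <- sort(sample.int(n_waves, counts[i]))
    ages <- config$wave_ages[waves] +
      stats::rnorm(counts[i], 0, config$jitter_sd)
    ages <- pmin(pmax(ages, config$standardizer$min_age),
                 config$standardizer$max_age)
    if (config$dropout_beta != 0) {
      late <- ages > 7
      p_drop <- stats::plogis(stats::qlogis(0.1) +
                                config$dropout_beta * g18s[i])
      lost <- late & stats::runif(length(ages)) < p_drop
      # never drop below the minimum number of measurements
      if (sum(!lost) >= config$min_measures) {
        ages <- ages[!lost]
      }
    }
    rows[[i]] <- data.frame(iid = panel$iids[i], sex = sex[i], age = ages,
                            stringsAsFactors = FALSE)
  }
  pheno <- do.call(rbind, rows)
  nrec <- nrow(pheno)
  mstd <- standardize_age(pheno$age, config$standardizer)
  Phif <- basis_matrix(mstd, 4)
  Phig <- Phif[, seq_len(kg), drop = FALSE]
  Phii <- Phif[, seq_len(ki), drop = FALSE]
  i_of <- match(pheno$iid, panel$iids)
  fixed <- ifelse(pheno$sex == "M",
                  Phif %*% config$fixed_curve$male,
                  Phif %*% config$fixed_curve$female)
  pheno$source <- sample(c("questionnaire", "clinic"), nrec, replace = TRUE)
  y <- drop(fixed) +
    config$fixed_curve$source_offset * (pheno$source == "clinic") +
    rowSums(Phig * alpha_g[i_of, , drop = FALSE]) +
    rowSums(Phii * alpha_i[i_of, , drop = FALSE]) +
    stats::rnorm(nrec, 0, sqrt(config$sigma2_e))
  pheno$log_bmi <- y
  pheno$bmi <- exp(y)
  pheno <- pheno[, c("iid", "sex", "age", "source", "bmi", "log_bmi")]

  truth <- structure(list(alpha_g = alpha_g, alpha_i = alpha_i,
                          snp_effects = U, snp_kept = which(keep),
                          grm = structure(list(A = A, iids = panel$iids,
                                               n_snps = M_used),
                                          class = "grm"),
                          config = config),
                     class = "sim_truth")
  list(pheno = pheno, truth = truth)
}

# Draw genetic coefficients by a direct Cholesky of A (x) Kg; the small-N
# reference path for validating the SNP-effect construction.
simulate_alpha_g_direct <- function(A, Kg, seed = 1) {
  N <- nrow(A)
  kg <- nrow(Kg)
  set.seed(seed)
  Sigma <- kronecker(A, Kg)
  z <- rmvnorm_chol(1, rep(0, N * kg), Sigma)
  matrix(z, N, kg, byrow = TRUE)
}

#' Simulate an external adult-trait PGS weight table
#'
#' Substitute for published adult-BMI SNP weights: the true per-SNP effects
#' are projected onto the age-18 direction of the basis (\eqn{U \phi(1)}),
#' then independent noise is added, scaled so that the resulting score
#' explains a target fraction (default 0.16) of the simulated age-18
#' phenotypic variance.
#'
#' @param truth A \code{sim_truth} from \code{\link{simulate_cohort}}.
#' @param target_r2 Variance in the age-18 phenotype explained by the score
#'   (default 0.16). Must not exceed the age-18 heritability.
#' @param seed Integer RNG seed.
#' @return Data frame with \code{snp} (column index into the panel) and
#'   \code{weight}.
#' @export
simulate_adult_pgs_weights <- function(truth, target_r2 = 0.16, seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  if (target_r2 < 0) stop("target_r2 must be non-negative")
  cfg <- truth$config
  kg <- nrow(cfg$Kg); ki <- nrow(cfg$Ki)
  phi18g <- drop(basis_matrix(1, kg))
  phi18i <- drop(basis_matrix(1, ki))
  vg18 <- drop(t(phi18g) %*% cfg$Kg %*% phi18g)
  vp18 <- vg18 + drop(t(phi18i) %*% cfg$Ki %*% phi18i) + cfg$sigma2_e
  if (target_r2 > vg18 / vp18 + 1e-12) {
    stop(sprintf("target_r2 exceeds the age-18 heritability (%.3f)", vg18 / vp18))
  }
  w_true <- drop(truth$snp_effects %*% phi18g)
  M <- length(w_true)
  if (target_r2 == 0) {
    noise_var <- Inf
  } else {
    noise_var <- vg18^2 / (target_r2 * vp18) - vg18
  }
  set.seed(seed)
  w <- if (is.finite(noise_var)) {
    w_true + stats::rnorm(M, 0, sqrt(noise_var / M))
  } else {
    stats::rnorm(M, 0, 1)
  }
  data.frame(snp = truth$snp_kept, weight = w)
}

#' Per-individual polygenic score from a weight table
#'
#' Weighted sum of column-standardized allele counts over the provided SNP
#' weights (weights on the standardized scale, matching
#' \code{\link{simulate_adult_pgs_weights}}).
#'
#' @param panel A \code{genotype_panel}.
#' @param weights Data frame with \code{snp} (column index or SNP id) and
#'   \code{weight}.
#' @return Named numeric vector of scores (names = iids).
#' @export
polygenic_score <- function(panel, weights) {
  stopifnot(inherits(panel, "genotype_panel"))
  idx <- if (is.numeric(weights$snp)) weights$snp
         else match(as.character(weights$snp), panel$snp_ids)
  if (any(is.na(idx))) stop("weight table refers to SNPs absent from the panel")
  G <- panel$geno[, idx, drop = FALSE]
  p <- colMeans(G, na.rm = TRUE) / 2
  W <- sweep(G, 2, 2 * p)
  W[is.na(W)] <- 0
  W <- sweep(W, 2, sqrt(pmax(2 * p * (1 - p), 1e-12)), `/`)
  stats::setNames(drop(W %*% weights$weight), panel$iids)
}
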