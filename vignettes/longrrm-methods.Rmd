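---
title: "Random regression models for the genetics of longitudinal BMI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random regression models for the genetics of longitudinal BMI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longrrm)
```

## The model

`longrrm` estimates how the genetic architecture of a longitudinal trait —
the motivating case is childhood body mass index (BMI), measured repeatedly
and irregularly between ages 1 and 18 — changes with age. Each individual's
log-BMI trajectory is a population mean curve plus two individual
departures, all expressed on a basis of normalized Legendre polynomials of
standardized age:

$$y = Xb + Z_g g + Z_i i + e,$$

where $y$ stacks all $n$ measurements, $X$ holds the fixed effects (cubic
Legendre polynomials, sex and its interactions with every polynomial, and a
questionnaire/clinic measurement-source indicator), and the random vectors
are per-individual regression coefficients on the first $k_g$ (genetic) and
$k_i$ (individual-specific environment plus untagged genetics) basis
functions:

$$\mathrm{var}(g) = A \otimes K_g,\qquad
  \mathrm{var}(i) = I_N \otimes K_i,\qquad
  \mathrm{var}(e) = I_n\,\sigma^2_e,$$

with $A$ the genomic relationship matrix (GRM) from common SNPs. $K_g$ is
the genetic covariance *function* in coefficient space: transformed through
the basis, $\Phi K_g \Phi'$, it gives the additive genetic covariance
between any two ages, from which age-varying SNP heritability, genetic
correlation surfaces, and eigenfunctions of genetic variation all follow.

Ages are standardized to $m \in [-1, 1]$ over a configurable window
(default 1–18 years); the standardizer is stored inside every fit so
downstream transforms are self-describing. The basis is
$\Phi = M\Lambda$, where $M$ holds powers $m^0 \dots m^{k-1}$ and $\Lambda$
(computed from the Bonnet recurrence, never hard-coded) scales the degree-$j$
Legendre polynomial by $\sqrt{(2j+1)/2}$ so the basis is orthonormal on
$[-1,1]$.

## REML estimation

Variance parameters are estimated by restricted maximum likelihood. The
implementation exploits two structures:

* **Individual effects are block-diagonal.** They are marginalized
  analytically into per-individual covariance blocks
  $V_j = \Phi_j K_i \Phi_j' + R_j$ (at most a few dozen rows each), so the
  dense system that remains is only $p + N k_g$ — Henderson mixed-model
  equations with $(A^{-1} \otimes K_g^{-1})$ added to the genetic block.
* **The quadratic form is computed in residual form.**
  $y'Py = r'\tilde V^{-1} r + \hat g'(A^{-1}\otimes K_g^{-1})\hat g$ rather
  than the textbook $y'\tilde V^{-1}y - \hat\theta' W'\tilde V^{-1} y$: with
  an uncentered response the subtractive form loses about three digits to
  cancellation, which puts a noise floor on the likelihood well above the
  convergence tolerance.

The optimizer is five EM-REML warm-up iterations followed by
average-information (AI) Newton steps. Steps are taken on a log-Cholesky
scale ($K = LL'$ with log-transformed diagonal of $L$, log residual
variances), which keeps every candidate inside the parameter space, with
Levenberg–Marquardt damping: when a step fails to increase the restricted
likelihood the damping is raised and the step re-solved (not merely
shortened along a fixed, possibly bad, direction), and an EM step is the
fallback of last resort since it can never decrease the likelihood.
Convergence requires $|\Delta \log L| < 10^{-6}$ *and* a maximum parameter
change below $10^{-4}$ relative to each parameter's magnitude (floored at
its sampling SE, so wobble along likelihood-flat directions does not block
termination).

### Boundary solutions

The genetic covariance of childhood BMI is dominated by its first principal
component, so at reduced sample sizes the REML optimum frequently sits *on*
the PSD boundary (rank-deficient $\hat K_g$). Two protections apply:
covariance eigenvalues are floored at $10^{-7}\,\mathrm{var}(y)$ (pure
numerical conditioning; far below any sampling SE), and a boundary-stall
rule ends the fit with status `converged_boundary` after six consecutive
iterations in which parameters are stationary relative to their SEs while
the likelihood still creeps along the constraint. Interior optima terminate
under the primary rule. A related caveat: PSD-constrained REML is biased
upward for weakly identified components (truncating negative eigenvalue
directions can only add variance), which is visible in the desk-scale
recovery simulations for the smallest elements of $K_g$ and disappears at
study-scale $N$.

A GRM standardized with in-sample allele frequencies is intrinsically
singular (centering puts the ones vector in its null space), and the
mixed-model equations need $A^{-1}$; the GRM is therefore *bent* with a
deterministic ridge of $10^{-6} \times$ its mean diagonal before inversion,
escalated only if still not positive definite. The effect on estimates is of
order $10^{-6}$.

The sampling covariance of the variance parameters is the inverse AI matrix
at the optimum, over the half-vectorized parameters in **diagonal-major
order** — diagonals first, then the lower triangle row-wise:
$(1,1), (2,2), (3,3), (2,1), (3,1), (3,2)$ — followed by vech($K_i$) and the
residual term(s). Every consumer of a sampling covariance in the package
(`variance_share_test()`, `eigenvalue_ci()`, `delta_method_se()`,
`age_scale_surfaces()`) uses this same ordering; see `?vech`.

AIC is $-2\log L_{REML} + 2q$ with $q$ the number of *variance* parameters
(REML likelihoods are functions of the variance parameters only; the
fixed-effect count is constant across the model menu being compared).
Likelihood-ratio tests between nested variance structures use a naive
$\chi^2$ reference with df equal to the difference in variance-parameter
count; because reduced models often sit on the parameter-space boundary the
naive p-value is conservative and every comparison carries a
`boundary_caveat` flag.

## Age-scale transforms

With $\hat K_g$, $\hat K_i$ and $\hat\sigma^2_e$ in hand,

$$\hat V_g = \Phi \hat K_g \Phi', \quad \hat V_i = \Phi \hat K_i \Phi',
\quad \hat V_P = \hat V_g + \hat V_i + \hat\sigma^2_e I,$$

on any age grid (the covariance function is continuous, so values at shared
ages are grid-independent; the default is the 18 yearly ages). Heritability
is the diagonal ratio $\hat V_g / \hat V_P$; genetic and phenotypic
correlations are the usual normalized off-diagonals. The residual variance
enters only the phenotypic *diagonal*; for the heterogeneous-residual model
(one residual variance per whole year of age, 17 bins on the default
window) the bin value at each grid age is used — the scalar formula
generalized in the obvious way. Standard errors come from a first-order
Taylor (delta-method) expansion with central-difference gradients (relative
step $10^{-6}$) against the full REML sampling covariance, including the
$K_i$ and residual blocks (published analyses are often ambiguous about
whether ratio quantities like $r_g$ used only the $K_g$ block; the full
covariance is the conservative choice). Confidence intervals are
the untransformed estimate $\pm 1.96\,\mathrm{SE}$, which can overshoot
natural boundaries near $h^2 = 0$ or $|r_g| = 1$.

## Genetic principal components

`decompose_kg()` eigendecomposes $K_g = EDE'$; the variance shares
$D_j/\sum D$ say how much genetic variation each independent axis explains
(for the published childhood-BMI estimates: 89%, 8.7%, 2.2%). Eigenvector
signs are fixed so each vector's largest-magnitude entry is positive — any
convention is arbitrary; this one is reproducible. Eigenfunctions
$\psi_j(m)$ have monomial coefficients $\Lambda E$ and make the axes
readable as functions of age (the second axis changes sign near 11.5 years:
opposite genetic effects in infancy versus adolescence).

The trailing-eigenvalue test zeroes the $q$ smallest eigenvalues and refers
$\mathrm{vech}(K_g - K_g^*)' S^{-1} \mathrm{vech}(K_g - K_g^*)$ to
$\chi^2_{q(q+1)/2}$. A derivation worth recording: with
$\Delta = \hat\lambda_3\, e_3 e_3'$ to first order, the statistic is
$(d'\varepsilon)^2\, w'S^{-1}w$ with $d$ the duplication-weighted and $w$
the plain vech of $e_3 e_3'$; it is $\chi^2_1$-calibrated exactly when
$(d'Sd)(w'S^{-1}w)=1$, which holds for sampling covariances of Wishart form
$\mathrm{Cov}(K_{ab},K_{cd}) = (K_{ac}K_{bd}+K_{ad}K_{bc})/n_{\mathrm{eff}}$
— the structure REML asymptotics produce — but not for an arbitrary S. The
calibration test therefore simulates under a Wishart-form S at a
non-singular reference matrix.

Eigenvalue confidence intervals are by simulation: draw
$\mathrm{vech}(K_g)$ from its asymptotic normal, rebuild, eigendecompose,
take empirical quantiles of the shares. Non-PSD draws are discarded and
counted (default), or eigenvalue-floored with `psd_mode = "project"`; an
error is raised if more than half the draws are non-PSD under discard mode,
since the quantiles would then describe a severely truncated distribution.

PC polygenic scores are $\hat G = \hat\alpha E$ — per-individual BLUPs of
the genetic coefficients projected on the eigenvectors — with individuals
stratified at one SD around the mean score per PC, and stratum mean genetic
trajectories reported on the age grid.

## The synthetic cohort

`simulate_cohort()` runs the generative model forwards, and its defaults
*are* the emulated study conditions:

* genetic covariance $K_g$ at the published point estimates (component
  variances 0.0073 / 0.0017 / 0.0004; correlations 0.682 / −0.678 / −0.473);
* $K_i = \mathrm{diag}(0.0144, 0.0054, 0.0037)$, back-solved from the
  published per-component heritabilities (28.4 / 23.8 / 9.8%) with
  $\sigma^2_e = 0.004$. The back-solve inherits the rounding of its printed
  inputs: the implied $h^2$ at the window midpoint is 0.278 versus the
  published 0.284. Recovery tests target the generative truth, not the
  rounded headline;
* sex-specific cubic mean curves anchored to a realistic BMI trajectory
  (≈17 kg/m² at age 1, nadir ≈15.6 near the adiposity rebound at 5–6 y,
  ≈21.6 by 18 y), boys slightly below girls through mid-childhood, and a
  +0.01 log-BMI clinic source offset (self-report understates weight);
* measurement counts of rounded Normal(10.5, 3.8) truncated to at least 4,
  on waves dense at 1–2 y and 7–18 y and sparse at 3–6 y, with 0.1 y age
  jitter — the questionnaire-heavy early follow-up of a birth cohort.

Genetic coefficients are built from per-SNP effects,
$\alpha_g = W U$ with $U_{M \times k_g} \sim N(0, K_g/M)$ i.i.d. across
SNPs and $W$ the column-standardized genotypes, so
$\mathrm{var}(\alpha_g) = A \otimes K_g$ holds *exactly* for the realized
GRM without an $N \times N$ Cholesky; a direct Cholesky path exists for
small-$N$ equivalence testing. Dropout is missing-completely-at-random by
default; `dropout_beta` makes the loss of post-childhood waves depend on
the individual's age-18 genetic value, for probing sensitivity to the
missing-at-random assumption.

What the generator does **not** emulate: linkage disequilibrium (SNPs are
independent), population structure or relatedness, genotype missingness,
imputation uncertainty, real measurement-error heteroscedasticity, secular
trends, or non-Gaussian BMI tails. A green recovery test therefore
establishes that the estimation machinery inverts the stated generative
model at desk scale — not that the pipeline is robust to the complications
of real cohort data.

The substitute adult-trait PGS weights are the true per-SNP effects
projected onto the age-18 basis direction plus independent noise scaled so
the score explains a target fraction (default 16%) of simulated age-18
phenotypic variance; this requires the target not to exceed the age-18
heritability (≈0.21 under the defaults).

## Phenotype cleaning

The implausible-value screen is a deliberately simple stand-in for
dedicated growth-cleaning software: each measurement is compared with an
exponentially weighted average of the same individual's other measurements
(weights halving per `window = 2` years of age distance) and flagged beyond
`z = 4` robust SDs. The robust scale is the individual's MAD floored at
half the cohort-wide value — a pure per-individual MAD over ≤ 18 points is
unstable enough to break the ≤ 1% false-flag requirement. Inclusion rules
run window-first (drop measurements outside 1–18 y, then individuals with
fewer than 4 remaining measurements — enough to fit a cubic); the order is
not dictated by the source analysis, but window-first matches the stated
purpose of the 4-measurement rule and the filters are idempotent.

## GWAS on derived phenotypes

The two-step design deliberately avoids a mixed-model association test: a
reduced model (individual effects only, no GRM) supplies per-individual
BLUPs of intercept, linear and quadratic coefficients; PC1/PC2 phenotypes
are their linear combinations with eigenvector weights; each derived
phenotype is tested per SNP by OLS with the top 10 GRM principal components
as covariates. Excluding the GRM from phenotype derivation avoids
re-introducing genetic structure into the phenotype, and the intercept of
the genomic-control diagnostic ($\lambda_{GC}$, median association
$\chi^2 / 0.45494$) should be near 1 under the null — reproduced on
synthetic data within [0.95, 1.05]. Lead SNPs are reported by positional
clumping (lowest p within 1 Mb); gene annotation is out of scope.

## Numerical choices and degenerate inputs, collected

* Ages exactly at the window endpoints standardize to ±1 and are retained.
* `lambda_matrix()` is analytic; the printed 4-decimal version of the
  order-4 matrix (one entry −2.8067 vs analytic −2.80624) is treated as a
  1e−3-tolerance test fixture, never used in computation.
* Monomorphic SNPs are a hard error in `build_grm()` (run `snp_qc()`
  first); missing genotypes are mean-imputed to $2\hat p$ so they
  contribute zero to the relationship.
* Empty residual-year bins merge into their lower neighbour with a warning.
* An all-zero (degenerate) external PGS would make the design rank
  deficient; the PGS fixed effects are dropped with a warning so the
  adjusted fit equals the unadjusted one.
* Relatedness pruning is greedy max-degree with seeded random tie-breaks;
  the kept set provably has no pair above the cutoff.
* The HWE filter is an exact (conditional enumeration) test on hard calls;
  the INFO filter is inert for synthetic hard calls and documented as such.

## Known limitations

Sex-stratified variance components, spline bases, non-Gaussian residuals,
LD-aware simulation, LDSC-based external genetic correlations and gene
annotation are all out of scope. The per-year residual model estimates 17
extra parameters and is noticeably less stable at small $N$; boundary fits
report `converged_boundary` status and their LRT p-values should be read
with the boundary caveat in mind. At desk scale the PSD constraint biases
the smallest genetic covariance elements upward (see the boundary
discussion above); conclusions about the smallest eigenvalue of $K_g$ need
study-scale samples.
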