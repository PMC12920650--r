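Package: longrrm
Title: Genomic Random Regression Models for Longitudinal Traits
Version: 0.1.0
Authors@R:
    person("longrrm", "developers", email = "longrrm@example.org", role = c("aut", "cre"))
Description: Tools for estimating the age-varying genetic architecture of
    longitudinal traits (such as childhood log-BMI) with random regression
    models on a normalized Legendre polynomial basis. Implements AI-REML
    estimation of Kronecker-structured additive-genetic (GRM x Kg) and
    individual-specific (I x Ki) covariance functions, back-transformation
    of variance components to age-scale heritability and correlation
    surfaces with delta-method standard errors, eigenfunction principal
    component analysis of the genetic covariance function, principal
    component polygenic scores, adult-PGS-adjusted fits, and genome-wide
    association on BLUP-derived trajectory phenotypes. Includes a synthetic
    cohort generator, phenotype cleaning filters, SNP QC, GRM construction
    with GCTA-compatible binary I/O, and PLINK bed/bim/fam I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
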