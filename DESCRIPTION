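Package: invasionQG
Title: Quantitative Genetics of Invasive Plant Traits from Partial Diallel Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evolutionary quantitative genetics of invasive plant
    populations studied with partial diallel breeding designs. Builds and
    validates reciprocal partial diallel crossing schemes, pedigrees and
    additive relationship matrices; simulates complete breeding experiments
    from a known additive G-matrix (parental breeding values, Mendelian
    sampling, family, block, range and climate effects) so every estimator can
    be checked by parameter recovery; derives and standardizes plant traits
    and fits the seed drop-time regression with partial-F model selection;
    fits divergence linear mixed models and univariate pedigree animal models
    by REML with likelihood-ratio tests for additive variance; estimates
    multivariate G-matrix posteriors with a Gibbs sampler under half-Cauchy
    style priors and structural zero residual covariances; and computes
    evolvability along sign-constrained random selection gradients together
    with the R metric of genetic constraint or facilitation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    lme4,
    car,
    emmeans,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    withr,
    jsonlite
Config/testthat/edition: 3
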