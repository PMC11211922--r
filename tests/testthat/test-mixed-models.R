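test_that("REML engine matches closed-form ANOVA on a balanced one-way layout", {
  set.seed(15)
  a <- 30; n <- 8
  grp <- rep(seq_len(a), each = n)
  y <- rnorm(a, sd = sqrt(0.6))[grp] + rnorm(a * n, sd = 1)
  anova_est <- oneway_anova_components(y, grp)
  Z <- model.matrix(~0 + factor(grp))
  fit <- reml_varcomp(y, matrix(1, length(y)), list(group = tcrossprod(Z)))
  expect_equal(unname(fit$sigma2["group"]), unname(anova_est["group"]),
               tolerance = 1e-6)
  expect_equal(unname(fit$sigma2["residual"]), unname(anova_est["residual"]),
               tolerance = 1e-6)
  # and agrees with lme4 as a second, independent REML implementation
  lmm <- lme4::lmer(y ~ 1 + (1 | g), data = data.frame(y = y, g = grp))
  vc <- as.data.frame(lme4::VarCorr(lmm))$vcov
  expect_equal(unname(fit$sigma2), vc, tolerance = 1e-5)
  expect_equal(fit$logLik, as.numeric(logLik(lmm)), tolerance = 1e-5)
})

test_that("REML estimates are invariant to record order and factor relabeling", {
  z <- sim_one_population(groups = 2, seed = 18, trait_names = "t",
                          family_traits = character(0), G_a = matrix(0.4),
                          germination_dropout = 0)
  A <- additive_relationship(z$sim$pedigree)
  fit1 <- fit_animal_model("t", z$ph, A)
  perm <- z$ph[sample(nrow(z$ph)), ]
  fit2 <- fit_animal_model("t", perm, A)
  expect_equal(fit1$sigma2_a, fit2$sigma2_a, tolerance = 1e-6)
  expect_equal(fit1$logLik, fit2$logLik, tolerance = 1e-6)

  # relabeling dam/sire levels leaves a divergence LMM's fixed effects alone
  set.seed(77)
  tab <- sim_dam_sire_table(range_effect = 0.4, traits = "t1")
  f1 <- fit_lmm(lmm_spec("value", c("range", "climate"), c("dam", "sire")), tab)
  tab2 <- tab
  tab2$dam <- paste0("zz_", tab2$dam)
  tab2$sire <- factor(tab2$sire, levels = sample(unique(tab2$sire)))
  f2 <- fit_lmm(lmm_spec("value", c("range", "climate"), c("dam", "sire")), tab2)
  expect_equal(f1$fixef$estimate, f2$fixef$estimate, tolerance = 1e-6)
})

test_that("divergence LMM recovers null and nonnull dam/sire structure", {
  set.seed(5)
  tab <- sim_dam_sire_table(n_dams = 20, n_sires = 20, sd_dam = 0, sd_sire = 0,
                            traits = "t1")
  fit <- fit_lmm(lmm_spec("value", c("range", "climate"), c("dam", "sire")), tab)
  expect_lt(fit$varcomp[["dam"]], 0.05)
  expect_lt(fit$varcomp[["sire"]], 0.05)

  # simulated range effect of 0.5 SD recovered within 2 SE
  set.seed(6)
  tab2 <- sim_dam_sire_table(n_dams = 23, n_sires = 22, range_effect = 0.5,
                             traits = "t1")
  fit2 <- fit_lmm(lmm_spec("value", c("range", "climate"), c("dam", "sire")), tab2)
  i <- grep("^range", fit2$fixef$term)
  expect_lt(abs(abs(fit2$fixef$estimate[i]) - 0.5), 2 * fit2$fixef$se[i])

  expect_error(fit_lmm(lmm_spec("value", "range", "nonexistent"), tab),
               "lacks columns")
  tab$one_level <- "x"
  expect_error(fit_lmm(lmm_spec("value", "range", "one_level"), tab),
               "< 2 levels")
})

test_that("stacked-trait divergence test finds interaction only when present", {
  set.seed(30)
  null_tab <- sim_dam_sire_table(range_effect = 0, traits = c("t1", "t2"))
  mv0 <- multivariate_divergence_test(null_tab)
  expect_true(all(c("trait", "range", "trait:range") %in% mv0$wald$term))

  # trait-specific range effects -> significant interaction at 200 families
  set.seed(31)
  tab <- sim_dam_sire_table(n_dams = 15, n_sires = 14, traits = c("t1", "t2"))
  shift <- ifelse(tab$trait == "t1", 0.6, -0.6)
  tab$value <- tab$value + shift * (tab$range == "invasive")
  mv <- multivariate_divergence_test(tab)
  expect_lt(mv$wald$p[mv$wald$term == "trait:range"], 1e-4)

  expect_error(multivariate_divergence_test(null_tab[null_tab$trait == "t1", ]),
               ">= 2 traits")
  expect_error(multivariate_divergence_test(null_tab[null_tab$range == "native", ]),
               "both ranges")
})

test_that("stacked-trait interaction test holds its size under the null", {
  set.seed(8)
  pvals <- replicate(120, {
    tab <- sim_dam_sire_table(n_dams = 8, n_sires = 8, range_effect = 0.3,
                              traits = c("t1", "t2"))
    mv <- multivariate_divergence_test(tab)
    mv$wald$p[mv$wald$term == "trait:range"]
  })
  rate <- mean(pvals < 0.05)
  # 3 binomial SE around 5% at 120 replicates
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 120))
})

test_that("per-trait range effects apply the Bonferroni threshold", {
  set.seed(40)
  tab <- sim_dam_sire_table(n_dams = 18, n_sires = 18, range_effect = 0.8,
                            traits = c("t1", "t2"))
  res <- univariate_range_effects(tab)
  expect_equal(res$bonferroni_alpha, rep(0.05 / 2, 2))
  expect_true(all(res$significant))

  res1 <- univariate_range_effects(tab, traits = "t1")
  expect_equal(res1$bonferroni_alpha, 0.05)
  # threshold for a 10-trait study is 0.005
  expect_equal(0.05 / 10, 0.005)
})

test_that("Bonferroni keeps the familywise error below the nominal level", {
  set.seed(41)
  famwise <- replicate(120, {
    tab <- sim_dam_sire_table(n_dams = 7, n_sires = 7, range_effect = 0,
                              traits = c("t1", "t2", "t3"))
    any(univariate_range_effects(tab)$significant)
  })
  expect_lt(mean(famwise), 0.05 + 3 * sqrt(0.05 * 0.95 / 120))
})

test_that("population contrasts give shared letters to identical populations", {
  set.seed(50)
  base <- sim_dam_sire_table(n_dams = 10, n_sires = 10, traits = "t")
  base$population <- rep(c("p1", "p2", "p3"), length.out = nrow(base))
  base$value[base$population == "p3"] <- base$value[base$population == "p3"] + 2
  pc <- posthoc_population_contrasts(base)
  # p1 and p2 are exchangeable -> share a letter; p3 shifted +2 SD -> distinct
  expect_true(any(strsplit(pc$letters[["p1"]], "")[[1]] %in%
                  strsplit(pc$letters[["p2"]], "")[[1]]))
  expect_false(any(strsplit(pc$letters[["p3"]], "")[[1]] %in%
                   strsplit(pc$letters[["p1"]], "")[[1]]))
  # letters are invariant to population relabeling order
  perm <- base[sample(nrow(base)), ]
  pc2 <- posthoc_population_contrasts(perm)
  expect_equal(pc$letters[sort(names(pc$letters))],
               pc2$letters[sort(names(pc2$letters))])
  expect_error(posthoc_population_contrasts(base[base$population == "p1", ]),
               ">= 2 populations")
})

test_that("animal model recovers additive variance and absorbs it without pedigree signal", {
  z <- sim_one_population(groups = 6, seed = 61, trait_names = "t",
                          family_traits = character(0), G_a = matrix(0.4),
                          sigma2_na = 0.05, sigma2_e = 0.55,
                          germination_dropout = 0)
  A <- additive_relationship(z$sim$pedigree)
  fit <- fit_animal_model("t", z$ph, A, se = TRUE)
  expect_true(fit$converged)
  expect_equal(sum(fit$proportions), 1)
  expect_lt(abs(fit$sigma2_a - 0.4), 3 * fit$se[["additive"]] + 0.05)

  # identity A: no pedigree signal; additive and residual are confounded and
  # the fit is likelihood-equivalent to a family + residual model
  I_A <- diag(nrow(z$ph))
  dimnames(I_A) <- list(z$ph$id, z$ph$id)
  fit_I <- fit_animal_model("t", z$ph, I_A)
  fit_0 <- fit_animal_model_null("t", z$ph)
  expect_equal(fit_I$logLik, fit_0$logLik, tolerance = 1e-4)
  expect_equal(fit_I$sigma2_a + fit_I$sigma2_e, fit_0$sigma2_e, tolerance = 1e-3)
  expect_equal(fit_I$sigma2_na, fit_0$sigma2_na, tolerance = 1e-3)

  expect_error(fit_animal_model("t", z$ph, A[1:10, 1:10]), "cover")
})

test_that("boundary LRT behaves at the identical-fit and strong-signal extremes", {
  z <- sim_one_population(groups = 10, seed = 62, trait_names = "t",
                          family_traits = character(0), G_a = matrix(0.5),
                          sigma2_na = 0.05, sigma2_e = 0.45,
                          germination_dropout = 0)
  A <- additive_relationship(z$sim$pedigree)
  full <- fit_animal_model("t", z$ph, A)
  null <- fit_animal_model_null("t", z$ph)
  lt <- test_additive_variance(full, null)
  expect_lt(lt$p, 0.001)              # strong true signal at this design size
  expect_equal(lt$stars, "***")

  ident <- test_additive_variance(full, full)
  expect_equal(ident$lrt, 0)
  expect_equal(ident$p, 0.5)

  worse <- full; worse$logLik <- null$logLik - 1
  expect_error(test_additive_variance(worse, null), "convergence")
})

test_that("divergence on V_A regression handles exact, degenerate and noisy input", {
  va <- c(a = 0.1, b = 0.2, c = 0.3, d = 0.4)
  div <- 2 * va                       # perfectly collinear
  fit <- suppressWarnings(divergence_va_regression(div, va))
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$slope, 2, tolerance = 1e-10)

  const <- c(a = 0.3, b = 0.3, c = 0.3, d = 0.3)
  degen <- divergence_va_regression(div, const)
  expect_true(degen$degenerate)
  expect_true(is.na(degen$slope))

  set.seed(70)
  va10 <- setNames(runif(10, 0.1, 0.6), letters[1:10])
  div10 <- 2 * va10 + rnorm(10, sd = 0.05)
  noisy <- divergence_va_regression(div10, va10, exclude = c("a", "b"))
  expect_equal(noisy$slope, 2, tolerance = 0.25)
  expect_false(is.null(noisy$excluded_fit))

  expect_error(divergence_va_regression(div[1:2], va[1:2]), ">= 3")
})
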