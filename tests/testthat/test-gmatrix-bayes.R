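test_that("MCMC schedule arithmetic and validation", {
  expect_equal(retained_samples(mcmc_schedule(1000, 0, 1)), 1000)
  expect_equal(retained_samples(mcmc_schedule(315000, 15000, 300)), 1000)
  expect_error(mcmc_schedule(1100, 100, 7), "whole number")
  expect_error(mcmc_schedule(100, 100, 1), "burnin")
  expect_error(mcmc_schedule(100, 0, 0), "thin")
})

test_that("prior spec validates scales and mask", {
  p <- prior_spec(c(1, 1, 1))
  expect_false(any(p$mask))
  expect_error(prior_spec(c(1, 0)), "scales")
  m <- matrix(FALSE, 2, 2); m[1, 2] <- TRUE
  expect_error(prior_spec(c(1, 1), m), "symmetric")
  m2 <- diag(TRUE, 2)
  expect_error(prior_spec(c(1, 1), m2), "diagonal|free")
})

test_that("HPD interval is the shortest mass-covering window", {
  # uniform grid 0..99 at mass 0.9: any window of 91 points, width 90
  hp <- hpd_interval(0:99, 0.9)
  expect_equal(unname(hp["upper"] - hp["lower"]), 90)

  # symmetric unimodal sample: HPD ~ central interval (+/- 1.645 for N(0,1))
  set.seed(1)
  x <- rnorm(1e5)
  hp2 <- hpd_interval(x, 0.9)
  expect_lt(abs(hp2[["lower"]] + 1.645), 0.05)
  expect_lt(abs(hp2[["upper"]] - 1.645), 0.05)

  expect_equal(unname(hpd_interval(rep(3, 50), 0.9)), c(3, 3))
  expect_error(hpd_interval(1:100, 1.2), "mass")
  expect_error(hpd_interval(1:5, 0.9), ">= 10")
})

test_that("chain diagnostics recover independence, AR(1) memory and degeneracy", {
  set.seed(2)
  x <- rnorm(4000)
  expect_lt(abs(lag_autocorrelation(x)), 0.05)
  expect_gt(effective_sample_size(x), 3200)

  # AR(1) with rho = 0.5 built by direct recursion as the oracle
  rho <- 0.5
  ar <- numeric(6000); ar[1] <- rnorm(1)
  for (t in 2:6000) ar[t] <- rho * ar[t - 1] + rnorm(1, sd = sqrt(1 - rho^2))
  expect_equal(lag_autocorrelation(ar), rho, tolerance = 0.1)
  expect_lt(effective_sample_size(ar), 3000)

  expect_true(is.na(lag_autocorrelation(rep(1, 100))))
})

# a small shared fit used by several blocks below
small_fit <- local({
  z <- sim_one_population(groups = 2, seed = 91, germination_dropout = 0)
  post <- fit_multivariate_animal(z$ph, z$sim$pedigree, z$cfg$trait_names,
                                  z$sr, schedule = mcmc_schedule(6000, 1000, 5),
                                  seed = 17)
  list(z = z, post = post)
})

test_that("retained G samples are symmetric PSD and match the schedule count", {
  post <- small_fit$post
  expect_equal(dim(post$G)[3], 1000)
  ev <- apply(post$G, 3, function(M) {
    expect_equal(M, t(M))
    min(eigen(M, TRUE, TRUE)$values)
  })
  expect_gte(min(ev), -1e-8)
})

test_that("masked residual covariances are exactly zero in every retained sample", {
  post <- small_fit$post
  k <- match("seed_size", post$traits)
  expect_true(all(post$R[k, -k, ] == 0))
  expect_true(all(post$R[-k, k, ] == 0))
  # free residual variances are strictly positive
  expect_true(all(apply(post$R, 3, diag) > 0))
})

test_that("chains with identical seed and data are bit-identical, different seeds differ", {
  z <- small_fit$z
  p1 <- fit_multivariate_animal(z$ph, z$sim$pedigree, z$cfg$trait_names, z$sr,
                                schedule = mcmc_schedule(2000, 500, 5), seed = 5)
  p2 <- fit_multivariate_animal(z$ph, z$sim$pedigree, z$cfg$trait_names, z$sr,
                                schedule = mcmc_schedule(2000, 500, 5), seed = 5)
  expect_identical(p1$G, p2$G)
  expect_identical(p1$R, p2$R)
  p3 <- fit_multivariate_animal(z$ph, z$sim$pedigree, z$cfg$trait_names, z$sr,
                                schedule = mcmc_schedule(2000, 500, 5), seed = 6)
  expect_false(identical(p1$G, p3$G))
})

test_that("posterior diagnostics and covariance summary are coherent", {
  post <- small_fit$post
  dg <- posterior_diagnostics(post)
  expect_equal(nrow(dg), 6)
  expect_true(all(dg$hpd_lower <= dg$mean & dg$mean <= dg$hpd_upper))
  expect_true(all(dg$ess <= 1000 + 1e-9, na.rm = TRUE))

  sm <- summarize_covariances(post)
  expect_equal(nrow(sm), 3)
  # summary is invariant to trait ordering up to transposition of the pair
  rev_tr <- rev(post$traits)
  post_rev <- post
  post_rev$traits <- rev_tr
  post_rev$G <- post$G[rev_tr, rev_tr, , drop = FALSE]
  sm_rev <- summarize_covariances(post_rev)
  key <- function(s) paste(pmin(s$trait_1, s$trait_2), pmax(s$trait_1, s$trait_2))
  expect_equal(sm$mean[order(key(sm))], sm_rev$mean[order(key(sm_rev))])
})

test_that("null genetic truth shrinks the posterior toward zero", {
  z <- sim_one_population(groups = 3, seed = 95, G_a = diag(c(0, 0, 0)),
                          sigma2_na = 0.05, sigma2_e = c(0.95, 0.95, 0.95),
                          germination_dropout = 0)
  post <- fit_multivariate_animal(z$ph, z$sim$pedigree, z$cfg$trait_names,
                                  z$sr, schedule = mcmc_schedule(12000, 2000, 10),
                                  seed = 2)
  sm <- summarize_covariances(post)
  expect_true(all(sm$hpd_lower <= 0 & sm$hpd_upper >= 0))
  expect_true(all(apply(post$G, 3, function(M) diag(M)) >= 0))
  expect_lt(max(abs(sm$mean)), 0.25)
})

test_that("near-duplicate traits concentrate the additive correlation near one", {
  z <- sim_one_population(groups = 3, seed = 96, trait_names = c("t1", "t2"),
                          family_traits = character(0),
                          G_a = matrix(c(0.6, 0.594, 0.594, 0.6), 2),
                          sigma2_na = c(0.02, 0.02), sigma2_e = c(0.38, 0.38),
                          residual_cor = 0.9, germination_dropout = 0)
  post <- fit_multivariate_animal(z$ph, z$sim$pedigree, c("t1", "t2"),
                                  schedule = mcmc_schedule(12000, 2000, 10),
                                  seed = 4)
  rg <- apply(post$G, 3, function(M) M[1, 2] / sqrt(M[1, 1] * M[2, 2]))
  expect_gt(median(rg), 0.7)
})

test_that("posterior CSV export writes one row per retained sample", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_posterior(small_fit$post, f)
  lines <- readLines(f, n = 2)
  expect_match(lines[1], "seed=17")
  tab <- read.csv(f, comment.char = "#")
  expect_equal(nrow(tab), 1000)
  expect_true("loglik" %in% names(tab))
})
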