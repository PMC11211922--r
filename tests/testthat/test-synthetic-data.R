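test_that("config validation enforces PSD G and sane rates", {
  expect_error(sim_config(G_a = matrix(c(1, 2, 2, 1), 2),
                          trait_names = c("a", "b"), family_traits = character(0)),
               "positive semidefinite")
  expect_error(sim_config(germination_dropout = 1), "dropout")
  expect_error(sim_config(sigma2_na = -0.1), "variances")
  cfg <- sim_config()
  expect_equal(sum(cfg$groups_per_population), 38)
  expect_equal(cfg$parents_per_group, 5L)
})

test_that("generator is a pure function of the config (determinism)", {
  cfg <- sim_config(n_populations_per_range = 1, groups_per_population = 2,
                    seed = 33)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$family_seed_records, s2$family_seed_records)
  s3 <- simulate_experiment(sim_config(n_populations_per_range = 1,
                                       groups_per_population = 2, seed = 34))
  expect_false(identical(s1$phenotypes$value, s3$phenotypes$value))
})

test_that("realized phenotypic variance matches diag(G) + sigma2_na + sigma2_e", {
  cfg <- sim_config(n_populations_per_range = 1, groups_per_population = 13,
                    trait_names = c("u", "v"), family_traits = character(0),
                    G_a = diag(c(0.4, 0.2)), sigma2_na = c(0.1, 0.05),
                    sigma2_e = c(0.5, 0.75), range_effects = 0,
                    climate_slopes = 0, block_effects = 0,
                    germination_dropout = 0, seed = 8)
  sim <- simulate_experiment(cfg)   # 2 * 13 * 20 * 2 = 1040 offspring
  v <- tapply(sim$phenotypes$value, sim$phenotypes$trait, var)
  expect_lt(max(abs(as.vector(v[c("u", "v")]) - 1)), 0.12)
})

test_that("breeding-value covariance is G/2 for full sibs and G/4 for half sibs", {
  cfg <- sim_config(n_populations_per_range = 1, groups_per_population = 25,
                    trait_names = c("u", "v"),
                    family_traits = character(0),
                    G_a = matrix(c(0.5, 0.2, 0.2, 0.4), 2),
                    germination_dropout = 0, seed = 21)
  sim <- simulate_experiment(cfg)
  ped <- sim$pedigree
  f1 <- ped[ped$generation == "F1", ]
  bv <- sim$breeding_values
  # reciprocal pairs within each family are full sibs; use first two records
  fams <- split(f1$id, f1$family)
  pair <- t(vapply(fams, function(ids) ids[1:2], c("", "")))
  fs_cov <- cov(bv[pair[, 1], ], bv[pair[, 2], ])
  expect_lt(max(abs(0.5 * (fs_cov + t(fs_cov)) - 0.5 * cfg$G_a)), 0.08)
  # half sibs: families sharing the dam
  byd <- split(seq_len(nrow(f1)), paste(f1$group, f1$dam))
  hs <- do.call(rbind, lapply(byd, function(ix) {
    fam <- f1$family[ix]
    k <- which(!duplicated(fam))[1:2]
    if (anyNA(k)) NULL else cbind(f1$id[ix[k[1]]], f1$id[ix[k[2]]])
  }))
  hs_cov <- cov(bv[hs[, 1], ], bv[hs[, 2], ])
  expect_lt(max(abs(0.5 * (hs_cov + t(hs_cov)) - 0.25 * cfg$G_a)), 0.08)
})

test_that("zero genetic signal gives near-zero full-sib phenotypic covariance", {
  cfg <- sim_config(n_populations_per_range = 1, groups_per_population = 25,
                    trait_names = "t", family_traits = character(0),
                    G_a = matrix(0), sigma2_na = 0, sigma2_e = 1,
                    range_effects = 0, climate_slopes = 0, block_effects = 0,
                    germination_dropout = 0, seed = 3)
  sim <- simulate_experiment(cfg)   # 500 families
  ph <- sim$phenotypes
  fams <- split(ph$value, ph$family)
  pairs <- t(vapply(fams, function(v) v[1:2], c(0, 0)))
  expect_lt(abs(cov(pairs[, 1], pairs[, 2])), 3 / sqrt(length(fams)))
})

test_that("full-sib phenotypic covariance matches half the additive variance", {
  cfg <- sim_config(trait_names = "t", family_traits = character(0),
                    G_a = matrix(0.4), sigma2_na = 0.05, sigma2_e = 0.55,
                    range_effects = 0, climate_slopes = 0, block_effects = 0,
                    germination_dropout = 0, seed = 14)
  sim <- simulate_experiment(cfg)   # 38 groups, 380 families
  ph <- sim$phenotypes
  fams <- split(ph$value, ph$family)
  pairs <- t(vapply(fams, function(v) v[1:2], c(0, 0)))
  expect_lt(abs(cov(pairs[, 1], pairs[, 2]) - (0.5 * 0.4 + 0.05)), 0.15)
})

test_that("seed measurements keep the largest seeds and inflate the mean by the order-statistic offset", {
  # seeds drawn exactly {1..5} -> retained {3,4,5}
  cfg0 <- sim_config(n_populations_per_range = 1, groups_per_population = 1,
                     germination_dropout = 0, seed = 2)
  sim0 <- simulate_experiment(cfg0)
  rec <- sim0$family_seed_records
  expect_true(all(tapply(rec$value, rec$family,
                         function(v) all(diff(v) <= 0))))  # stored largest-first
  expect_true(attr(rec, "order_statistic_selected"))

  # retained = seeds_per_family -> no selection, unbiased mean
  cfg <- sim_config(n_populations_per_range = 3, groups_per_population = 13,
                    G_a = diag(c(0, 0, 0)), sigma2_na = 0,
                    sigma2_e = c(1, 1, 1), range_effects = 0,
                    climate_slopes = 0, germination_dropout = 0, seed = 5)
  sim <- simulate_experiment(cfg)
  all5 <- simulate_seed_measurements(sim, seeds_per_family = 5, retained = 5)
  expect_false(attr(all5$family_seed_records, "order_statistic_selected"))
  expect_lt(abs(mean(all5$family_seed_records$value)), 0.05)

  # top 3 of 5: mean shifted by E(mean of top 3 of 5 standard normals)
  top3 <- simulate_seed_measurements(sim, seeds_per_family = 5, retained = 3)
  set.seed(99)  # Monte-Carlo oracle for the order-statistic offset
  draws <- matrix(rnorm(2e5 * 5), ncol = 5)
  offset <- mean(apply(draws, 1, function(x) mean(sort(x)[3:5])))
  expect_lt(abs(mean(top3$family_seed_records$value) - offset), 0.06)

  expect_error(simulate_seed_measurements(sim, 5, 6), "retained")
})

test_that("drop-time generator reproduces configured slopes and signs", {
  # zero noise: fitted slopes equal the configured coefficients exactly
  dt0 <- simulate_drop_time(n = 40, coef_size_pappus = 0.56,
                            coef_drop_size = -0.75, noise = 0, seed = 1)
  expect_equal(unname(coef(lm(pappus_length ~ seed_size, dt0))[2]), 0.56,
               tolerance = 1e-10)
  expect_equal(unname(coef(lm(drop_time ~ seed_size, dt0))[2]), -0.75,
               tolerance = 1e-10)

  # default 60-seed configuration: negative size -> drop-time slope
  dt <- simulate_drop_time(seed = 10)
  expect_equal(nrow(dt), 60)
  expect_lt(coef(lm(drop_time ~ seed_size, dt))[2], 0)

  expect_identical(simulate_drop_time(seed = 3), simulate_drop_time(seed = 3))
  expect_error(simulate_drop_time(n = 2), "at least 3")
})

test_that("dropout thins F1 records at the requested rate, pedigree untouched", {
  cfg <- sim_config(germination_dropout = 0, seed = 6)
  sim <- simulate_experiment(cfg)
  expect_equal(length(unique(sim$phenotypes$id)), 1520)

  same <- apply_dropout(sim, 0)
  expect_identical(same$phenotypes, sim$phenotypes)

  thinned <- apply_dropout(sim, 1 - 1324 / 1520, seed = 4)
  n_kept <- length(unique(thinned$phenotypes$id))
  # binomial mean 1324, sd ~ 13
  expect_lt(abs(n_kept - 1324), 45)
  expect_identical(thinned$pedigree, sim$pedigree)

  expect_error(apply_dropout(sim, 1), "rate")
})

test_that("extreme dropout leads to an insufficient-data error downstream, not a crash", {
  z <- sim_one_population(groups = 1, seed = 9,
                          trait_names = "t", family_traits = character(0),
                          G_a = matrix(0.4), germination_dropout = 0)
  tiny <- apply_dropout(z$sim, 0.95, seed = 1)
  ph <- tiny$phenotypes[tiny$phenotypes$range == "native", ]
  A <- additive_relationship(tiny$pedigree)
  expect_error(fit_animal_model("t", ph, A), "insufficient|< 2|data")
})

test_that("dataset tables round-trip to plain text with a truth sidecar", {
  z <- sim_one_population(groups = 1, seed = 12)
  dir <- withr::local_tempdir()
  write_dataset(z$sim, dir)
  expect_true(all(file.exists(file.path(dir, c("phenotypes.csv", "pedigree.txt",
                                               "family_seed_records.csv",
                                               "crosses.csv", "truth.json")))))
  back <- read.csv(file.path(dir, "phenotypes.csv"))
  expect_equal(nrow(back), nrow(z$sim$phenotypes))
})
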