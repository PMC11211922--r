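#' Configuration for a synthetic diallel breeding experiment
#'
#' Collects every generative parameter of the simulated study. Defaults
#' emulate the study conditions: 3 native + 3 invasive populations, 38
#' diallel groups in total (4-7 per population), 5 parents per group crossed
#' in a reciprocal partial diallel without selfing, 2 offspring per cross,
#' and ~13% germination dropout so roughly 1324 of the 1520 possible F1
#' records survive. Trait defaults are the three focal "invasion strategy"
#' traits on the standardized scale (phenotypic variance ~ 1): leaf mass,
#' root polyacetylene concentration, and seed size, with additive variances,
#' covariances, range shifts, and climate slopes in the ranges the study
#' design targets.
#'
#' @param n_populations_per_range populations per range (native, invasive).
#' @param groups_per_population diallel groups per population; a scalar or a
#'   vector of length `2 * n_populations_per_range`. The default
#'   `c(7, 6, 6, 7, 6, 6)` gives the study's 38 groups while respecting the
#'   4-7 groups-per-population envelope.
#' @param parents_per_group parents in each diallel group (default 5).
#' @param offspring_per_cross F1 seedlings planted per cross (default 2).
#' @param trait_names character vector of trait names.
#' @param family_traits traits measured on bulked family seeds rather than
#'   on individuals (default `"seed_size"` when present among
#'   `trait_names`); they get no individual phenotype rows.
#' @param G_a true additive genetic covariance matrix (trait x trait),
#'   symmetric positive semidefinite.
#' @param sigma2_na per-trait family (nonadditive) variance.
#' @param sigma2_e per-trait residual variance.
#' @param residual_cor residual correlation among co-measured (non-family)
#'   traits (default 0).
#' @param range_effects per-trait mean shift of the invasive range.
#' @param climate_slopes per-trait slope on the climate covariate.
#' @param climate_scores optional per-population climate covariate values
#'   (temperature-gradient PC score); default evenly spaced between -1 and 1
#'   within each range.
#' @param block_effects per-block shifts (default 6 blocks, small spread).
#' @param grand_mean per-trait intercept (default 0: standardized scale).
#' @param germination_dropout probability an F1 record is lost (at least 0, below 1).
#' @param seed integer RNG seed; the generator is a pure function of the
#'   config including this seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_populations_per_range = 3L,
                       groups_per_population = c(7L, 6L, 6L, 7L, 6L, 6L),
                       parents_per_group = 5L,
                       offspring_per_cross = 2L,
                       trait_names = c("leaf_mass", "polyacetylenes", "seed_size"),
                       family_traits = intersect("seed_size", trait_names),
                       G_a = default_G_a(trait_names),
                       sigma2_na = rep(0.05, length(trait_names)),
                       sigma2_e = NULL,
                       residual_cor = 0,
                       range_effects = default_range_effects(trait_names),
                       climate_slopes = default_climate_slopes(trait_names),
                       climate_scores = NULL,
                       block_effects = seq(-0.15, 0.15, length.out = 6),
                       grand_mean = rep(0, length(trait_names)),
                       germination_dropout = 1 - 1324 / 1520,
                       seed = 1L) {
  d <- length(trait_names)
  G_a <- as.matrix(G_a)
  if (!isTRUE(all.equal(dim(G_a), c(d, d))) || !isSymmetric(unname(G_a), tol = 1e-8))
    stop("G_a must be a symmetric trait x trait matrix", call. = FALSE)
  if (min(eigen(G_a, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("G_a must be positive semidefinite", call. = FALSE)
  dimnames(G_a) <- list(trait_names, trait_names)
  sigma2_na <- rep_len(sigma2_na, d)
  if (is.null(sigma2_e)) sigma2_e <- pmax(1 - diag(G_a) - sigma2_na, 0.05)
  sigma2_e <- rep_len(sigma2_e, d)
  if (any(sigma2_na < 0) || any(sigma2_e < 0))
    stop("variances must be >= 0", call. = FALSE)
  if (germination_dropout < 0 || germination_dropout >= 1)
    stop("germination_dropout must be in [0, 1)", call. = FALSE)
  n_pop <- 2L * n_populations_per_range
  groups_per_population <- rep_len(as.integer(groups_per_population), n_pop)
  if (is.null(climate_scores))
    climate_scores <- rep(seq(-1, 1, length.out = n_populations_per_range), 2)
  climate_scores <- rep_len(climate_scores, n_pop)
  cfg <- list(n_populations_per_range = as.integer(n_populations_per_range),
              groups_per_population = groups_per_population,
              parents_per_group = as.integer(parents_per_group),
              offspring_per_cross = as.integer(offspring_per_cross),
              trait_names = trait_names, family_traits = family_traits,
              G_a = G_a, sigma2_na = stats::setNames(sigma2_na, trait_names),
              sigma2_e = stats::setNames(sigma2_e, trait_names),
              residual_cor = residual_cor,
              range_effects = stats::setNames(rep_len(range_effects, d), trait_names),
              climate_slopes = stats::setNames(rep_len(climate_slopes, d), trait_names),
              climate_scores = climate_scores,
              block_effects = block_effects,
              grand_mean = stats::setNames(rep_len(grand_mean, d), trait_names),
              germination_dropout = germination_dropout,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Default truth for the three focal traits, on the standardized scale:
# additive variances inside the observed per-trait V_A envelopes
# (leaf mass ~0.2, polyacetylenes ~0.45, seed size ~0.55 of phenotypic
# variance) and small positive covariances of the magnitude the posterior
# summaries report.
default_G_a <- function(trait_names) {
  d <- length(trait_names)
  va <- rep_len(c(0.20, 0.45, 0.55), d)
  G <- diag(va, d)
  if (d >= 2) G[1, 2] <- G[2, 1] <- 0.10
  if (d >= 3) G[2, 3] <- G[3, 2] <- 0.10
  dimnames(G) <- list(trait_names, trait_names)
  G
}

default_range_effects <- function(trait_names) {
  def <- c(leaf_mass = 0.39, polyacetylenes = 0.60, seed_size = -0.27)
  out <- def[trait_names]
  out[is.na(out)] <- 0.3
  stats::setNames(as.numeric(out), trait_names)
}

default_climate_slopes <- function(trait_names) {
  def <- c(leaf_mass = 0.01, polyacetylenes = 0.19, seed_size = -0.23)
  out <- def[trait_names]
  out[is.na(out)] <- 0
  stats::setNames(as.numeric(out), trait_names)
}

# lower-triangular factor for (possibly singular) covariance draws
chol_psd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S)) %*% t(e$vectors)
}

rmvn <- function(n, S, Lfac = chol_psd(S)) {
  matrix(stats::rnorm(n * nrow(Lfac)), n) %*% t(Lfac)
}

#' Simulate a complete diallel breeding experiment
#'
#' Draws parental breeding values from the true G-matrix, forms offspring
#' breeding values as mid-parent plus a Mendelian-sampling deviate with
#' covariance G/2 (non-inbred unrelated parents), and builds phenotypes as
#' grand mean + range effect + climate slope x covariate + block effect +
#' breeding value + family deviate + residual. Family-measured traits (seed
#' size) get no individual rows; they are generated by
#' [simulate_seed_measurements()], which is called automatically when the
#' config lists family traits. Germination dropout is applied at the
#' configured rate. The whole generator is a pure function of the config,
#' including its seed.
#'
#' @param config a [sim_config()].
#' @return a list of class `diallel_sim` with elements `pedigree`,
#'   `phenotypes` (long table: id, trait, value, block, population, range,
#'   group, family, climate), `family_seed_records` (or `NULL`),
#'   `breeding_values` (true BVs, individuals x traits), and `truth` (the
#'   config).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  d <- length(config$trait_names)
  ranges <- c("native", "invasive")
  n_pop <- 2L * config$n_populations_per_range
  pops <- paste0(rep(ranges, each = config$n_populations_per_range),
                 rep(seq_len(config$n_populations_per_range), 2))

  # -- parents and crosses ------------------------------------------------
  parent_rows <- list(); cross_rows <- list(); g_idx <- 0L
  for (p in seq_len(n_pop)) {
    for (g in seq_len(config$groups_per_population[p])) {
      g_idx <- g_idx + 1L
      gid <- sprintf("G%02d", g_idx)
      ids <- sprintf("%s.%s.P%d", pops[p], gid, seq_len(config$parents_per_group))
      parent_rows[[g_idx]] <- data.frame(
        id = ids, population = pops[p],
        range = ranges[(p - 1L) %/% config$n_populations_per_range + 1L],
        group = gid, climate = config$climate_scores[p],
        stringsAsFactors = FALSE)
      cross_rows[[g_idx]] <- build_partial_diallel(ids, group = gid)
    }
  }
  parents <- do.call(rbind, parent_rows)
  crosses <- assign_families(do.call(rbind, cross_rows))
  ped <- build_pedigree(parents, crosses, config$offspring_per_cross)

  # -- breeding values ----------------------------------------------------
  Lg <- chol_psd(config$G_a)
  bv <- matrix(0, nrow(ped), d, dimnames = list(ped$id, config$trait_names))
  is_f1 <- ped$generation == "F1"
  bv[!is_f1, ] <- rmvn(sum(!is_f1), Lfac = Lg)
  if (any(is_f1)) {
    mid <- 0.5 * (bv[ped$dam[is_f1], , drop = FALSE] +
                  bv[ped$sire[is_f1], , drop = FALSE])
    bv[is_f1, ] <- mid + rmvn(sum(is_f1), Lfac = Lg / sqrt(2))
  }

  # -- family deviates (shared by garden offspring and seed records) ------
  fams <- sort(unique(crosses$family))
  fam_dev <- matrix(stats::rnorm(length(fams) * d), length(fams), d) %*%
    diag(sqrt(config$sigma2_na), d)
  dimnames(fam_dev) <- list(fams, config$trait_names)

  # -- individual phenotypes for non-family traits ------------------------
  ind_traits <- setdiff(config$trait_names, config$family_traits)
  f1 <- ped[is_f1, , drop = FALSE]
  n1 <- nrow(f1)
  phen <- NULL
  if (n1 > 0 && length(ind_traits) > 0) {
    nb <- length(config$block_effects)
    block <- sprintf("B%d", ((seq_len(n1) - 1L) %% nb) + 1L)
    it <- match(ind_traits, config$trait_names)
    Re <- diag(config$sigma2_e[it], length(it))
    if (length(it) > 1 && config$residual_cor != 0) {
      sds <- sqrt(config$sigma2_e[it])
      C <- matrix(config$residual_cor, length(it), length(it)); diag(C) <- 1
      Re <- diag(sds) %*% C %*% diag(sds)
    }
    resid <- rmvn(n1, Re)
    inv <- as.numeric(f1$range == "invasive")
    clim <- f1$climate
    vals <- sapply(seq_along(it), function(k) {
      t_ <- it[k]
      config$grand_mean[t_] + config$range_effects[t_] * inv +
        config$climate_slopes[t_] * clim +
        config$block_effects[match(block, sprintf("B%d", seq_len(nb)))] +
        bv[f1$id, t_] + fam_dev[f1$family, t_] + resid[, k]
    })
    phen <- data.frame(id = rep(f1$id, length(it)),
                       trait = rep(ind_traits, each = n1),
                       value = as.numeric(vals),
                       block = rep(block, length(it)),
                       population = rep(f1$population, length(it)),
                       range = rep(f1$range, length(it)),
                       group = rep(f1$group, length(it)),
                       family = rep(f1$family, length(it)),
                       climate = rep(f1$climate, length(it)),
                       stringsAsFactors = FALSE)
  }

  out <- list(pedigree = ped, phenotypes = phen, family_seed_records = NULL,
              breeding_values = bv, family_deviates = fam_dev,
              crosses = crosses, truth = config)
  class(out) <- "diallel_sim"

  if (length(config$family_traits) > 0)
    out <- simulate_seed_measurements(out)
  if (config$germination_dropout > 0)
    out <- apply_dropout(out, config$germination_dropout)
  out
}

#' Simulate bulked family seed-size measurements
#'
#' For each family, draws `seeds_per_family` seed sizes around the family
#' genetic value (mid-parent breeding value plus the family deviate, plus
#' range/climate fixed effects) and retains the `retained` largest, matching
#' a protocol that photographs the largest seeds of a bulk germination batch.
#' The retained records are order-statistic-selected and therefore biased
#' upward relative to the family mean; downstream models treat each retained
#' seed as one phantom-offspring record.
#'
#' @param dataset a `diallel_sim`.
#' @param seeds_per_family seeds generated per family (default 5).
#' @param retained number of largest seeds kept (default 3).
#' @param trait which family trait to measure (default first configured).
#' @return the dataset with `family_seed_records` filled in: columns
#'   `family`, `dam`, `sire`, `population`, `range`, `climate`, `replicate`,
#'   `value`, and attribute `order_statistic_selected = TRUE`.
#' @export
simulate_seed_measurements <- function(dataset, seeds_per_family = 5L,
                                       retained = 3L,
                                       trait = dataset$truth$family_traits[1]) {
  stopifnot(inherits(dataset, "diallel_sim"))
  if (retained > seeds_per_family)
    stop("retained must be <= seeds_per_family", call. = FALSE)
  cfg <- dataset$truth
  if (!trait %in% cfg$trait_names) stop("unknown trait: ", trait, call. = FALSE)
  t_ <- match(trait, cfg$trait_names)
  cr <- dataset$crosses
  fam <- cr[!duplicated(cr$family), c("family", "dam", "sire"), drop = FALSE]
  ped <- dataset$pedigree
  meta <- ped[match(fam$dam, ped$id), c("population", "range", "climate")]
  inv <- as.numeric(meta$range == "invasive")
  # family genetic value: mid-parent breeding value + family deviate
  gval <- 0.5 * (dataset$breeding_values[fam$dam, t_] +
                 dataset$breeding_values[fam$sire, t_]) +
    dataset$family_deviates[fam$family, t_]
  mu <- cfg$grand_mean[t_] + cfg$range_effects[t_] * inv +
    cfg$climate_slopes[t_] * meta$climate + gval
  nf <- nrow(fam)
  sizes <- matrix(stats::rnorm(nf * seeds_per_family, mean = rep(mu, seeds_per_family),
                               sd = sqrt(cfg$sigma2_e[t_] + 0.5 * cfg$G_a[t_, t_])),
                  nf, seeds_per_family)
  # keep the `retained` largest per family, in decreasing order
  kept <- t(apply(sizes, 1, function(x) sort(x, decreasing = TRUE)[seq_len(retained)]))
  rec <- data.frame(family = rep(fam$family, retained),
                    dam = rep(fam$dam, retained),
                    sire = rep(fam$sire, retained),
                    population = rep(meta$population, retained),
                    range = rep(meta$range, retained),
                    climate = rep(meta$climate, retained),
                    replicate = rep(seq_len(retained), each = nf),
                    trait = trait,
                    value = as.numeric(kept),
                    stringsAsFactors = FALSE)
  rec <- rec[order(rec$family, rec$replicate), ]
  rownames(rec) <- NULL
  attr(rec, "order_statistic_selected") <- retained < seeds_per_family
  dataset$family_seed_records <- rec
  dataset
}

#' Simulate the seed drop-time experiment
#'
#' Generates a table of seed size, pappus length and drop time for `n`
#' seeds: pappus length is regressed on size with a positive slope, drop
#' time decreases with size, and each seed is dropped twice with independent
#' measurement noise (the mean of the two drops is the modelling response).
#' Default coefficients are the study's observed size-pappus slope (0.56)
#' and size-drop-time slope (-0.75) on the standardized scale.
#'
#' @param n number of seeds (default 60).
#' @param coef_size_pappus slope of pappus length on seed size.
#' @param coef_drop_size slope of drop time on seed size.
#' @param coef_drop_pappus slope of drop time on pappus length net of size
#'   (default 0: pappus carries no partial effect).
#' @param noise residual SD for pappus and for each replicate drop.
#' @param seed RNG seed.
#' @return data frame with columns `seed_id`, `seed_size`, `pappus_length`,
#'   `drop_1`, `drop_2`, `drop_time` (the replicate mean).
#' @export
simulate_drop_time <- function(n = 60L, coef_size_pappus = 0.56,
                               coef_drop_size = -0.75, coef_drop_pappus = 0,
                               noise = 1.0, seed = 1L) {
  if (n < 3) stop("need at least 3 seeds", call. = FALSE)
  set.seed(seed)
  size <- stats::rnorm(n)
  pappus <- coef_size_pappus * size + stats::rnorm(n, sd = noise)
  mu <- coef_drop_size * size + coef_drop_pappus * pappus
  d1 <- mu + stats::rnorm(n, sd = noise)
  d2 <- mu + stats::rnorm(n, sd = noise)
  data.frame(seed_id = sprintf("S%02d", seq_len(n)), seed_size = size,
             pappus_length = pappus, drop_1 = d1, drop_2 = d2,
             drop_time = (d1 + d2) / 2)
}

#' Remove F1 phenotype records at random (germination dropout)
#'
#' Each F1 individual is independently lost with probability `rate`; all of
#' its phenotype rows are removed. The pedigree (and the family seed
#' records, which are measured before germination) are unchanged.
#'
#' @param dataset a `diallel_sim`.
#' @param rate dropout probability (at least 0, below 1).
#' @param seed optional seed; by default continues the generator's RNG
#'   stream (dropout applied inside [simulate_experiment()] is part of the
#'   pure function of the config).
#' @return the dataset with thinned `phenotypes`.
#' @export
apply_dropout <- function(dataset, rate, seed = NULL) {
  stopifnot(inherits(dataset, "diallel_sim"))
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)", call. = FALSE)
  if (rate == 0 || is.null(dataset$phenotypes)) return(dataset)
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(dataset$phenotypes$id)
  lost <- ids[stats::runif(length(ids)) < rate]
  dataset$phenotypes <- dataset$phenotypes[!dataset$phenotypes$id %in% lost, ,
                                           drop = FALSE]
  rownames(dataset$phenotypes) <- NULL
  dataset$dropped_ids <- lost
  dataset
}

#' Write the synthetic dataset as plain-text tables
#'
#' Writes the standard CSV tables (long phenotypes, family seed records,
#' crosses), the 3-column pedigree text file, and a JSON sidecar of the
#' ground-truth generative parameters.
#'
#' @param dataset a `diallel_sim`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "diallel_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  if (!is.null(dataset$family_seed_records))
    utils::write.csv(dataset$family_seed_records,
                     file.path(dir, "family_seed_records.csv"), row.names = FALSE)
  utils::write.csv(dataset$crosses, file.path(dir, "crosses.csv"),
                   row.names = FALSE)
  write_pedigree(dataset$pedigree, file.path(dir, "pedigree.txt"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- dataset$truth
    truth$G_a <- as.data.frame(truth$G_a)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(dir)
}
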