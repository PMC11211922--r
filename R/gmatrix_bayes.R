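#' MCMC schedule
#'
#' Total iterations, burn-in, and thinning interval for the Gibbs sampler.
#' The retained sample count `(total - burnin) / thin` must be whole. The
#' full-study schedule is `mcmc_schedule(3150000, 150000, 3000)` (1000
#' retained samples); the package's default working profile is one tenth of
#' that, `mcmc_schedule(315000, 15000, 300)`, which also retains 1000.
#'
#' @param total total MCMC iterations.
#' @param burnin initial iterations discarded (`< total`).
#' @param thin keep every `thin`-th iteration after burn-in (`>= 1`).
#' @return list of class `mcmc_schedule`.
#' @export
mcmc_schedule <- function(total = 315000, burnin = 15000, thin = 300) {
  if (burnin >= total) stop("burnin must be < total", call. = FALSE)
  if (thin < 1) stop("thin must be >= 1", call. = FALSE)
  if ((total - burnin) %% thin != 0)
    stop("(total - burnin) / thin must be a whole number", call. = FALSE)
  structure(list(total = as.double(total), burnin = as.double(burnin),
                 thin = as.double(thin)), class = "mcmc_schedule")
}

#' Retained sample count of a schedule
#'
#' @param schedule an [mcmc_schedule()].
#' @return `(total - burnin) / thin`.
#' @export
retained_samples <- function(schedule) {
  stopifnot(inherits(schedule, "mcmc_schedule"))
  (schedule$total - schedule$burnin) / schedule$thin
}

#' Prior specification for the multivariate animal model
#'
#' Scales for the hierarchical covariance priors and the structural-zero
#' mask for residual covariances. Each covariance matrix (additive G,
#' family, residual) carries a parameter-expanded inverse-Wishart prior
#' whose implied marginal on every standard deviation is half-t with `nu`
#' degrees of freedom (`nu = 1`: half-Cauchy) and scale equal to the
#' trait's value in `scales` — the working convention of weakly informative
#' priors based on observed phenotypic variances.
#'
#' @param scales positive per-trait scale (typically the phenotypic SD; 1
#'   on the standardized scale).
#' @param mask symmetric logical matrix marking residual covariances fixed
#'   at zero (free diagonal). Traits measured on disjoint sets of
#'   individuals (bulked family seed size vs. garden traits) must be masked.
#' @param nu half-t degrees of freedom (default 1 = half-Cauchy).
#' @return list of class `prior_spec`.
#' @export
prior_spec <- function(scales, mask = NULL, nu = 1) {
  if (any(scales <= 0)) stop("prior scales must be > 0", call. = FALSE)
  d <- length(scales)
  if (is.null(mask)) mask <- matrix(FALSE, d, d)
  mask <- as.matrix(mask)
  if (!isSymmetric(unname(mask)) || any(diag(mask)))
    stop("mask must be symmetric with a free diagonal", call. = FALSE)
  structure(list(scales = scales, mask = mask, nu = nu), class = "prior_spec")
}

# residual-independent trait groups implied by a zero mask: connected
# components of the "covariance is free" graph
mask_groups <- function(mask) {
  d <- nrow(mask)
  free <- !mask; diag(free) <- TRUE
  comp <- rep(NA_integer_, d); cur <- 0L
  for (i in seq_len(d)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    frontier <- i
    while (length(frontier)) {
      comp[frontier] <- cur
      frontier <- setdiff(which(apply(free[frontier, , drop = FALSE], 2, any)),
                          which(!is.na(comp)))
    }
  }
  split(seq_len(d), comp)
}

#' Bayesian multivariate animal model (Gibbs sampler)
#'
#' Samples the posterior of the additive genetic covariance matrix G for a
#' trait set, together with the family (nonadditive) and residual
#' covariance matrices, under the animal model
#' `y = X B + Z_a a + Z_na f + e` with `a ~ N(0, G (x) A)`. Block enters as
#' a fixed effect. Bulked family seed records enter as phantom-offspring
#' rows (each retained seed is an F1 individual attached to its family's
#' dam and sire), and their residual covariance with individually measured
#' traits is held at exactly zero every iteration via the prior mask. All
#' sampled covariance matrices are inverse-Wishart draws, hence symmetric
#' positive definite by construction; chains are reproducible from `seed`.
#'
#' @param phenotypes long standardized table (`id`, `trait`, `value`,
#'   `block`, `family`) restricted to the individuals to model (e.g. one
#'   population).
#' @param pedigree pedigree covering the phenotyped individuals and their
#'   parents (phantom seed ids are added internally).
#' @param traits trait set of 2-5 names, in display order.
#' @param seed_records family seed table (`family`, `dam`, `sire`,
#'   `replicate`, `trait`, `value`) or `NULL` if no family-measured trait.
#' @param prior a [prior_spec()]; default: scales = observed SD per trait,
#'   mask = zeros between the seed trait and all others, nu = 1.
#' @param schedule an [mcmc_schedule()].
#' @param family_cov `"full"` (default) or `"diagonal"` nonadditive
#'   covariance.
#' @param seed integer RNG seed.
#' @return object of class `gmatrix_posterior`: `traits`, `G`, `Fna`, `R`
#'   (d x d x S arrays), `B` (S x coefficients), `loglik` (per retained
#'   sample), `schedule`, `prior`, `seed`, `n_units`, `n_ped`.
#' @export
fit_multivariate_animal <- function(phenotypes, pedigree, traits,
                                    seed_records = NULL, prior = NULL,
                                    schedule = mcmc_schedule(),
                                    family_cov = c("full", "diagonal"),
                                    seed = 1L) {
  family_cov <- match.arg(family_cov)
  d <- length(traits)
  if (d < 2 || d > 5) stop("trait set must have 2-5 traits", call. = FALSE)
  fam_trait <- if (!is.null(seed_records)) unique(seed_records$trait) else character(0)
  if (length(fam_trait) > 1)
    stop("only one family-measured trait is supported", call. = FALSE)
  ind_traits <- setdiff(traits, fam_trait)
  miss <- setdiff(ind_traits, unique(phenotypes$trait))
  if (length(miss))
    stop("phenotypes lack traits: ", paste(miss, collapse = ", "), call. = FALSE)

  # --- wide table of garden units (complete cases across ind_traits) ----
  ph <- phenotypes[phenotypes$trait %in% ind_traits, , drop = FALSE]
  wide <- stats::reshape(ph[, c("id", "trait", "value")], direction = "wide",
                         idvar = "id", timevar = "trait")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  meta <- ph[!duplicated(ph$id), c("id", "block", "family")]
  wide <- merge(wide, meta, by = "id", sort = FALSE)

  # --- phantom seed units ------------------------------------------------
  seed_units <- NULL
  if (length(fam_trait)) {
    sr <- seed_records[!is.na(seed_records$value), , drop = FALSE]
    seed_units <- data.frame(id = paste0(sr$family, "_seed", sr$replicate),
                             dam = sr$dam, sire = sr$sire, family = sr$family,
                             value = sr$value, stringsAsFactors = FALSE)
  }

  # --- pedigree: ancestors of units + phantom rows ------------------------
  ped <- pedigree[, c("id", "dam", "sire")]
  need <- unique(c(wide$id,
                   if (!is.null(seed_units)) c(seed_units$dam, seed_units$sire)))
  keep <- rep(FALSE, nrow(ped)); names(keep) <- ped$id
  keep[need[need %in% ped$id]] <- TRUE
  for (i in rev(seq_len(nrow(ped)))) if (keep[i]) {
    for (p in c(ped$dam[i], ped$sire[i])) if (!is.na(p)) keep[p] <- TRUE
  }
  ped <- ped[keep, , drop = FALSE]
  if (!is.null(seed_units))
    ped <- rbind(ped, data.frame(id = seed_units$id, dam = seed_units$dam,
                                 sire = seed_units$sire))
  Ai <- additive_relationship_inverse(ped)
  n_ped <- nrow(ped)

  # --- units -------------------------------------------------------------
  units <- data.frame(id = wide$id, family = wide$family, block = wide$block,
                      group = 1L, stringsAsFactors = FALSE)
  ymat <- matrix(0, nrow(wide) + NROW(seed_units), d,
                 dimnames = list(NULL, traits))
  ymat[seq_len(nrow(wide)), ind_traits] <- as.matrix(wide[, ind_traits])
  if (!is.null(seed_units)) {
    units <- rbind(units, data.frame(id = seed_units$id,
                                     family = seed_units$family,
                                     block = NA_character_, group = 2L))
    ymat[nrow(wide) + seq_len(nrow(seed_units)), fam_trait] <- seed_units$value
  }
  fam_f <- factor(units$family)
  blocks <- sort(unique(stats::na.omit(units$block)))
  X <- matrix(1, nrow(units), 1)
  if (length(blocks) > 1) {
    bd <- outer(units$block, blocks[-1], function(a, b) as.numeric(!is.na(a) & a == b))
    X <- cbind(X, bd)
  }

  # --- priors and residual groups from the mask ---------------------------
  if (is.null(prior)) {
    sds <- stats::setNames(rep(1, d), traits)
    for (t in ind_traits) sds[t] <- stats::sd(wide[[t]])
    if (length(fam_trait)) sds[fam_trait] <- stats::sd(seed_units$value)
    sds[!is.finite(sds) | sds == 0] <- 1
    mask <- matrix(FALSE, d, d)
    if (length(fam_trait)) {
      k <- match(fam_trait, traits)
      mask[k, -k] <- TRUE; mask[-k, k] <- TRUE
    }
    prior <- prior_spec(sds, mask, nu = 1)
  }
  groups <- mask_groups(prior$mask)
  # each unit must observe exactly one mask group's trait set
  gsets <- vapply(groups, function(g) paste(sort(traits[g]), collapse = "|"), "")
  expected <- if (length(fam_trait))
    c(paste(sort(ind_traits), collapse = "|"), fam_trait)
  else paste(sort(traits), collapse = "|")
  if (!setequal(gsets, expected))
    stop("residual mask must separate exactly the family-measured trait ",
         "from the jointly measured traits", call. = FALSE)
  g_ind <- which(gsets == paste(sort(ind_traits), collapse = "|"))
  unit_group <- rep(g_ind, nrow(units))
  if (length(fam_trait)) unit_group[units$group == 2L] <- which(gsets == fam_trait)
  group_traits <- lapply(groups, function(g) as.integer(g - 1L))
  group_xcols <- lapply(seq_along(groups), function(g) {
    if (length(fam_trait) && gsets[g] == fam_trait) 0L
    else as.integer(seq_len(ncol(X)) - 1L)
  })

  # --- A-inverse in CSR form (diagonal separate from off-diagonal) --------
  ai_diag <- Matrix::diag(Ai)
  trip <- Matrix::summary(Ai)
  off <- trip$i != trip$j
  ord <- order(trip$i[off])
  oi <- trip$i[off][ord]; idx <- trip$j[off][ord] - 1L; val <- trip$x[off][ord]
  ptr <- cumsum(c(0L, tabulate(oi, n_ped)))

  unit_ped <- match(units$id, ped$id) - 1L
  if (anyNA(unit_ped)) stop("unit ids missing from pedigree", call. = FALSE)
  unit_fam <- as.integer(fam_f) - 1L

  # --- starting values: 1/3 of phenotypic (co)variance per component -----
  svar <- prior$scales^2
  G0 <- diag(svar / 3, d); F0 <- diag(svar / 3, d)
  R0 <- lapply(groups, function(g) diag(svar[g] / 3, length(g)))

  S <- retained_samples(schedule)
  set.seed(seed)
  res <- cpp_gibbs_animal(ymat, as.integer(unit_group - 1L), group_traits,
                          group_xcols, X, unit_ped, unit_fam,
                          ai_diag, as.integer(ptr), as.integer(idx), val,
                          nlevels(fam_f), prior$nu, prior$scales, prior$scales,
                          lapply(groups, function(g) prior$scales[g]),
                          family_cov == "diagonal",
                          as.integer(schedule$total),
                          as.integer(schedule$burnin),
                          as.integer(schedule$thin),
                          G0, F0, R0)
  dimnames(res$G) <- list(traits, traits, NULL)
  dimnames(res$Fna) <- list(traits, traits, NULL)
  dimnames(res$R) <- list(traits, traits, NULL)
  # every retained sample must be symmetric PSD
  ev <- apply(res$G, 3, function(M) min(eigen(M, TRUE, TRUE)$values))
  if (any(ev < -1e-8))
    stop("sampler emitted a non-PSD G sample", call. = FALSE)
  out <- list(traits = traits, G = res$G, Fna = res$Fna, R = res$R,
              B = res$B, loglik = drop(res$loglik), schedule = schedule,
              prior = prior, seed = seed, n_units = nrow(units),
              n_ped = n_ped, n_retained = S)
  class(out) <- "gmatrix_posterior"
  out
}

#' @export
print.gmatrix_posterior <- function(x, ...) {
  cat(sprintf("G-matrix posterior: %d traits, %d retained samples (n_units = %d)\n",
              length(x$traits), x$n_retained, x$n_units))
  cat("Posterior mean G:\n")
  print(round(apply(x$G, 1:2, mean), 4))
  invisible(x)
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing the requested posterior mass of
#' an empirical sample.
#'
#' @param samples numeric vector (>= 10 values).
#' @param mass probability mass in (0, 1), default 0.90.
#' @return named numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, mass = 0.90) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)", call. = FALSE)
  x <- sort(samples[!is.na(samples)])
  n <- length(x)
  if (n < 10) stop("need >= 10 samples", call. = FALSE)
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  width <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(width)
  c(lower = x[i], upper = x[i + k])
}

#' Lag-k autocorrelation and effective sample size of a chain
#'
#' @param x numeric chain.
#' @param lag lag (default 1).
#' @return `lag_autocorrelation()`: the lag-`lag` autocorrelation.
#' @export
lag_autocorrelation <- function(x, lag = 1) {
  if (stats::sd(x) == 0) return(NA_real_)
  stats::cor(x[-seq_len(lag)], x[-(length(x) - seq_len(lag) + 1)])
}

#' @rdname lag_autocorrelation
#' @details `effective_sample_size()` uses the initial positive sequence of
#'   autocorrelations: `ESS = n / (1 + 2 sum rho_k)`, truncated at the
#'   first non-positive `rho_k`, capped at `n`.
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(NA_real_)
  rho <- stats::acf(x, lag.max = min(n - 1, 100), plot = FALSE)$acf[-1]
  stop_at <- which(rho <= 0)[1]
  if (!is.na(stop_at)) rho <- rho[seq_len(stop_at - 1)]
  min(n, n / (1 + 2 * sum(rho)))
}

#' Convergence diagnostics for a G-matrix posterior
#'
#' Per G element (lower triangle): posterior mean, 90% HPD interval, lag-1
#' autocorrelation (flagged when above the recommended 0.1), and effective
#' sample size.
#'
#' @param posterior a `gmatrix_posterior` with >= 100 retained samples.
#' @param mass HPD mass (default 0.90).
#' @return data frame of class `posterior_summary` with one row per G
#'   element: `parameter`, `mean`, `hpd_lower`, `hpd_upper`, `lag1`, `ess`,
#'   `flagged` (lag1 > 0.1 or degenerate chain).
#' @export
posterior_diagnostics <- function(posterior, mass = 0.90) {
  stopifnot(inherits(posterior, "gmatrix_posterior"))
  S <- dim(posterior$G)[3]
  if (S < 100) stop("need >= 100 retained samples", call. = FALSE)
  tr <- posterior$traits; d <- length(tr)
  rows <- list()
  for (i in seq_len(d)) for (j in seq_len(i)) {
    ch <- posterior$G[i, j, ]
    degenerate <- stats::sd(ch) == 0
    l1 <- if (degenerate) NA_real_ else lag_autocorrelation(ch)
    hp <- if (degenerate) c(ch[1], ch[1]) else hpd_interval(ch, mass)
    rows[[length(rows) + 1]] <- data.frame(
      parameter = if (i == j) paste0("Va_", tr[i])
                  else paste0("CovA_", tr[j], ":", tr[i]),
      mean = mean(ch), hpd_lower = hp[1], hpd_upper = hp[2],
      lag1 = l1, ess = if (degenerate) NA_real_ else effective_sample_size(ch),
      flagged = degenerate || (!is.na(l1) && l1 > 0.1),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' Posterior summary of pairwise additive genetic covariances
#'
#' Posterior mean and 90% HPD interval per trait pair, flagging pairs whose
#' HPD excludes zero.
#'
#' @param posterior a `gmatrix_posterior`.
#' @param mass HPD mass (default 0.90).
#' @return data frame: trait_1, trait_2, mean, hpd_lower, hpd_upper,
#'   excludes_zero.
#' @export
summarize_covariances <- function(posterior, mass = 0.90) {
  stopifnot(inherits(posterior, "gmatrix_posterior"))
  tr <- posterior$traits; d <- length(tr)
  rows <- list()
  for (i in seq_len(d - 1)) for (j in (i + 1):d) {
    ch <- posterior$G[i, j, ]
    hp <- hpd_interval(ch, mass)
    rows[[length(rows) + 1]] <- data.frame(
      trait_1 = tr[i], trait_2 = tr[j], mean = mean(ch),
      hpd_lower = hp[1], hpd_upper = hp[2],
      excludes_zero = hp[1] > 0 | hp[2] < 0, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write posterior samples as CSV
#'
#' One row per retained sample; flattened lower triangles of G, the family
#' covariance and the residual covariance, plus the log-likelihood. Seed
#' and schedule are recorded in a header comment.
#'
#' @param posterior a `gmatrix_posterior`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_posterior <- function(posterior, file) {
  tr <- posterior$traits; d <- length(tr)
  lab <- function(pre) {
    out <- character(0)
    for (i in seq_len(d)) for (j in seq_len(i))
      out <- c(out, paste0(pre, "_", tr[j], if (i != j) paste0(":", tr[i])))
    out
  }
  flat <- function(arr) t(apply(arr, 3, function(M) M[lower.tri(M, diag = TRUE)]))
  tab <- data.frame(flat(posterior$G), flat(posterior$Fna), flat(posterior$R),
                    loglik = posterior$loglik)
  names(tab) <- c(lab("Va"), lab("Vna"), lab("Ve"), "loglik")
  con <- file(file, "w")
  writeLines(sprintf("# seed=%d total=%g burnin=%g thin=%g",
                     posterior$seed, posterior$schedule$total,
                     posterior$schedule$burnin, posterior$schedule$thin), con)
  utils::write.csv(tab, con, row.names = FALSE)
  close(con)
  invisible(file)
}
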