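# Independent oracles used across the suite.

# Brute-force additive relationship by path counting, valid for pedigrees
# whose common ancestors are unrelated, non-inbred founders (true for any
# two-generation pedigree with founder parents): A[i,j] is the sum over
# common founder ancestors of (1/2)^(L1 + L2) across all ancestral path
# pairs, and A[i,i] = 1 (no inbreeding possible with unrelated parents).
oracle_A_paths <- function(ped) {
  n <- nrow(ped)
  # list of (ancestor, depth) pairs per individual, one entry per path
  anc <- vector("list", n)
  names(anc) <- ped$id
  for (i in seq_len(n)) {
    paths <- data.frame(a = ped$id[i], L = 0, stringsAsFactors = FALSE)
    frontier <- paths
    while (nrow(frontier) > 0) {
      up <- list()
      for (k in seq_len(nrow(frontier))) {
        row <- ped[ped$id == frontier$a[k], ]
        for (p in c(row$dam, row$sire)) if (!is.na(p))
          up[[length(up) + 1]] <- data.frame(a = p, L = frontier$L[k] + 1,
                                             stringsAsFactors = FALSE)
      }
      frontier <- if (length(up)) do.call(rbind, up) else frontier[0, ]
      paths <- rbind(paths, frontier)
    }
    anc[[i]] <- paths
  }
  founders <- ped$id[is.na(ped$dam) & is.na(ped$sire)]
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    A[i, i] <- 1
    if (i == 1) next
    for (j in seq_len(i - 1)) {
      ai <- anc[[i]]; aj <- anc[[j]]
      tot <- 0
      for (f in founders) {
        Li <- ai$L[ai$a == f]; Lj <- aj$L[aj$a == f]
        if (length(Li) && length(Lj))
          tot <- tot + sum(outer(Li, Lj, function(x, y) 0.5^(x + y)))
      }
      A[i, j] <- A[j, i] <- tot
    }
  }
  A
}

# random two-generation pedigree: founders plus offspring of founder pairs
random_two_gen_pedigree <- function(max_n = 50) {
  nf <- sample(4:12, 1)
  no <- sample(5:(max_n - nf), 1)
  founders <- data.frame(id = paste0("F", seq_len(nf)),
                         dam = NA_character_, sire = NA_character_,
                         stringsAsFactors = FALSE)
  pairs <- t(replicate(no, sample(founders$id, 2)))
  off <- data.frame(id = paste0("O", seq_len(no)),
                    dam = pairs[, 1], sire = pairs[, 2],
                    stringsAsFactors = FALSE)
  rbind(founders, off)
}

# closed-form REML (= ANOVA) variance components for a balanced one-way
# random-effects layout: a groups of size n
oneway_anova_components <- function(y, group) {
  n <- as.integer(table(group)[1])
  a <- length(unique(group))
  gm <- tapply(y, group, mean)
  msb <- n * sum((gm - mean(y))^2) / (a - 1)
  msw <- sum((y - gm[group])^2) / (a * (n - 1))
  c(group = (msb - msw) / n, residual = msw)
}

# quick direct generator for dam/sire LMM tests: family-mean style records
# with crossed dam and sire effects; traits get independent residuals
sim_dam_sire_table <- function(n_dams = 12, n_sires = 12, traits = c("t1", "t2"),
                               range_effect = 0, sd_dam = 0.3, sd_sire = 0.3,
                               sd_e = 1, n_per_range = NULL) {
  dams <- paste0("D", seq_len(n_dams)); sires <- paste0("S", seq_len(n_sires))
  fam <- expand.grid(dam = dams, sire = sires, stringsAsFactors = FALSE)
  fam$range <- rep(c("native", "invasive"), length.out = nrow(fam))
  fam$climate <- stats::rnorm(nrow(fam), sd = 0.5)
  de <- stats::setNames(stats::rnorm(n_dams, sd = sd_dam), dams)
  se <- stats::setNames(stats::rnorm(n_sires, sd = sd_sire), sires)
  out <- do.call(rbind, lapply(traits, function(tr) {
    v <- range_effect * (fam$range == "invasive") + de[fam$dam] + se[fam$sire] +
      stats::rnorm(nrow(fam), sd = sd_e)
    data.frame(family = paste(fam$dam, fam$sire, sep = "x"), trait = tr,
               value = v, range = fam$range, climate = fam$climate,
               dam = fam$dam, sire = fam$sire, stringsAsFactors = FALSE)
  }))
  out
}

# a single-population synthetic experiment, convenient shorthand
sim_one_population <- function(groups = 4, seed = 1, ...) {
  cfg <- sim_config(n_populations_per_range = 1, groups_per_population = groups,
                    seed = seed, ...)
  sim <- simulate_experiment(cfg)
  list(cfg = cfg, sim = sim,
       ph = sim$phenotypes[sim$phenotypes$range == "native", ],
       sr = if (!is.null(sim$family_seed_records))
         sim$family_seed_records[sim$family_seed_records$range == "native", ])
}
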