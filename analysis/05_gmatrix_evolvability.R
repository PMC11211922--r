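#!/usr/bin/env Rscript
# Multivariate genetic architecture and constraint.  Per population, the
# Bayesian multivariate animal model estimates the G-matrix of the three
# "invasion strategy" traits (leaf mass, polyacetylenes, seed size) under
# half-Cauchy-style covariance priors, with seed size entering as phantom
# family-seed records whose residual covariance with the garden traits is
# structurally zero.  Posterior G samples then feed the evolvability
# analysis: for each sample a random novel selection gradient with signs
# (+ leaf mass, + polyacetylenes, - seed size) is drawn and the R score
# (evolvability with covariances / evolvability without) is tested against
# 1 with a 90% HPD interval.
#
# The working chain is one tenth of the full-study schedule (315,000
# iterations, 15,000 burn-in, thinning 300 -> 1000 retained samples).

suppressMessages(library(invasionQG))

ph <- read.csv("results/synthetic/phenotypes.csv")
sr <- read.csv("results/synthetic/family_seed_records.csv")
ped <- read_pedigree("results/synthetic/pedigree.txt")

ph_std <- standardize_traits(ph)
sr_std <- sr
sr_std$value <- scale(sr$value)[, 1]

traits <- c("leaf_mass", "polyacetylenes", "seed_size")
populations <- sort(unique(ph$population))

cov_rows <- list(); r_rows <- list(); diag_rows <- list()
for (i in seq_along(populations)) {
  pop <- populations[i]
  cat("==", pop, "==\n")
  post <- fit_multivariate_animal(
    ph_std[ph_std$population == pop, ], ped, traits,
    sr_std[sr_std$population == pop, ],
    schedule = mcmc_schedule(), seed = 4000 + i)
  dg <- posterior_diagnostics(post)
  diag_rows[[i]] <- cbind(population = pop, dg)
  if (any(dg$flagged))
    cat("  note: flagged parameters (lag-1 autocorrelation > 0.1):",
        paste(dg$parameter[dg$flagged], collapse = ", "), "\n")
  sm <- summarize_covariances(post)
  cov_rows[[i]] <- cbind(population = pop, sm)
  print(sm, digits = 2)
  rp <- r_posterior(post, "competitive", seed = 600 + i)
  cat(sprintf("  R score: mean %.3f, 90%% HPD [%.3f, %.3f] -> %s\n",
              rp$mean_R, rp$hpd[["lower"]], rp$hpd[["upper"]], rp$verdict))
  r_rows[[i]] <- data.frame(population = pop, trait_set = "competitive",
                            mean_R = rp$mean_R, hpd_lower = rp$hpd[["lower"]],
                            hpd_upper = rp$hpd[["upper"]], verdict = rp$verdict)
  if (i == 1) {
    dir.create("results", showWarnings = FALSE)
    write_posterior(post, file.path("results",
                                    paste0("gmatrix_posterior_", pop, ".csv")))
  }
}

write.csv(do.call(rbind, cov_rows), "results/gmatrix_covariances.csv",
          row.names = FALSE)
write.csv(do.call(rbind, diag_rows), "results/gmatrix_diagnostics.csv",
          row.names = FALSE)
write.csv(do.call(rbind, r_rows), "results/r_scores.csv", row.names = FALSE)

cat("\nSummary across populations:\n")
print(do.call(rbind, r_rows), digits = 3)
cat("\nWith the generator's weak covariances the HPD intervals are expected",
    "\nto overlap 1: the covariance structure neither constrains nor",
    "\nfacilitates joint evolution of the three traits.\n")
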