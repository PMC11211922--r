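# invasionQG

Evolutionary quantitative genetics of invasive plant traits from partial
diallel breeding designs.

Introduced plant populations can evolve an "invasion syndrome" — faster
resource exploitation, stronger allelopathic interference, better seed
dispersal — but only if the traits involved retain additive genetic
variance ($V_A$) and are not locked together by unfavourable genetic
covariances. `invasionQG` implements the complete analysis chain for a
common-garden breeding study of native vs invasive populations (the
motivating system is tall goldenrod, *Solidago altissima*, crossed in
five-parent partial diallels with reciprocals and no selfing):

* **Design & pedigree** — enumerate and validate reciprocal partial
  diallel crossing schemes, assign reciprocal crosses to shared families,
  build two-generation pedigrees, and compute the additive relationship
  matrix A (tabular method) and its sparse Henderson inverse.
* **Synthetic data** — simulate whole experiments from a known additive
  G-matrix (parental breeding values, Mendelian sampling, family, block,
  range and climate effects, germination dropout, bulked top-3-of-5 seed
  measurements, a seed drop-time experiment), so every estimator in the
  package is verifiable by parameter recovery.
* **Trait pipeline** — derived traits (growth rate, SLA, flowering
  duration), z-standardization with back-transform, family means, and the
  drop-time multiple regression with backward partial-F model selection.
* **Mixed models** — stacked-trait and per-trait divergence LMMs (dam and
  sire as crossed random intercepts, Wald χ² tests, Bonferroni control,
  Tukey post hoc letters) and a univariate pedigree **animal model** fit
  by the package's own REML engine:
  `Var(y) = σ²ₐA + σ²_na Z_f Z_f′ + σ²_e I`, with boundary-mixture
  likelihood-ratio tests for σ²ₐ ( ½χ²₀ + ½χ²₁ ).
* **Bayesian G-matrix** — a C++ Gibbs sampler for the multivariate animal
  model with half-Cauchy-style (Huang–Wand, ν = 1) covariance priors
  scaled by phenotypic SDs, structural-zero residual covariances for the
  family-measured seed trait, 90% HPD summaries, and autocorrelation/ESS
  diagnostics.
* **Evolvability** — e(β) = β′Gβ/β′β along sign-constrained random
  selection gradients, and the **R score** (evolvability with genetic
  covariances / evolvability without), tested against 1 with 90% HPD
  intervals: R < 1 means the covariance structure constrains the joint
  response to novel selection, R > 1 that it facilitates it.

## Worked example

```r
library(invasionQG)

# a synthetic study at the default design: 6 populations, 38 groups,
# 760 crosses, ~13% germination dropout
cfg <- sim_config(seed = 11)
sim <- simulate_experiment(cfg)

# one population's G-matrix for the three invasion-strategy traits
ph <- sim$phenotypes[sim$phenotypes$population == "native1", ]
sr <- sim$family_seed_records[sim$family_seed_records$population == "native1", ]
post <- fit_multivariate_animal(ph, sim$pedigree, cfg$trait_names, sr,
                                schedule = mcmc_schedule(20000, 2000, 18),
                                seed = 3)
print(post)
#> G-matrix posterior: 3 traits, 1000 retained samples (n_units = 462)
#> Posterior mean G:
#>                leaf_mass polyacetylenes seed_size
#> leaf_mass         0.1454         0.0453   -0.0208
#> polyacetylenes    0.0453         0.6162    0.3339
#> seed_size        -0.0208         0.3339    0.5694

# does the covariance structure constrain novel selection
# (+ leaf mass, + polyacetylenes, - seed size)?
rp <- r_posterior(post, "competitive", seed = 1)
print(rp)
#> R-score posterior: mean = 0.958, 90% HPD = [0.609, 1.264]
#> verdict vs 1: neither
```

The posterior mean G recovers the generator's truth (additive variances
0.20 / 0.45 / 0.55 with covariances 0.10 / 0 / 0.10) to within the
uncertainty a single 7-group population allows, and the R-score interval
straddling 1 says these weak covariances neither block nor accelerate the
joint evolution of the three traits. (The short 20k-iteration schedule
here is for the example; analyses use `mcmc_schedule()`'s 315k default.)

The `analysis/` directory holds the full narrative pipeline over a
synthetic study — `01_simulate_experiment.R` (design + data),
`02_seed_dispersal.R` (drop-time model selection),
`03_trait_divergence.R` (multivariate/univariate divergence, post hoc
letters), `04_univariate_genetics.R` (per-population animal models, LRTs,
divergence-on-V_A regression), `05_gmatrix_evolvability.R` (per-population
G posteriors and R scores). Each writes its tables under `results/`.

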