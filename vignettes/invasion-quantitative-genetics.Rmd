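---
title: "Quantitative genetics of invasion traits from a partial diallel design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics of invasion traits from a partial diallel design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invasionQG)
```

# The problem

Invasive plant populations are often said to carry an "invasion syndrome":
vigorous growth, strong competitive ability (including allelopathy), and
high seed dispersal. Whether such a syndrome can keep evolving in an
introduced range depends on two quantitative-genetic quantities: how much
additive genetic variance ($V_A$) each trait harbours within populations,
and whether additive genetic covariances among traits constrain or
facilitate their joint response to selection. `invasionQG` implements the
full chain of analyses needed to answer both questions from a partial
diallel breeding design of the kind used for tall goldenrod (*Solidago
altissima*) sampled in its native and invasive ranges: design and pedigree
construction, a synthetic-data generator with known ground truth,
divergence mixed models, univariate REML animal models, Bayesian
multivariate G-matrix estimation, and evolvability / R-score computation
under simulated novel selection.

Because the package is organized as an analysis, the `analysis/` scripts
(01 through 05) walk through the whole pipeline on a synthetic study;
every computation they perform lives in the package and is unit-tested.

# The breeding design and the relationship matrix

Parents collected within each population are split into groups of five and
crossed in a **partial diallel with reciprocals and no selfing**: every
ordered dam × sire pair within a group, $n(n-1) = 20$ crosses per 5-parent
group, each parent serving four times as dam and four times as sire.
Offspring of reciprocal crosses (A×B and B×A) are full sibs and share a
*family* identity; the canonical family id is the sorted parent pair.
`build_partial_diallel()`, `assign_families()`, `build_pedigree()` and
`validate_design()` construct and audit this design.

`additive_relationship()` computes the numerator relationship matrix A by
the recursive tabular method. Founders are assumed unrelated and
non-inbred — field plants were sampled at least 10 m apart precisely to
justify this — so with a single offspring generation no individual is
inbred, every diagonal is exactly 1, parent–offspring and full-sib entries
are 0.5, and half sibs (one shared parent within a group) are 0.25. The
test suite checks the tabular method entry-wise against an independent
path-counting oracle on random two-generation pedigrees.
`additive_relationship_inverse()` builds the sparse inverse directly with
Henderson's rules (exact here because no parent is inbred); the Gibbs
sampler only ever needs A$^{-1}$.

# The synthetic-data generator

`sim_config()` + `simulate_experiment()` generate a complete experiment
from known truth, which makes every estimator testable by parameter
recovery. The generative model mirrors the estimation model read forwards:

* parental breeding values $a_P \sim N(0, G_a)$;
* offspring breeding values: mid-parent plus a Mendelian-sampling deviate
  with covariance $\tfrac12 G_a$ (exact for unrelated, non-inbred parents);
* phenotype = grand mean + range effect + climate slope × population
  climate score + block effect + breeding value + family deviate
  ($\sigma^2_{na}$) + residual ($\sigma^2_e$).

Defaults are the study conditions: 3 populations per range, 38 diallel
groups in total (the per-population counts `c(7, 6, 6, 7, 6, 6)` respect
the reported 4–7 envelope; the exact allocation is not reported, so the
generator exposes it as a free parameter), 5 parents per group, 2
offspring per cross (1520 potential F1), and independent germination
dropout at rate $1 - 1324/1520 \approx 0.129$ so about 1324 individuals
survive. Everything is on the standardized scale (phenotypic variance
≈ 1), because the study standardizes all traits before analysis and
never reports raw trait scales. Default truth for the three focal traits
places $V_A$ inside the reported per-trait envelopes (leaf mass ≈ 0.20,
polyacetylenes ≈ 0.45, seed size ≈ 0.55 of phenotypic variance), small
positive covariances (0.10) of the magnitude the posterior summaries
report, family variance 0.05 (nonadditive variance is reported small,
< 10%), and range shifts / climate slopes equal to the published
univariate coefficients for those traits.

Two features of the real data are emulated deliberately:

* **Bulked seed measurement.** Seed size is measured on the three largest
  of five seeds per family before germination, so seed records attach to
  families, never to garden individuals. The generative unit is the family
  genetic value (mid-parent breeding value + family deviate); replicate
  seeds add residual noise that also absorbs the Mendelian-sampling
  variance, and the top-3-of-5 retention is a real order-statistic
  selection whose upward bias the tests quantify against a Monte-Carlo
  oracle. Downstream models re-expose each retained seed as a *phantom
  offspring* of the family's dam and sire
  (`augment_pedigree_with_seeds()`), which is exactly how the estimation
  model treats them.
* **Drop-time experiment.** `simulate_drop_time()` generates 60 seeds with
  pappus length positively regressed on seed size (slope 0.56) and drop
  time negatively regressed on seed size (slope −0.75), two replicate
  drops per seed averaged before modelling.

What the generator does **not** emulate: selection, multiple generations,
linkage or explicit genomes, non-Gaussian traits, non-random missingness
(dropout is independent), spatial structure in the greenhouse beyond the
block shifts, and any raw-scale trait units. Passing recovery tests
therefore show the estimators are correct *under the declared model*, not
that the model captures every feature of real greenhouse data.

# Mixed models

**Divergence models.** The stacked-trait family-mean model
(`multivariate_divergence_test()`) fits trait, range and trait × range as
fixed effects with the population climate score as a covariate and dam and
sire as crossed iid random intercepts; fixed terms are evaluated with Wald
χ² tests. Family means are used so that the family-level seed-size trait
can sit next to individually measured traits; the pipeline standardizes
first and averages second. The stacked model assumes a common residual
variance across traits (the simplest structure consistent with a
single-response mixed-model fit of scaled traits); a per-trait residual
variance is available via `heterogeneous_residuals = TRUE`. These models
are fitted with `lme4`, the tool a practitioner would use; the package's
own REML engine is reserved for the pedigree models that `lme4` cannot
express.

**Animal model.** `fit_animal_model()` estimates, for one trait,
$\mathrm{Var}(y) = \sigma^2_a A + \sigma^2_{na} Z_f Z_f' + \sigma^2_e I$
with block fixed, by REML: the residual variance is profiled out and the
two variance ratios are optimized under non-negativity constraints
(quasi-Newton with box constraints, derivative-free fallback; convergence
tolerance 1e-8 on the log-likelihood; variances clamped at 1e-10). The
engine is validated against closed-form ANOVA estimators on balanced
one-way layouts and against `lme4` on models both can fit.

**Testing $V_A$.** `test_additive_variance()` compares full vs
$\sigma^2_a = 0$ fits with a likelihood-ratio test referred to the 50:50
mixture of $\chi^2_0$ and $\chi^2_1$, the standard reference when a
variance is pinned at the boundary of its space. At an identical pair of
fits the mixture gives p = 0.5. The type-I-error calibration test runs
null simulations on a 12-group design: in this crossing scheme
$\sigma^2_a$ is informed mainly by the half-sib covariance contrast, so
small designs leave the LRT visibly conservative and a ~480-record design
is the point where the asymptotic mixture is accurate.

# Bayesian G-matrix estimation

`fit_multivariate_animal()` samples the joint posterior of the additive
covariance matrix G (trait set of 2–5 traits), the family covariance
matrix and the residual covariance structure, under the multivariate
animal model with block fixed. The sampler is a Gibbs scheme written in
C++:

* breeding values are updated single-site over pedigree ids through the
  sparse A$^{-1}$ (Henderson neighborhoods), family effects per family;
* fixed effects are drawn from their matrix-normal conditional;
* all covariance matrices use the Huang–Wand (2013) hierarchical
  inverse-Wishart construction with $\nu = 1$, whose implied marginal on
  every standard deviation is half-Cauchy with scale equal to the trait's
  observed phenotypic SD — a concrete multivariate realization of "weakly
  informative half-Cauchy priors based on phenotypic variances". The
  construction keeps every conditional conjugate, and inverse-Wishart
  draws are symmetric positive definite by construction, so no retained G
  sample can be non-PSD (asserted anyway).

**Structural zeros.** Seed size lives on phantom seed individuals, so its
residual covariance with garden-measured traits is not estimable; the
prior mask partitions the traits into residual-independent groups and the
sampler parameterizes the residual as separate blocks, making the masked
covariances *exactly* zero in every retained sample rather than shrunk.

**Schedule.** The full-study schedule is 3,150,000 iterations, 150,000
burn-in, thinning 3000 (1000 retained). The package's working profile is
one tenth of that (`mcmc_schedule()` default: 315,000 / 15,000 / 300,
also 1000 retained), which keeps a population-scale fit at desk scale;
`posterior_diagnostics()` reports lag-1 autocorrelations (flagged above
the conventional 0.1) and effective sample sizes so a user can judge
whether a longer chain is needed. Chains are bit-identical under a fixed
seed; the sampler's bulk normal draws come from an internal xoshiro256++
generator seeded from R's RNG, so `set.seed()` governs everything.

**Starting values** are one third of the observed phenotypic (co)variance
per component. The family covariance is a full matrix by default with a
`"diagonal"` option, since the original specification of that component is
ambiguous.

# Evolvability and the R metric

For a selection gradient $\beta$, evolvability is
$e(\beta) = \beta' G \beta / \beta'\beta$ — identical (and asserted
identical to 1e-10) to the projection of the response
$\Delta \bar z = G\beta$ onto the direction of selection. The printed
form of the projection identity is ambiguous about normalization; the
package resolves it through the Hansen–Houle identity above, and
normalizes $\beta$ to unit length so both $e$ and $R$ are scale-free
(R is ratio-invariant to the convention regardless).

The **R score** is $e$ under the full G divided by $e$ under G with
off-diagonals zeroed: R < 1 means covariances constrain evolution along
$\beta$, R > 1 means they facilitate it, and any diagonal G gives R = 1
exactly. For 2×2 G with equal variances and correlation $\rho$,
$\beta = (1,1)/\sqrt2$ gives R = $1+\rho$, which the tests sweep across
the correlation grid.

Because the direction of novel selection is unknown, gradients are
simulated: elementwise |standard normal| magnitudes with signs fixed by
the hypothesized direction (competitive set: + leaf mass,
+ polyacetylenes, − seed size), normalized to the unit sphere — i.e.
uniform over the specified orthant. The distribution of gradient
magnitudes is not prescribed anywhere; orthant-uniformity is this
package's choice and is what the distributional test asserts. The
reproductive preset (+ days to first flower, + rhizome mass, − seed size)
follows the observed divergence directions and is flagged as an assumed
pattern. `r_posterior()` draws one fresh gradient per retained G sample,
so the R posterior deliberately mixes G-uncertainty with β-uncertainty,
and tests R against 1 with the same 90% HPD machinery used for the
covariances.

# Numerical choices and degenerate inputs

* HPD intervals are the shortest contiguous window containing the
  requested mass of the sorted samples; an all-equal sample gives a
  zero-width interval.
* `standardize_traits()` refuses constant traits (zero SD) and traits with
  fewer than two values; missing values pass through and models drop them
  listwise, never imputing.
* `select_drop_time_model()` does backward elimination from the full
  two-predictor model at α = 0.05 — the named partial-F procedure leaves
  direction and level unstated, so both are fixed here and exposed as an
  argument. Exactly collinear predictors are an error.
* `divergence_va_regression()` flags a constant-$V_A$ input as degenerate
  (undefined slope) instead of erroring, and refuses fewer than 3 traits.
* The compact letter display is computed by the insert-and-absorb
  algorithm from the Tukey-adjusted pairwise tests.
* Extreme dropout produces a downstream "insufficient data" error rather
  than a crash.

# Problem sizes used by the test suite

The suite favors parameter-recovery tests at the sizes the design
dictates: full-design (38 groups, ~1324 surviving records) REML recovery
over 20 replicates; Bayesian coverage and R-score recovery on
population-scale fits (4-group populations, the small end of the 4–7
envelope) at the 1/10-length working schedule over 20 replicates; LRT
calibration over 500 null simulations of a 12-group design; the A-matrix
oracle over 100 random two-generation pedigrees; and the evolvability
identities over 10^4 random matrices. Distributional assertions use
3-Monte-Carlo-SE tolerances around their expected values.

# Known limitations

* The REML engine builds dense n × n covariance matrices; it is
  comfortable to a few thousand records but not designed for large
  pedigrees.
* The Gibbs sampler supports residual masks that partition the trait set
  into groups measured on disjoint individuals (the design's actual
  structure); arbitrary element-wise residual masks are not supported.
* Single-generation pedigrees are the tested regime. The tabular A and
  its Henderson inverse are general, but the Henderson inverse assumes
  non-inbred parents.
* No multi-chain convergence machinery (R-hat); diagnostics follow the
  original single-chain practice of autocorrelation + ESS.
* The stacked-trait divergence model treats family means as exchangeable
  observations and ignores the unequal precision of family means with
  different sib counts.
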