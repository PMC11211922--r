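#' Attach dam and sire ids to a phenotype table
#'
#' @param table long phenotype table with an `id` column.
#' @param pedigree pedigree data frame with `id`, `dam`, `sire`.
#' @return the table with `dam` and `sire` columns.
#' @export
attach_parents <- function(table, pedigree) {
  i <- match(table$id, pedigree$id)
  table$dam <- pedigree$dam[i]
  table$sire <- pedigree$sire[i]
  table
}

#' Phantom-offspring representation of bulked family seed records
#'
#' Bulked seed measurements cannot be linked to individual garden plants,
#' but every measured seed is itself an F1 individual of its family's cross.
#' These helpers therefore give each retained seed a phantom offspring id
#' (`<family>_seed<replicate>`) attached to the family's dam and sire, so
#' seed size can enter pedigree animal models like any other record.
#'
#' @param pedigree a pedigree data frame (`id`, `dam`, `sire`, ...).
#' @param seed_records family seed table with `family`, `dam`, `sire`,
#'   `replicate`, `trait`, `value`.
#' @return `augment_pedigree_with_seeds()`: the pedigree with one phantom
#'   F1 row per seed record; `seed_records_as_phenotypes()`: a long
#'   phenotype table (`id`, `trait`, `value`, `family`) for the same rows.
#' @export
augment_pedigree_with_seeds <- function(pedigree, seed_records) {
  extra <- data.frame(id = paste0(seed_records$family, "_seed",
                                  seed_records$replicate),
                      dam = seed_records$dam, sire = seed_records$sire,
                      stringsAsFactors = FALSE)
  for (v in setdiff(names(pedigree), names(extra))) extra[[v]] <- NA
  rbind(pedigree[, names(pedigree)], extra[, names(pedigree)])
}

#' @rdname augment_pedigree_with_seeds
#' @export
seed_records_as_phenotypes <- function(seed_records) {
  data.frame(id = paste0(seed_records$family, "_seed", seed_records$replicate),
             trait = seed_records$trait, value = seed_records$value,
             family = seed_records$family, stringsAsFactors = FALSE)
}

#' Model specification for a divergence linear mixed model
#'
#' A light container naming the response, the fixed terms and the iid
#' random grouping factors of a divergence model; [fit_lmm()] turns it into
#' an `lme4` formula.
#'
#' @param response response column name (default `"value"`).
#' @param fixed character vector of fixed-effect terms (may include
#'   interactions like `"trait:range"`).
#' @param random character vector of grouping factors fitted as iid random
#'   intercepts (e.g. `c("dam", "sire")`).
#' @return list of class `lmm_spec`.
#' @export
lmm_spec <- function(response = "value", fixed = c("range", "climate"),
                     random = c("dam", "sire")) {
  structure(list(response = response, fixed = fixed, random = random),
            class = "lmm_spec")
}

#' Fit a divergence linear mixed model (REML, crossed iid random intercepts)
#'
#' Fits the Gaussian LMM named by an [lmm_spec()] with `lme4::lmer` and
#' evaluates fixed terms with Wald chi-square tests. Random factors enter
#' as crossed iid random intercepts (dam, sire, family).
#'
#' @param spec an [lmm_spec()].
#' @param data data frame containing every column the spec names.
#' @return list of class `lmm_fit`: `model` (the `lmerMod`), `fixef`
#'   (estimate/SE table), `wald` (term, chisq, df, p), `varcomp` (named
#'   variance components incl. residual), `logLik`, `converged`.
#' @export
fit_lmm <- function(spec, data) {
  stopifnot(inherits(spec, "lmm_spec"))
  missing_cols <- setdiff(c(spec$response,
                            unique(unlist(strsplit(spec$fixed, ":", fixed = TRUE))),
                            spec$random), names(data))
  if (length(missing_cols))
    stop("data lacks columns named in the model spec: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (r in spec$random)
    if (length(unique(stats::na.omit(data[[r]]))) < 2)
      stop("random factor with < 2 levels: ", r, call. = FALSE)
  rhs <- paste(c(spec$fixed, sprintf("(1 | %s)", spec$random)), collapse = " + ")
  fml <- stats::as.formula(paste(spec$response, "~", rhs))
  mod <- lme4::lmer(fml, data = data, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  if (nrow(stats::model.frame(mod)) <= length(lme4::fixef(mod)))
    stop("model not identifiable: more coefficients than observations",
         call. = FALSE)
  wald <- car::Anova(mod, type = "II", test.statistic = "Chisq")
  vc <- as.data.frame(lme4::VarCorr(mod))
  varcomp <- stats::setNames(vc$vcov, ifelse(vc$grp == "Residual", "residual", vc$grp))
  co <- summary(mod)$coefficients
  out <- list(model = mod,
              fixef = data.frame(term = rownames(co), estimate = co[, 1],
                                 se = co[, 2], row.names = NULL),
              wald = data.frame(term = rownames(wald), chisq = wald$Chisq,
                                df = wald$Df, p = wald$`Pr(>Chisq)`,
                                row.names = NULL),
              varcomp = varcomp, logLik = as.numeric(stats::logLik(mod)),
              converged = length(mod@optinfo$conv$lme4$messages) == 0)
  class(out) <- "lmm_fit"
  out
}

#' Multivariate (stacked-trait) divergence test
#'
#' Tests overall trait divergence between ranges on family means: the long
#' family-mean table is modelled with trait, range and their interaction as
#' fixed effects, the climate covariate as a fixed covariate, and dam and
#' sire as crossed random intercepts; fixed terms are evaluated with Wald
#' chi-square tests. With `populations = TRUE` the model instead fits
#' population nested in range (climate dropped: it is constant within a
#' population).
#'
#' @param fam_table long family-mean table (`family`, `trait`, `value`,
#'   `range`, `climate`, `dam`, `sire`, and `population` if needed).
#' @param populations logical; fit the population-nested variant.
#' @param heterogeneous_residuals logical; allow a separate residual
#'   variance per trait (via `nlme::gls`-style weights using `glmmTMB` if
#'   available). Default `FALSE`: common residual variance.
#' @return an `lmm_fit` (see [fit_lmm()]).
#' @export
multivariate_divergence_test <- function(fam_table, populations = FALSE,
                                         heterogeneous_residuals = FALSE) {
  if (length(unique(fam_table$trait)) < 2)
    stop("need >= 2 traits for the multivariate test", call. = FALSE)
  if (length(unique(fam_table$range)) < 2)
    stop("both ranges must be present", call. = FALSE)
  fam_table$trait <- factor(fam_table$trait)
  fam_table$range <- factor(fam_table$range)
  if (heterogeneous_residuals) {
    if (!requireNamespace("glmmTMB", quietly = TRUE))
      stop("heterogeneous residuals require the glmmTMB package", call. = FALSE)
    fml <- if (populations)
      value ~ trait * range + trait * population + (1 | dam) + (1 | sire)
    else value ~ trait * range + climate + (1 | dam) + (1 | sire)
    mod <- glmmTMB::glmmTMB(fml, dispformula = ~trait, data = fam_table)
    wald <- car::Anova(mod, type = "II")
    return(structure(list(model = mod,
                          wald = data.frame(term = rownames(wald),
                                            chisq = wald$Chisq, df = wald$Df,
                                            p = wald$`Pr(>Chisq)`,
                                            row.names = NULL),
                          logLik = as.numeric(stats::logLik(mod)),
                          converged = TRUE), class = "lmm_fit"))
  }
  spec <- if (populations)
    lmm_spec("value", c("trait", "range", "trait:range", "population",
                        "trait:population"), c("dam", "sire"))
  else lmm_spec("value", c("trait", "range", "trait:range", "climate"),
                c("dam", "sire"))
  fit_lmm(spec, fam_table)
}

#' Per-trait range effects with Bonferroni flags
#'
#' Fits one divergence LMM per trait (range + climate fixed, dam and sire
#' random) and tabulates the standardized range coefficient, its Wald
#' chi-square and p value, and whether it stays significant after
#' Bonferroni correction for the number of traits tested
#' (threshold `alpha / k`, i.e. 0.005 for 10 traits at alpha = 0.05).
#'
#' @param data long standardized phenotype table with `trait`, `value`,
#'   `range`, `climate`, `dam`, `sire`.
#' @param traits traits to test (default: all in `data`).
#' @param alpha family-wise level (default 0.05).
#' @return data frame: trait, coefficient, se, chisq, p, bonferroni
#'   threshold and flag.
#' @export
univariate_range_effects <- function(data, traits = unique(data$trait),
                                     alpha = 0.05) {
  k <- length(traits)
  thr <- alpha / k
  spec <- lmm_spec("value", c("range", "climate"), c("dam", "sire"))
  rows <- lapply(traits, function(tr) {
    d <- data[data$trait == tr, , drop = FALSE]
    d$range <- factor(d$range)
    if ("native" %in% levels(d$range))
      d$range <- stats::relevel(d$range, ref = "native")
    fit <- fit_lmm(spec, d)
    ci <- grep("^range", fit$fixef$term)
    wi <- fit$wald$term == "range"
    data.frame(trait = tr, coefficient = fit$fixef$estimate[ci][1],
               se = fit$fixef$se[ci][1], chisq = fit$wald$chisq[wi],
               p = fit$wald$p[wi], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bonferroni_alpha <- thr
  out$significant <- out$p < thr
  rownames(out) <- NULL
  out
}

# compact letter display from a logical "significantly different" matrix,
# insert-and-absorb algorithm; levels must be ordered by decreasing mean
cld_letters <- function(diff_mat) {
  lv <- rownames(diff_mat)
  groups <- list(lv)
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (j <= i || !diff_mat[i, j]) next
    for (g in seq_along(groups)) {
      if (all(c(lv[i], lv[j]) %in% groups[[g]])) {
        g1 <- setdiff(groups[[g]], lv[i]); g2 <- setdiff(groups[[g]], lv[j])
        groups[[g]] <- g1
        groups <- c(groups, list(g2))
      }
    }
    # absorb: drop groups contained in another
    keep <- rep(TRUE, length(groups))
    for (a in seq_along(groups)) for (b in seq_along(groups))
      if (a != b && keep[a] && all(groups[[a]] %in% groups[[b]]) &&
          (length(groups[[a]]) < length(groups[[b]]) || a > b))
        keep[a] <- FALSE
    groups <- groups[keep]
  }
  # order groups by the first (highest-mean) member they contain
  ord <- order(vapply(groups, function(g) min(match(g, lv)), 0))
  groups <- groups[ord]
  out <- stats::setNames(rep("", length(lv)), lv)
  for (g in seq_along(groups))
    out[groups[[g]]] <- paste0(out[groups[[g]]], letters[g])
  out
}

#' Post hoc population contrasts with Tukey adjustment and letter groups
#'
#' Fits a per-trait LMM with population (nested in range) as a fixed effect
#' and dam and sire as random intercepts, computes estimated marginal means
#' per population, all pairwise contrasts with Tukey adjustment, and a
#' compact letter display (populations sharing a letter do not differ at
#' `alpha`).
#'
#' @param data long table for one trait: `value`, `population`, `dam`,
#'   `sire` (and `range`, unused in the fit since populations are nested).
#' @param alpha significance level for the letter display (default 0.05).
#' @return list of class `population_contrasts`: `emmeans` (population,
#'   emmean, SE), `contrasts` (pair, estimate, SE, t, adjusted p),
#'   `letters` (named character), `model`.
#' @export
posthoc_population_contrasts <- function(data, alpha = 0.05) {
  if (length(unique(data$population)) < 2)
    stop("need >= 2 populations", call. = FALSE)
  data$population <- factor(data$population)
  fit <- fit_lmm(lmm_spec("value", "population", c("dam", "sire")), data)
  emm <- emmeans::emmeans(fit$model, "population")
  prs <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"))
  es <- summary(emm)
  es <- es[order(-es$emmean), ]
  lv <- as.character(es$population)
  dm <- matrix(FALSE, length(lv), length(lv), dimnames = list(lv, lv))
  pair <- strsplit(as.character(prs$contrast), " - ", fixed = TRUE)
  for (k in seq_along(pair)) {
    a <- pair[[k]][1]; b <- pair[[k]][2]
    if (prs$p.value[k] < alpha) dm[a, b] <- dm[b, a] <- TRUE
  }
  out <- list(emmeans = data.frame(population = lv, emmean = es$emmean,
                                   se = es$SE, row.names = NULL),
              contrasts = data.frame(contrast = as.character(prs$contrast),
                                     estimate = prs$estimate, se = prs$SE,
                                     t = prs$t.ratio, p = prs$p.value,
                                     row.names = NULL),
              letters = cld_letters(dm), model = fit$model)
  class(out) <- "population_contrasts"
  out
}

#' Univariate pedigree animal model by REML
#'
#' Decomposes the phenotypic variance of one standardized trait into
#' additive genetic (via the pedigree relationship matrix A), nonadditive
#' family (iid per dam x sire family, reciprocals pooled) and residual
#' components, with block as a fixed effect:
#' `Var(y) = sigma2_a A + sigma2_na Z_f Z_f' + sigma2_e I`.
#'
#' @param trait trait name to model (rows of `data` are filtered to it),
#'   or `NULL` if `data` is already a single trait.
#' @param data long table with `id`, `trait`, `value`, `family`, and
#'   optionally `block` (fitted fixed when present).
#' @param A additive relationship matrix covering every `id` in the data
#'   (from [additive_relationship()]).
#' @param se logical; report asymptotic SEs of the components.
#' @return list of class `varcomp_qg`: `sigma2_a`, `sigma2_na`, `sigma2_e`,
#'   `proportions` (summing to 1), `logLik`, `converged`, `n`, `se` and
#'   `vcov_sigma2` (if requested), `reml` (engine fit).
#' @export
fit_animal_model <- function(trait = NULL, data, A, se = FALSE) {
  if (!is.null(trait)) data <- data[data$trait == trait, , drop = FALSE]
  data <- data[!is.na(data$value), , drop = FALSE]
  if (nrow(data) < 10)
    stop("insufficient data for the animal model (< 10 records)", call. = FALSE)
  if (!all(data$id %in% rownames(A)))
    stop("A does not cover every individual in the data", call. = FALSE)
  y <- data$value
  X <- if ("block" %in% names(data) && length(unique(data$block)) > 1)
    stats::model.matrix(~block, data) else matrix(1, nrow(data), 1)
  Aff <- A[data$id, data$id, drop = FALSE]
  Zf <- stats::model.matrix(~0 + factor(family), data)
  fit <- reml_varcomp(y, X, list(additive = Aff, family = tcrossprod(Zf)),
                      se = se)
  s2 <- fit$sigma2
  tot <- sum(s2)
  out <- list(sigma2_a = unname(s2["additive"]),
              sigma2_na = unname(s2["family"]),
              sigma2_e = unname(s2["residual"]),
              proportions = s2 / tot, logLik = fit$logLik,
              converged = fit$converged, n = fit$n, reml = fit)
  if (se) {
    out$se <- fit$se
    out$vcov_sigma2 <- fit$vcov_sigma2
  }
  class(out) <- "varcomp_qg"
  out
}

#' @export
print.varcomp_qg <- function(x, ...) {
  cat(sprintf("Animal model variance components (n = %d, logLik = %.3f)\n",
              x$n, x$logLik))
  cat(sprintf("  additive  sigma2_a  = %.4f (%.1f%%)\n", x$sigma2_a,
              100 * x$proportions["additive"]))
  cat(sprintf("  family    sigma2_na = %.4f (%.1f%%)\n", x$sigma2_na,
              100 * x$proportions["family"]))
  cat(sprintf("  residual  sigma2_e  = %.4f (%.1f%%)\n", x$sigma2_e,
              100 * x$proportions["residual"]))
  invisible(x)
}

#' Constrained (no additive variance) animal model
#'
#' Convenience wrapper fitting the null model with `sigma2_a` fixed at 0,
#' for likelihood-ratio testing against the full animal model.
#'
#' @inheritParams fit_animal_model
#' @return a `varcomp_qg` with `sigma2_a = 0`.
#' @export
fit_animal_model_null <- function(trait = NULL, data, A = NULL) {
  if (!is.null(trait)) data <- data[data$trait == trait, , drop = FALSE]
  data <- data[!is.na(data$value), , drop = FALSE]
  y <- data$value
  X <- if ("block" %in% names(data) && length(unique(data$block)) > 1)
    stats::model.matrix(~block, data) else matrix(1, nrow(data), 1)
  Zf <- stats::model.matrix(~0 + factor(family), data)
  fit <- reml_varcomp(y, X, list(family = tcrossprod(Zf)))
  out <- list(sigma2_a = 0, sigma2_na = unname(fit$sigma2["family"]),
              sigma2_e = unname(fit$sigma2["residual"]),
              proportions = c(additive = 0, fit$sigma2 / sum(fit$sigma2)),
              logLik = fit$logLik, converged = fit$converged, n = fit$n,
              reml = fit)
  class(out) <- "varcomp_qg"
  out
}

#' Likelihood-ratio test for additive genetic variance
#'
#' Compares the full animal model against the null with `sigma2_a`
#' constrained to zero. Because the null pins a variance at the boundary of
#' its parameter space, the reference distribution is the 50:50 mixture of
#' chi-square(0) and chi-square(1). Significance tiers follow the usual
#' dagger/asterisk convention at 0.1 / 0.05 / 0.01 / 0.001.
#'
#' @param fit_full,fit_null `varcomp_qg` fits of the full and constrained
#'   model on identical data.
#' @param tol tolerance below which a negative LRT is treated as 0.
#' @return list: `lrt`, `p`, `stars`.
#' @export
test_additive_variance <- function(fit_full, fit_null, tol = 1e-6) {
  lrt <- 2 * (fit_full$logLik - fit_null$logLik)
  if (lrt < -tol)
    stop("full-model likelihood below null: convergence failure", call. = FALSE)
  lrt <- max(lrt, 0)
  p <- 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  if (lrt == 0) p <- 0.5  # point mass of chi-square(0) sits exactly at 0
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else if (p < 0.1) "†" else ""
  list(lrt = lrt, p = p, stars = stars)
}

#' Regression of range divergence on additive variance
#'
#' Ordinary least squares of the absolute per-trait range divergence on the
#' per-trait additive genetic variance (summarized as the median over
#' populations of the population-mean V_A), with an optional refit
#' excluding named traits.
#'
#' @param divergence named numeric vector of per-trait range coefficients
#'   (absolute values are taken).
#' @param va_medians named numeric vector of per-trait V_A medians, same
#'   names as `divergence`.
#' @param exclude optional trait names to drop in a second fit.
#' @return list of class `va_divergence_fit`: `slope`, `t`, `p`,
#'   `r_squared`, `model`, `degenerate` (TRUE when V_A is constant so the
#'   slope is undefined), and `excluded_fit` (same fields, or `NULL`).
#' @export
divergence_va_regression <- function(divergence, va_medians, exclude = NULL) {
  traits <- intersect(names(divergence), names(va_medians))
  if (length(traits) < 3) stop("need >= 3 traits", call. = FALSE)
  d <- data.frame(trait = traits, div = abs(divergence[traits]),
                  va = va_medians[traits])
  fit_one <- function(dd) {
    if (stats::sd(dd$va) == 0)
      return(list(slope = NA_real_, t = NA_real_, p = NA_real_,
                  r_squared = NA_real_, model = NULL, degenerate = TRUE))
    m <- stats::lm(div ~ va, dd)
    co <- summary(m)$coefficients
    list(slope = co["va", 1], t = co["va", 3], p = co["va", 4],
         r_squared = summary(m)$r.squared, model = m, degenerate = FALSE)
  }
  out <- fit_one(d)
  out$data <- d
  out$excluded_fit <- if (!is.null(exclude)) {
    dd <- d[!d$trait %in% exclude, , drop = FALSE]
    if (nrow(dd) >= 3) fit_one(dd) else NULL
  } else NULL
  class(out) <- "va_divergence_fit"
  out
}
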