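#' Derived plant traits
#'
#' Simple derivations used before analysis: relative growth rate from two
#' height measurements taken two weeks apart, specific leaf area (SLA) from
#' fresh leaf area and dry mass, and flowering duration from onset and last
#' flowering days. Missing inputs propagate to missing outputs.
#'
#' @param height_wk8,height_wk10 heights (cm) at weeks 8 and 10.
#' @return `derive_growth_rate()`: growth rate in cm/day,
#'   `(height_wk10 - height_wk8) / 14`.
#' @name derived_traits
#' @export
derive_growth_rate <- function(height_wk8, height_wk10) {
  (height_wk10 - height_wk8) / 14
}

#' @rdname derived_traits
#' @param leaf_area fresh leaf area; `dry_mass` leaf dry mass (> 0).
#' @param dry_mass leaf dry mass.
#' @return `derive_sla()`: specific leaf area, `leaf_area / dry_mass`.
#' @export
derive_sla <- function(leaf_area, dry_mass) {
  if (any(!is.na(dry_mass) & dry_mass <= 0))
    stop("dry_mass must be > 0", call. = FALSE)
  leaf_area / dry_mass
}

#' @rdname derived_traits
#' @param onset_day,last_day day of first and of last flower; `last_day`
#'   must not precede `onset_day`.
#' @return `derive_flowering_duration()`: days from onset to last flower.
#' @export
derive_flowering_duration <- function(onset_day, last_day) {
  bad <- !is.na(onset_day) & !is.na(last_day) & last_day < onset_day
  if (any(bad)) stop("last_day precedes onset_day", call. = FALSE)
  last_day - onset_day
}

#' Standardize traits to mean 0, SD 1
#'
#' Z-scores each trait across all individuals (long-format table), keeping
#' the per-trait mean and SD as an attribute so values can be
#' back-transformed. Missing values are left untouched and excluded from the
#' moments.
#'
#' @param table long phenotype table with `trait` and `value` columns.
#' @return the table with `value` standardized per trait, carrying a
#'   `scaling` attribute (data frame: trait, mean, sd).
#' @export
standardize_traits <- function(table) {
  stopifnot(all(c("trait", "value") %in% names(table)))
  sp <- split(table$value, table$trait)
  mu <- vapply(sp, function(v) mean(v, na.rm = TRUE), 0)
  sd_ <- vapply(sp, function(v) stats::sd(v, na.rm = TRUE), 0)
  nn <- vapply(sp, function(v) sum(!is.na(v)), 0L)
  if (any(nn < 2)) stop("need >= 2 non-missing values per trait", call. = FALSE)
  if (any(sd_ == 0))
    stop("constant trait (zero SD): ",
         paste(names(sd_)[sd_ == 0], collapse = ", "), call. = FALSE)
  i <- match(table$trait, names(mu))
  table$value <- (table$value - mu[i]) / sd_[i]
  attr(table, "scaling") <- data.frame(trait = names(mu), mean = unname(mu),
                                       sd = unname(sd_), stringsAsFactors = FALSE)
  table
}

#' Undo a standardization
#'
#' @param table a table produced by [standardize_traits()] (or any long
#'   table plus an explicit `scaling` data frame).
#' @param scaling data frame with `trait`, `mean`, `sd`.
#' @return the table on the original scale.
#' @export
unstandardize_traits <- function(table, scaling = attr(table, "scaling")) {
  if (is.null(scaling)) stop("no scaling attribute found", call. = FALSE)
  i <- match(table$trait, scaling$trait)
  table$value <- table$value * scaling$sd[i] + scaling$mean[i]
  attr(table, "scaling") <- NULL
  table
}

#' Family means of a long phenotype table
#'
#' Arithmetic mean per family x trait, carrying dam and sire ids and any
#' family-constant metadata (population, range, climate). Used so that
#' family-level measurements (bulked seed size) can enter multivariate
#' divergence models next to individually measured traits.
#'
#' @param table long table with `family`, `trait`, `value` and optionally
#'   `dam`, `sire`, `population`, `range`, `climate` columns (taken from the
#'   pedigree/crosses when family-constant).
#' @param crosses optional cross table supplying `dam`/`sire` per family.
#' @return long table with one row per family x trait.
#' @export
family_means <- function(table, crosses = NULL) {
  stopifnot(all(c("family", "trait", "value") %in% names(table)))
  mean_na <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  out <- stats::aggregate(value ~ family + trait, data = table, FUN = mean_na,
                          na.action = stats::na.pass)
  # carry family-constant metadata
  meta_cols <- intersect(c("population", "range", "climate", "dam", "sire"),
                         names(table))
  if (length(meta_cols)) {
    first <- table[!duplicated(table$family), c("family", meta_cols)]
    out <- merge(out, first, by = "family", sort = FALSE)
  }
  if (!is.null(crosses)) {
    fam <- crosses[!duplicated(crosses$family), c("family", "dam", "sire")]
    # dam/sire of the canonical (lexicographically first) cross member
    lo <- pmin(fam$dam, fam$sire); hi <- pmax(fam$dam, fam$sire)
    fam$dam <- lo; fam$sire <- hi
    out$dam <- NULL; out$sire <- NULL
    out <- merge(out, fam, by = "family", sort = FALSE)
  }
  out[order(out$trait, out$family), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Seed drop-time regression with backward partial-F model selection
#'
#' Fits the full multiple regression of mean drop time on seed size and
#' pappus length, then drops the predictor whose partial F-test is
#' non-significant (backward elimination at `alpha`), and refits. Returns
#' the retained model with per-term coefficients, t statistics, p values
#' and R-squared.
#'
#' @param drop_table table from [simulate_drop_time()] (or measured data
#'   with columns `seed_size`, `pappus_length` and either `drop_time` or
#'   `drop_1`/`drop_2`, which are averaged).
#' @param alpha significance level for the partial F-test (default 0.05).
#' @return list of class `drop_time_model`: `model` (the lm fit), `retained`
#'   (character), `dropped`, `coefficients` (term, estimate, se, t, p),
#'   `r_squared`, `partial_F` (the full-model partial F table).
#' @export
select_drop_time_model <- function(drop_table, alpha = 0.05) {
  stopifnot(all(c("seed_size", "pappus_length") %in% names(drop_table)))
  if (!"drop_time" %in% names(drop_table)) {
    stopifnot(all(c("drop_1", "drop_2") %in% names(drop_table)))
    drop_table$drop_time <- (drop_table$drop_1 + drop_table$drop_2) / 2
  }
  if (nrow(drop_table) < 3) stop("need >= 3 seeds", call. = FALSE)
  full <- stats::lm(drop_time ~ seed_size + pappus_length, data = drop_table)
  if (any(is.na(stats::coef(full))))
    stop("degenerate (collinear) predictors", call. = FALSE)
  pf_tab <- stats::drop1(full, test = "F")
  terms_ <- rownames(pf_tab)[-1]
  pvals <- pf_tab[["Pr(>F)"]][-1]
  dropped <- character(0)
  retained <- terms_
  if (any(pvals > alpha, na.rm = TRUE)) {
    # backward: remove the least significant term, then re-test
    worst <- terms_[which.max(pvals)]
    dropped <- worst
    retained <- setdiff(terms_, worst)
    fml <- stats::reformulate(if (length(retained)) retained else "1",
                              response = "drop_time")
    fit <- stats::lm(fml, data = drop_table)
    if (length(retained)) {
      p2 <- stats::drop1(fit, test = "F")[["Pr(>F)"]][-1]
      if (any(p2 > alpha, na.rm = TRUE)) {
        dropped <- c(dropped, retained[which.max(p2)])
        retained <- setdiff(retained, retained[which.max(p2)])
        fit <- stats::lm(stats::reformulate(
          if (length(retained)) retained else "1", "drop_time"), drop_table)
      }
    }
  } else {
    fit <- full
  }
  sm <- summary(fit)
  co <- sm$coefficients
  out <- list(model = fit, retained = retained, dropped = dropped,
              coefficients = data.frame(term = rownames(co),
                                        estimate = co[, 1], se = co[, 2],
                                        t = co[, 3], p = co[, 4],
                                        row.names = NULL),
              r_squared = sm$r.squared, partial_F = pf_tab)
  class(out) <- "drop_time_model"
  out
}

#' @export
print.drop_time_model <- function(x, ...) {
  cat("Drop-time model selection (backward partial-F)\n")
  cat("  retained:", if (length(x$retained)) paste(x$retained, collapse = " + ")
      else "(intercept only)", "\n")
  if (length(x$dropped)) cat("  dropped:", paste(x$dropped, collapse = ", "), "\n")
  cat(sprintf("  R-squared = %.3f\n", x$r_squared))
  print(x$coefficients, digits = 3)
  invisible(x)
}
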