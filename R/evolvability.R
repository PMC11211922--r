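#' Evolvability along a selection gradient
#'
#' The expected proportional response of a population with additive
#' covariance matrix G to directional selection along gradient beta:
#' `e(beta) = beta' G beta / (beta' beta)`. This equals the projection of
#' the response vector `dz = G beta` onto the direction of selection,
#' `|dz| cos(theta) / |beta|`, with `theta` the angle between `beta` and
#' `dz` (the Hansen-Houle identity); the two forms agree to numerical
#' precision and the quadratic form is used.
#'
#' @param G symmetric trait covariance matrix.
#' @param beta nonzero selection gradient (normalized internally).
#' @return evolvability `e` (scalar).
#' @export
evolvability <- function(G, beta) {
  G <- as.matrix(G)
  if (!isSymmetric(unname(G), tol = 1e-8))
    stop("G must be symmetric", call. = FALSE)
  beta <- as.numeric(beta)
  nb <- sqrt(sum(beta^2))
  if (nb == 0) stop("beta must be nonzero", call. = FALSE)
  if (length(beta) != nrow(G))
    stop("beta length must match G dimension", call. = FALSE)
  drop(crossprod(beta, G %*% beta)) / nb^2
}

#' Selection response vector and angle to the gradient
#'
#' `dz = G beta` and the angle theta between beta and dz, the ingredients
#' of the projection form of evolvability.
#'
#' @inheritParams evolvability
#' @return list: `dz`, `theta` (radians), `e_projection`
#'   (`|dz| cos(theta) / |beta|`).
#' @export
selection_response <- function(G, beta) {
  beta <- as.numeric(beta)
  dz <- drop(as.matrix(G) %*% beta)
  nb <- sqrt(sum(beta^2)); nd <- sqrt(sum(dz^2))
  ct <- if (nd == 0) 0 else sum(beta * dz) / (nb * nd)
  ct <- min(1, max(-1, ct))
  list(dz = dz, theta = acos(ct), e_projection = nd * ct / nb)
}

#' Random sign-constrained selection gradient
#'
#' Draws a gradient whose element signs follow a fixed hypothesis about the
#' direction of novel selection (e.g. increased leaf mass and allelopathy,
#' decreased seed size): elementwise |standard normal| magnitudes with the
#' imposed signs, normalized to unit length — uniform over the specified
#' orthant of the unit sphere. Deterministic under `set.seed()`.
#'
#' @param sign_pattern character (`"+"`/`"-"`) or numeric (+1/-1) vector,
#'   one sign per trait.
#' @param n number of gradients (default 1).
#' @return a unit-length numeric vector (or an `n` x d matrix of row
#'   gradients when `n > 1`).
#' @export
random_selection_gradient <- function(sign_pattern, n = 1) {
  s <- parse_signs(sign_pattern)
  d <- length(s)
  m <- abs(matrix(stats::rnorm(n * d), n, d))
  m <- sweep(m, 2, s, `*`)
  m <- m / sqrt(rowSums(m^2))
  if (n == 1) drop(m) else m
}

parse_signs <- function(sign_pattern) {
  if (length(sign_pattern) == 0) stop("empty sign pattern", call. = FALSE)
  if (is.character(sign_pattern)) {
    if (!all(sign_pattern %in% c("+", "-")))
      stop("sign pattern must be '+'/'-'", call. = FALSE)
    ifelse(sign_pattern == "+", 1, -1)
  } else {
    s <- sign(as.numeric(sign_pattern))
    if (any(s == 0)) stop("sign pattern must be non-zero", call. = FALSE)
    s
  }
}

#' R metric: effect of genetic covariances on evolvability
#'
#' Ratio of evolvability under the full G-matrix to evolvability under G
#' with all off-diagonal elements set to zero. `R < 1` means covariances
#' constrain evolution along `beta`; `R > 1` means they facilitate it; for
#' any diagonal G, `R = 1` exactly.
#'
#' @inheritParams evolvability
#' @return the scalar R.
#' @export
r_score <- function(G, beta) {
  G <- as.matrix(G)
  if (any(diag(G) <= 0))
    stop("diag(G) must be strictly positive", call. = FALSE)
  evolvability(G, beta) / evolvability(diag(diag(G), nrow(G)), beta)
}

#' Posterior distribution of the R metric under random novel selection
#'
#' For each retained G sample, draws one fresh sign-constrained random
#' gradient and computes R, so the resulting distribution mixes posterior
#' uncertainty in G with uncertainty in the (unknown) novel selection
#' gradient. R is tested against 1 with a 90% HPD interval: covariances
#' "constrain" if the interval lies below 1, "facilitate" if above, else
#' "neither".
#'
#' @param posterior a `gmatrix_posterior` (>= 100 retained samples), or a
#'   3-d array of G samples (d x d x S).
#' @param sign_pattern per-trait signs (see [random_selection_gradient()]),
#'   or a preset name from [trait_set_presets()].
#' @param seed RNG seed for the gradient draws.
#' @param mass HPD mass for the verdict (default 0.90).
#' @return list of class `evolvability_result`: `R` (per-sample), `e_full`,
#'   `e_diag`, `theta`, `hpd`, `mean_R`, `verdict`.
#' @export
r_posterior <- function(posterior, sign_pattern, seed = 1L, mass = 0.90) {
  Garr <- if (inherits(posterior, "gmatrix_posterior")) posterior$G else posterior
  S <- dim(Garr)[3]
  if (is.null(S) || S < 100) stop("need >= 100 posterior samples", call. = FALSE)
  if (is.character(sign_pattern) && length(sign_pattern) == 1 &&
      !sign_pattern %in% c("+", "-"))
    sign_pattern <- trait_set_presets(sign_pattern)$signs
  set.seed(seed)
  betas <- random_selection_gradient(sign_pattern, n = S)
  e_full <- e_diag <- theta <- numeric(S)
  for (s in seq_len(S)) {
    G <- Garr[, , s]
    b <- betas[s, ]
    e_full[s] <- evolvability(G, b)
    e_diag[s] <- evolvability(diag(diag(G), nrow(G)), b)
    theta[s] <- selection_response(G, b)$theta
  }
  R <- e_full / e_diag
  hp <- hpd_interval(R, mass)
  verdict <- if (hp["upper"] < 1) "constrains"
  else if (hp["lower"] > 1) "facilitates" else "neither"
  structure(list(R = R, e_full = e_full, e_diag = e_diag, theta = theta,
                 hpd = hp, mean_R = mean(R), verdict = verdict,
                 sign_pattern = sign_pattern, mass = mass),
            class = "evolvability_result")
}

#' @export
print.evolvability_result <- function(x, ...) {
  cat(sprintf("R-score posterior: mean = %.3f, %d%% HPD = [%.3f, %.3f]\n",
              x$mean_R, round(100 * x$mass), x$hpd["lower"], x$hpd["upper"]))
  cat("  verdict vs 1:", x$verdict, "\n")
  invisible(x)
}

#' Named sign patterns for the hypothesized novel selection
#'
#' `"competitive"`: novel selection favors increased leaf mass and
#' polyacetylene concentration and decreased seed size (smaller seeds
#' disperse better). `"reproductive"`: favors later first flowering and
#' increased rhizome mass with decreased seed size; the reproductive signs
#' follow the observed divergence directions and are a documented
#' assumption, configurable by passing an explicit pattern instead.
#'
#' @param name preset name, or missing to list all presets.
#' @return list with `traits` and `signs` (or a named list of presets).
#' @export
trait_set_presets <- function(name) {
  presets <- list(
    competitive = list(traits = c("leaf_mass", "polyacetylenes", "seed_size"),
                       signs = c(1, 1, -1), assumed = FALSE),
    reproductive = list(traits = c("days_to_flower", "rhizome_mass", "seed_size"),
                        signs = c(1, 1, -1), assumed = TRUE))
  if (missing(name)) return(presets)
  if (!name %in% names(presets))
    stop("unknown preset: ", name, " (available: ",
         paste(names(presets), collapse = ", "), ")", call. = FALSE)
  presets[[name]]
}
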