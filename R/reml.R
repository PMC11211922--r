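# REML engine for Gaussian mixed models with known random-effect covariance
# structures: y = X beta + sum_k u_k + e,  u_k ~ N(0, sigma2_k * V_k),
# e ~ N(0, sigma2_e * I), with each V_k an n x n known matrix (e.g. the
# pedigree A submatrix for additive effects, Z Z' for iid family effects).
# The likelihood is profiled over sigma2_e and maximized over the variance
# ratios gamma_k = sigma2_k / sigma2_e, constrained >= 0.

# REML log-likelihood pieces at unit residual scale V0 = I + sum gamma_k V_k
reml_pieces <- function(gamma, y, X, Vlist) {
  n <- length(y); p <- ncol(X)
  V0 <- diag(n)
  for (k in seq_along(Vlist)) V0 <- V0 + gamma[k] * Vlist[[k]]
  U <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(U)) return(NULL)
  ldV0 <- 2 * sum(log(diag(U)))
  M <- backsolve(U, cbind(X, y), transpose = TRUE)  # t(U)^-1 [X y]
  Mx <- M[, seq_len(p), drop = FALSE]; My <- M[, p + 1L]
  XtViX <- crossprod(Mx)
  XtViy <- crossprod(Mx, My)
  Ux <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(Ux)) return(NULL)
  ldXVX <- 2 * sum(log(diag(Ux)))
  beta <- backsolve(Ux, backsolve(Ux, XtViy, transpose = TRUE))
  q <- drop(crossprod(My) - crossprod(XtViy, beta))  # y' P0 y
  list(ldV0 = ldV0, ldXVX = ldXVX, q = q, beta = drop(beta), n = n, p = p,
       XtViX = XtViX)
}

# profiled REML log-likelihood (lme4/ASReml constant convention)
reml_profile_ll <- function(gamma, y, X, Vlist) {
  pc <- reml_pieces(gamma, y, X, Vlist)
  if (is.null(pc) || pc$q <= 0) return(-Inf)
  np <- pc$n - pc$p
  s2e <- pc$q / np
  -0.5 * (np * log(2 * pi) + np * log(s2e) + pc$ldV0 + pc$ldXVX + np)
}

# unprofiled REML log-likelihood in terms of the variance components
# sigma2 = c(sigma2_k ..., sigma2_e); used for numeric Hessians / SEs
reml_ll_sigma <- function(sigma2, y, X, Vlist) {
  ne <- length(sigma2)
  s2e <- sigma2[ne]
  if (s2e <= 0) return(-Inf)
  gamma <- sigma2[-ne] / s2e
  pc <- reml_pieces(gamma, y, X, Vlist)
  if (is.null(pc)) return(-Inf)
  np <- pc$n - pc$p
  # log|V| = n log s2e + ldV0 ; log|X'V-1X| = ldXVX - p log s2e ; yPy = q/s2e
  -0.5 * (np * log(2 * pi) + np * log(s2e) + pc$ldV0 + pc$ldXVX + pc$q / s2e)
}

#' REML variance components for known covariance structures
#'
#' Maximizes the restricted likelihood of a Gaussian mixed model whose
#' random effects have known n x n covariance structures, by profiling out
#' the residual variance and optimizing the variance ratios (constrained
#' non-negative, clamped at 1e-10) with a quasi-Newton box-constrained
#' optimizer and a derivative-free Nelder-Mead fallback. Convergence
#' tolerance is 1e-8 on the log-likelihood scale.
#'
#' @param y numeric response.
#' @param X fixed-effect design matrix (full column rank).
#' @param Vlist named list of n x n covariance structure matrices.
#' @param se logical; compute asymptotic SEs of the variance components from
#'   the numeric Hessian of the (unprofiled) REML log-likelihood.
#' @param start optional starting variance ratios.
#' @return list of class `reml_fit`: `sigma2` (named: components then
#'   `residual`), `gamma`, `beta`, `beta_vcov`, `logLik`, `converged`,
#'   `se` (if requested), `n`, `p`.
#' @export
reml_varcomp <- function(y, X, Vlist, se = FALSE, start = NULL) {
  X <- as.matrix(X)
  keep <- !is.na(y)
  if (!all(keep)) {
    y <- y[keep]; X <- X[keep, , drop = FALSE]
    Vlist <- lapply(Vlist, function(V) V[keep, keep, drop = FALSE])
  }
  n <- length(y); p <- qr(X)$rank
  if (p < ncol(X)) stop("fixed-effect design is rank deficient", call. = FALSE)
  if (n <= ncol(X) + length(Vlist))
    stop("insufficient data: fewer observations than parameters", call. = FALSE)
  K <- length(Vlist)
  if (K == 0) {
    fit <- stats::lm.fit(X, y)
    s2 <- sum(fit$residuals^2) / (n - p)
    return(structure(list(sigma2 = c(residual = s2), gamma = numeric(0),
                          beta = fit$coefficients, logLik = NA_real_,
                          converged = TRUE, n = n, p = p), class = "reml_fit"))
  }
  if (is.null(start)) start <- rep(0.5, K)
  negll <- function(g) -reml_profile_ll(g, y, X, Vlist)
  opt <- stats::nlminb(start, negll, lower = rep(0, K), upper = rep(1e6, K),
                       control = list(rel.tol = 1e-12, abs.tol = 1e-14,
                                      x.tol = 1e-10, iter.max = 500))
  converged <- opt$convergence == 0
  if (!is.finite(opt$objective) || !converged) {
    # derivative-free fallback on |gamma| (Brent for a single ratio)
    opt2 <- if (K == 1)
      stats::optim(pmax(start, 0.1), function(g) negll(abs(g)),
                   method = "Brent", lower = 0, upper = 1e4,
                   control = list(reltol = 1e-12))
    else
      stats::optim(pmax(start, 0.1), function(g) negll(abs(g)),
                   method = "Nelder-Mead",
                   control = list(reltol = 1e-12, maxit = 2000))
    if (is.finite(opt2$value) && (opt2$value < opt$objective || !is.finite(opt$objective))) {
      opt <- list(par = abs(opt2$par), objective = opt2$value,
                  convergence = opt2$convergence)
      converged <- opt2$convergence == 0
    }
  }
  if (!is.finite(opt$objective))
    stop("REML optimization failed to find a finite likelihood", call. = FALSE)
  gamma <- pmax(opt$par, 0)
  pc <- reml_pieces(gamma, y, X, Vlist)
  s2e <- pc$q / (pc$n - pc$p)
  sigma2 <- pmax(c(gamma * s2e, s2e), 1e-10)
  names(sigma2) <- c(if (!is.null(names(Vlist))) names(Vlist)
                     else paste0("u", seq_len(K)), "residual")
  out <- list(sigma2 = sigma2, gamma = gamma, beta = pc$beta,
              beta_vcov = solve(pc$XtViX) * s2e,
              logLik = -opt$objective, converged = converged, n = n, p = p)
  if (se) {
    H <- numeric_hessian(function(s) reml_ll_sigma(s, y, X, Vlist), sigma2)
    cv <- tryCatch(solve(-H), error = function(e) matrix(NA, K + 1, K + 1))
    out$vcov_sigma2 <- cv
    out$se <- stats::setNames(sqrt(pmax(diag(cv), 0)), names(sigma2))
  }
  class(out) <- "reml_fit"
  out
}

# central-difference Hessian; steps scaled to parameter magnitude
numeric_hessian <- function(f, x, h = NULL) {
  k <- length(x)
  if (is.null(h)) h <- pmax(abs(x), 1e-3) * 1e-4
  H <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- numeric(k); ei[i] <- h[i]; ej[j] <- h[j]
      fpp <- f(x + ei + ej); fpm <- f(x + ei - ej)
      fmp <- f(x - ei + ej); fmm <- f(x - ei - ej)
      H[i, j] <- H[j, i] <- (fpp - fpm - fmp + fmm) / (4 * h[i] * h[j])
    }
  }
  H
}
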