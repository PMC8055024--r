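#' Beta-binomial probability mass function
#'
#' Density of the beta-binomial distribution parameterised by its mean
#' `mu` and precision `theta` (the sum of the two beta shape parameters,
#' `shape1 = mu * theta`, `shape2 = (1 - mu) * theta`). Small `theta`
#' means strong overdispersion relative to the binomial; as
#' `theta -> Inf` the distribution converges to `Binomial(n, mu)`, and
#' `theta = Inf` is accepted and evaluated as the exact binomial.
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials.
#' @param mu mean in (0, 1).
#' @param theta precision, > 0 (possibly `Inf`).
#' @param log return log-density?
#' @return Density (or log-density), vectorised over `k`, `n`, `mu`.
#' @examples
#' dbetabinom(0:2, 2, 0.5, 2)   # uniform: 1/3 each
#' @export
dbetabinom <- function(k, n, mu, theta, log = FALSE) {
  if (any(theta <= 0)) stop("theta must be > 0")
  if (any(mu <= 0 | mu >= 1)) stop("mu must lie strictly in (0, 1)")
  if (any(k < 0 | k > n)) stop("k must satisfy 0 <= k <= n")
  if (any(k %% 1 != 0 | n %% 1 != 0)) stop("k and n must be integers")
  if (all(is.infinite(theta)))
    return(stats::dbinom(k, n, mu, log = log))
  a <- mu * theta
  b <- (1 - mu) * theta
  ll <- lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
  if (log) ll else exp(ll)
}

## internal: sum of beta-binomial log-likelihood at linear predictor eta
.bb_loglik <- function(k, n, eta, theta) {
  mu <- stats::plogis(eta)
  # clamp away from 0/1; qlogis bounds keep lbeta finite
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  if (is.infinite(theta)) return(sum(stats::dbinom(k, n, mu, log = TRUE)))
  a <- mu * theta
  b <- (1 - mu) * theta
  sum(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
}

## internal: first and second derivatives of the per-observation
## beta-binomial log-likelihood with respect to the linear predictor
.bb_eta_derivs <- function(k, n, eta, theta) {
  mu <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
  mp <- mu * (1 - mu)
  if (is.infinite(theta)) {
    return(list(d1 = k - n * mu, d2 = -n * mp))
  }
  a <- mu * theta
  b <- (1 - mu) * theta
  g <- theta * (digamma(k + a) - digamma(n - k + b) - digamma(a) + digamma(b))
  dg <- theta^2 * (trigamma(k + a) + trigamma(n - k + b) -
                     trigamma(a) - trigamma(b))
  list(d1 = g * mp, d2 = dg * mp^2 + g * mp * (1 - 2 * mu))
}

#' Beta-binomial regression by maximum likelihood
#'
#' Fits `k ~ BetaBinomial(n, mu, theta)` with `logit(mu) = X beta +
#' offset` by quasi-Newton maximisation of the joint likelihood in
#' `(beta, log theta)`. Standard errors come from the inverse observed
#' information (numerical Hessian at the optimum); Wald z statistics and
#' two-sided p-values are reported per coefficient. On a flagged
#' non-convergence the optimiser is restarted from up to three jittered
#' starts; failure is never silent (`converged` is part of the fit).
#'
#' @param k,n integer vectors of successes and trials.
#' @param X design matrix (include an intercept column yourself); must
#'   have full column rank.
#' @param offset optional offset on the logit scale.
#' @param theta_fixed if non-`NULL`, the precision is held at this value
#'   (use `Inf` for a plain binomial fit) and not counted as an
#'   estimated parameter.
#' @return An object of class `betabin_fit` with elements
#'   `coefficients`, `se`, `z`, `p_value`, `theta`, `logLik`, `AIC`,
#'   `n_obs`, `n_par`, `converged`, `vcov`.
#' @examples
#' set.seed(1)
#' x <- runif(50); n <- rep(20, 50)
#' k <- rbinom(50, n, plogis(-1 + 2 * x))
#' fit_betabin_regression(k, n, cbind(1, x))$coefficients
#' @export
fit_betabin_regression <- function(k, n, X, offset = NULL,
                                   theta_fixed = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))[seq_len(ncol(X))]
  nm <- colnames(X)
  if (length(k) != length(n) || nrow(X) != length(k))
    stop("k, n and rows of X must have the same length")
  if (any(k < 0 | k > n)) stop("need 0 <= k <= n")
  if (qr(X)$rank < ncol(X)) stop("X must have full column rank")
  if (is.null(offset)) offset <- rep(0, length(k))
  p <- ncol(X)
  est_theta <- is.null(theta_fixed)

  negll <- function(par) {
    beta <- par[seq_len(p)]
    theta <- if (est_theta) exp(par[p + 1]) else theta_fixed
    ll <- .bb_loglik(k, n, drop(X %*% beta) + offset, theta)
    if (!is.finite(ll)) 1e10 else -ll
  }

  # empirical-logit start for beta
  z0 <- stats::qlogis((k + 0.5) / (n + 1)) - offset
  beta0 <- tryCatch(qr.solve(X, z0), error = function(e) rep(0, p))
  start <- if (est_theta) c(beta0, log(10)) else beta0

  best <- NULL
  for (attempt in 1:4) {
    st <- if (attempt == 1) start else
      start + stats::rnorm(length(start), 0, 0.5)
    opt <- tryCatch(
      stats::optim(st, negll, method = "BFGS", hessian = TRUE,
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(opt) &&
        (is.null(best) || opt$value < best$value - 1e-8)) best <- opt
    if (!is.null(best) && best$convergence == 0) break
  }
  if (is.null(best)) stop("beta-binomial optimisation failed to evaluate")

  par <- best$par
  beta <- par[seq_len(p)]
  names(beta) <- nm
  theta <- if (est_theta) exp(par[p + 1]) else theta_fixed
  vc <- tryCatch(solve(best$hessian), error = function(e) NULL)
  se <- rep(NA_real_, p)
  if (!is.null(vc)) {
    dv <- diag(vc)[seq_len(p)]
    dv[!is.finite(dv) | dv <= 0] <- NA_real_
    se <- sqrt(dv)
  }
  names(se) <- nm
  zstat <- beta / se
  n_par <- p + as.integer(est_theta)
  ll <- -best$value
  structure(list(
    coefficients = beta, se = se, z = zstat,
    p_value = 2 * stats::pnorm(-abs(zstat)),
    theta = theta, theta_estimated = est_theta,
    logLik = ll, AIC = 2 * n_par - 2 * ll,
    n_obs = length(k), n_par = n_par,
    converged = best$convergence == 0,
    vcov = if (is.null(vc)) NULL else vc[seq_len(p), seq_len(p), drop = FALSE]),
    class = "betabin_fit")
}

#' @export
print.betabin_fit <- function(x, ...) {
  cat(sprintf("Beta-binomial %s (logit link), %d observations%s\n",
              if (is.null(x$var_comp)) "regression" else "mixed model",
              x$n_obs, if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se,
               z = x$z, `Pr(>|z|)` = x$p_value)
  print(round(tab, 4))
  cat(sprintf("theta = %s%s, logLik = %.3f, AIC = %.2f\n",
              format(x$theta, digits = 4),
              if (x$theta_estimated) "" else " (fixed)", x$logLik, x$AIC))
  if (!is.null(x$var_comp)) {
    cat("random-intercept SDs:\n")
    print(round(x$var_comp, 5))
  }
  invisible(x)
}

## internal: Laplace-approximate marginal log-likelihood for random
## intercepts. Z: N x q indicator matrix; sd_u: per-column SD (length q).
## Returns list(ll, u_hat). Mode found by damped Newton with analytic
## gradient/Hessian, warm-started at u0.
.laplace_ll <- function(k, n, Xb_off, Z, sd_u, theta, u0 = NULL) {
  q <- ncol(Z)
  u <- if (is.null(u0)) rep(0, q) else u0
  prec <- 1 / sd_u^2
  pll <- function(u) {
    .bb_loglik(k, n, Xb_off + drop(Z %*% u), theta) +
      sum(stats::dnorm(u, 0, sd_u, log = TRUE))
  }
  cur <- pll(u)
  for (iter in 1:50) {
    dv <- .bb_eta_derivs(k, n, Xb_off + drop(Z %*% u), theta)
    grad <- drop(crossprod(Z, dv$d1)) - u * prec
    H <- -crossprod(Z, Z * dv$d2)           # = -t(Z) diag(d2) Z, PSD-ish
    diag(H) <- diag(H) + prec
    step <- tryCatch(solve(H, grad), error = function(e) grad / max(diag(H)))
    lam <- 1
    repeat {
      u_new <- u + lam * step
      new <- pll(u_new)
      if (is.finite(new) && new >= cur - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) { u_new <- u; new <- cur; break }
    }
    done <- new - cur < 1e-10 && max(abs(grad)) < 1e-6
    u <- u_new; cur <- new
    if (done) break
  }
  dv <- .bb_eta_derivs(k, n, Xb_off + drop(Z %*% u), theta)
  H <- -crossprod(Z, Z * dv$d2)
  diag(H) <- diag(H) + prec
  ld <- tryCatch(determinant(H, logarithm = TRUE)$modulus,
                 error = function(e) NA_real_)
  if (!is.finite(ld)) return(list(ll = -Inf, u_hat = u))
  list(ll = cur + q / 2 * log(2 * pi) - 0.5 * as.numeric(ld), u_hat = u)
}

#' Beta-binomial mixed model with Laplace-approximated random intercepts
#'
#' Adds Gaussian random intercepts per grouping factor to the
#' beta-binomial regression of [fit_betabin_regression()]. The random
#' effects are integrated out by a Laplace approximation (mode plus
#' curvature of the penalised log-likelihood, found by damped Newton
#' with analytic derivatives); fixed effects, precision and
#' random-effect standard deviations are then estimated by maximum
#' likelihood with a box-constrained quasi-Newton optimiser. SD
#' estimates may sit at the (numerical) zero boundary; the fit records
#' which components are at the boundary. Nested designs are expressed by
#' passing both the outer factor and the outer:inner interaction.
#'
#' @inheritParams fit_betabin_regression
#' @param groups a list or data frame of grouping factors (each of
#'   length `length(k)`), one random intercept per factor level.
#' @param sd_zero if `TRUE`, all variance components are fixed at zero
#'   and the model degenerates exactly to [fit_betabin_regression()]
#'   (useful for boundary likelihood-ratio tests).
#' @return A `betabin_fit` with additional elements `var_comp` (named
#'   vector of random-intercept SDs), `var_comp_boundary` (logical),
#'   `ranef` (conditional modes).
#' @export
fit_betabin_mixed <- function(k, n, X, groups, offset = NULL,
                              theta_fixed = NULL, sd_zero = FALSE) {
  groups <- as.list(groups)
  if (length(groups) == 0 || sd_zero) {
    fit <- fit_betabin_regression(k, n, X, offset = offset,
                                  theta_fixed = theta_fixed)
    fit$var_comp <- stats::setNames(rep(0, length(groups)), names(groups))
    fit$var_comp_boundary <- rep(TRUE, length(groups))
    fit$ranef <- NULL
    return(fit)
  }
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))[seq_len(ncol(X))]
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  if (is.null(offset)) offset <- rep(0, length(k))
  fac <- lapply(groups, function(g) factor(g))
  Zs <- lapply(fac, function(f) {
    z <- matrix(0, length(f), nlevels(f))
    z[cbind(seq_along(f), as.integer(f))] <- 1
    colnames(z) <- levels(f)
    z
  })
  Z <- do.call(cbind, Zs)
  block <- rep(seq_along(Zs), vapply(Zs, ncol, integer(1)))
  p <- ncol(X)
  nfac <- length(Zs)
  est_theta <- is.null(theta_fixed)
  log_sd_min <- -6           # sd ~ 0.0025: numerical zero boundary

  state <- new.env(parent = emptyenv())
  state$u <- rep(0, ncol(Z))

  negll <- function(par) {
    beta <- par[seq_len(p)]
    theta <- if (est_theta) exp(par[p + 1]) else theta_fixed
    log_sd <- par[(p + as.integer(est_theta) + 1):length(par)]
    sd_u <- exp(log_sd)[block]
    lap <- .laplace_ll(k, n, drop(X %*% beta) + offset, Z, sd_u, theta,
                       u0 = state$u)
    if (!is.finite(lap$ll)) return(1e10)
    state$u <- lap$u_hat
    -lap$ll
  }

  z0 <- stats::qlogis((k + 0.5) / (n + 1)) - offset
  beta0 <- tryCatch(qr.solve(X, z0), error = function(e) rep(0, p))
  start <- c(beta0, if (est_theta) log(10), rep(log(0.5), nfac))
  lower <- c(rep(-Inf, p), if (est_theta) -8, rep(log_sd_min, nfac))
  upper <- c(rep(Inf, p), if (est_theta) 25, rep(4, nfac))

  best <- NULL
  for (attempt in 1:4) {
    st <- if (attempt == 1) start else
      pmin(pmax(start + stats::rnorm(length(start), 0, 0.4), lower), upper)
    state$u <- rep(0, ncol(Z))
    opt <- tryCatch(
      stats::optim(st, negll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(opt) &&
        (is.null(best) || opt$value < best$value - 1e-8)) best <- opt
    if (!is.null(best) && best$convergence == 0) break
  }
  if (is.null(best)) stop("mixed-model optimisation failed to evaluate")

  par <- best$par
  beta <- stats::setNames(par[seq_len(p)], colnames(X))
  theta <- if (est_theta) exp(par[p + 1]) else theta_fixed
  log_sd <- par[(p + as.integer(est_theta) + 1):length(par)]
  sd_hat <- stats::setNames(exp(log_sd), names(groups))

  # observed information for the fixed effects (beta block only), by
  # central finite differences of the profile objective
  hess <- tryCatch(
    stats::optimHess(par, negll), error = function(e) NULL)
  vc <- if (!is.null(hess))
    tryCatch(solve(hess), error = function(e) NULL) else NULL
  se <- rep(NA_real_, p)
  if (!is.null(vc)) {
    dv <- diag(vc)[seq_len(p)]
    dv[!is.finite(dv) | dv <= 0] <- NA_real_
    se <- sqrt(dv)
  }
  names(se) <- colnames(X)
  zstat <- beta / se
  n_par <- p + as.integer(est_theta) + nfac
  ll <- -best$value
  state$u <- rep(0, ncol(Z))
  lap <- .laplace_ll(k, n, drop(X %*% beta) + offset, Z,
                     exp(log_sd)[block], theta)
  structure(list(
    coefficients = beta, se = se, z = zstat,
    p_value = 2 * stats::pnorm(-abs(zstat)),
    theta = theta, theta_estimated = est_theta,
    logLik = ll, AIC = 2 * n_par - 2 * ll,
    n_obs = length(k), n_par = n_par,
    converged = best$convergence == 0,
    vcov = if (is.null(vc)) NULL else vc[seq_len(p), seq_len(p), drop = FALSE],
    var_comp = sd_hat,
    var_comp_boundary = log_sd <= log_sd_min + 1e-6,
    ranef = stats::setNames(lap$u_hat, colnames(Z))),
    class = "betabin_fit")
}

#' Likelihood-ratio test against a chi-square mixture
#'
#' For hypotheses on the boundary of the parameter space (a variance
#' component or overdispersion parameter tested against zero) the
#' likelihood-ratio statistic is not asymptotically chi-square but a
#' mixture of chi-squares of different degrees of freedom (chi-bar
#' square). The p-value is `sum_d w_d P(chisq_d > X2)` with the 0-df
#' component a point mass at zero.
#'
#' @param loglik_full,loglik_reduced maximised log-likelihoods.
#' @param weights named numeric vector of mixture weights; names are the
#'   degrees of freedom (e.g. `c("0" = 0.5, "1" = 0.5)`). Must sum to 1.
#' @param tol tolerance for a slightly negative statistic due to
#'   optimiser noise (clamped to 0); a deficit beyond `tol` is an error.
#' @return An object of class `mixture_lrt` with `statistic`, `weights`,
#'   `p_value`.
#' @examples
#' mixture_lrt_stat(1.51, c("0" = 0.5, "1" = 0.5))$p_value       # ~0.11
#' @export
mixture_lrt <- function(loglik_full, loglik_reduced,
                        weights = c("0" = 0.5, "1" = 0.5), tol = 1e-3) {
  x2 <- 2 * (loglik_full - loglik_reduced)
  if (x2 < -tol)
    stop(sprintf("full model log-likelihood is below reduced by %.4g", -x2 / 2))
  mixture_lrt_stat(max(0, x2), weights)
}

#' @rdname mixture_lrt
#' @param statistic a non-negative likelihood-ratio statistic.
#' @export
mixture_lrt_stat <- function(statistic, weights = c("0" = 0.5, "1" = 0.5)) {
  if (is.null(names(weights))) stop("weights must be named by degrees of freedom")
  dfs <- as.numeric(names(weights))
  if (any(is.na(dfs)) || any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be non-negative, named by df, and sum to 1")
  if (statistic < 0) stop("statistic must be >= 0")
  tail <- vapply(dfs, function(d) {
    if (d == 0) as.numeric(statistic <= 0)
    else stats::pchisq(statistic, df = d, lower.tail = FALSE)
  }, numeric(1))
  structure(list(statistic = statistic, weights = weights,
                 p_value = sum(weights * tail)),
            class = "mixture_lrt")
}

#' @export
print.mixture_lrt <- function(x, ...) {
  cat(sprintf("LRT X2 = %.4g on a chi-square mixture (df %s; weights %s), p = %.4g\n",
              x$statistic, paste(names(x$weights), collapse = ", "),
              paste(format(x$weights), collapse = ", "), x$p_value))
  invisible(x)
}

#' Likelihood-ratio pseudo R-squared
#'
#' `1 - exp(-(2 / n) * (logLik_full - logLik_null))`; with
#' `rescale = TRUE` the value is divided by its attainable maximum
#' `1 - exp((2 / n) * logLik_null)` (Nagelkerke-style cap).
#'
#' @param loglik_full,loglik_null maximised log-likelihoods.
#' @param n_obs number of observations.
#' @param rescale rescale to the attainable maximum?
#' @return Value in `[0, 1)`.
#' @export
pseudo_r2_lr <- function(loglik_full, loglik_null, n_obs, rescale = FALSE) {
  if (n_obs < 1) stop("n_obs must be >= 1")
  r2 <- 1 - exp(-(2 / n_obs) * (loglik_full - loglik_null))
  if (rescale) r2 <- r2 / (1 - exp((2 / n_obs) * loglik_null))
  r2
}

#' Correlation with a t-based two-sided p-value
#'
#' Product-moment correlation between two vectors, with the p-value from
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' `method = "rank"` applies the same product-moment machinery to the
#' ranks of the data (the rank correlation coefficient), which is robust
#' to monotone transformations and to rounding of the raw values.
#'
#' @param x,y numeric vectors, length >= 3, non-constant.
#' @param method `"pearson"` or `"rank"`.
#' @return List with `estimate`, `p_value`, `n`, `method`.
#' @examples
#' pearson_correlation(1:10, (1:10)^2)$estimate
#' @export
pearson_correlation <- function(x, y, method = c("pearson", "rank")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have the same length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  if (method == "rank") { x <- rank(x); y <- rank(y) }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       n = length(x), method = method)
}

#' Summarise a coefficient across simulation runs
#'
#' Mean, standard error of the mean and a one-sample t-test against zero
#' for a vector of per-run slope estimates.
#'
#' @param slopes numeric vector of per-run estimates; `NA`s (failed
#'   fits) are dropped and counted.
#' @return An object of class `run_coefficient_summary` with `mean`,
#'   `sem`, `t`, `df`, `p_value`, `n_runs`, `n_failed`.
#' @examples
#' summarize_across_runs(rnorm(40, mean = 1.3, sd = 3))
#' @export
summarize_across_runs <- function(slopes) {
  n_failed <- sum(is.na(slopes))
  s <- slopes[!is.na(slopes)]
  if (length(s) < 2) stop("need at least two successful runs")
  m <- mean(s)
  sem <- stats::sd(s) / sqrt(length(s))
  t <- if (sem > 0) m / sem else NA_real_
  structure(list(
    mean = m, sem = sem, t = t, df = length(s) - 1,
    p_value = if (is.na(t)) NA_real_ else
      2 * stats::pt(-abs(t), df = length(s) - 1),
    n_runs = length(s), n_failed = n_failed, slopes = s),
    class = "run_coefficient_summary")
}

#' @export
print.run_coefficient_summary <- function(x, ...) {
  cat(sprintf("mean slope %.3f, s.e.m. %.3f, t(%d) = %.2f, p = %.3g (%d runs%s)\n",
              x$mean, x$sem, x$df, x$t, x$p_value, x$n_runs,
              if (x$n_failed > 0) sprintf(", %d failed", x$n_failed) else ""))
  invisible(x)
}
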