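test_that("beta-binomial pmf closed forms and limits hold", {
  # theta = 2 at mu = 0.5 is the uniform beta: each k equally likely
  expect_equal(dbetabinom(0:2, 2, 0.5, 2), rep(1 / 3, 3))
  # binomial limit at huge theta
  expect_equal(dbetabinom(0:10, 10, 0.3, 1e8, log = TRUE),
               dbinom(0:10, 10, 0.3, log = TRUE), tolerance = 1e-4)
  expect_equal(dbetabinom(3, 10, 0.3, Inf), dbinom(3, 10, 0.3))
  # quadrature oracle
  expect_equal(dbetabinom(3, 10, 0.4, 5), oracle_betabinom(3, 10, 0.4, 5),
               tolerance = 1e-8)
  expect_error(dbetabinom(3, 10, 0.4, -1), "theta")
  expect_error(dbetabinom(11, 10, 0.4, 5), "k")
})

test_that("beta-binomial pmf sums to one for randomised parameters", {
  set.seed(3)
  for (rep in 1:25) {
    n <- sample(1:40, 1)
    mu <- runif(1, 0.05, 0.95)
    theta <- exp(runif(1, -1, 4))
    expect_equal(sum(dbetabinom(0:n, n, mu, theta)), 1, tolerance = 1e-10)
  }
})

test_that("intercept-only fit recovers the logit of the mean", {
  k <- rep(10L, 20); n <- rep(20L, 20)
  fit <- fit_betabin_regression(k, n, matrix(1, 20, 1))
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients[1]), 0, tolerance = 1e-4)
})

test_that("binomial-generated data match a logistic-regression oracle", {
  set.seed(21)
  x <- runif(80); n <- rep(30L, 80)
  k <- rbinom(80, n, plogis(-0.5 + 1.5 * x))
  fit <- fit_betabin_regression(k, n, cbind(1, x = x), theta_fixed = Inf)
  glm_fit <- glm(cbind(k, n - k) ~ x, family = binomial)
  expect_equal(unname(fit$coefficients), unname(coef(glm_fit)),
               tolerance = 1e-3)
  expect_equal(fit$logLik, as.numeric(logLik(glm_fit)), tolerance = 1e-6)
  # Wald SEs agree too
  expect_equal(unname(fit$se), unname(summary(glm_fit)$coefficients[, 2]),
               tolerance = 1e-2)
})

test_that("regression recovers known coefficients with nominal CI coverage", {
  set.seed(99)
  n_rep <- 60
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    X <- cbind(1, x = runif(120))
    d <- simulate_betabin_dataset(c(0, 2), 10, X, rep(20L, 120))
    fit <- fit_betabin_regression(d$k, d$n, X)
    ci <- fit$coefficients[2] + c(-1.96, 1.96) * fit$se[2]
    covered[r] <- fit$converged && ci[1] <= 2 && 2 <= ci[2]
  }
  expect_gte(mean(covered), 0.9)
})

test_that("fit against an independent maximum-likelihood oracle", {
  skip_if_not_installed("glmmTMB")
  set.seed(31)
  X <- cbind(1, x = runif(60))
  d <- simulate_betabin_dataset(c(-0.5, 1.5), 4, X, rep(25L, 60))
  fit <- fit_betabin_regression(d$k, d$n, X)
  df <- data.frame(k = d$k, n = d$n, x = X[, 2])
  or <- glmmTMB::glmmTMB(cbind(k, n - k) ~ x,
                         family = glmmTMB::betabinomial, data = df)
  expect_equal(unname(fit$coefficients),
               unname(glmmTMB::fixef(or)$cond), tolerance = 1e-3)
  expect_equal(fit$logLik, as.numeric(logLik(or)), tolerance = 1e-5)
})

test_that("mixed fit with variance forced to zero equals the fixed fit", {
  set.seed(5)
  X <- cbind(1, x = runif(30))
  d <- simulate_betabin_dataset(c(0, 1), 8, X, rep(15L, 30))
  g <- list(pop = rep(letters[1:5], each = 6))
  fixed <- fit_betabin_regression(d$k, d$n, X)
  mixed0 <- fit_betabin_mixed(d$k, d$n, X, g, sd_zero = TRUE)
  expect_equal(mixed0$logLik, fixed$logLik, tolerance = 1e-6)
  expect_equal(mixed0$coefficients, fixed$coefficients, tolerance = 1e-6)
  # free fit at the numerical zero boundary also approaches the fixed fit
  mixed <- fit_betabin_mixed(d$k, d$n, X, g)
  expect_gte(mixed$logLik, fixed$logLik - 1e-4)
})

test_that("Laplace mixed model recovers a population intercept SD", {
  set.seed(77)
  n_rep <- 12
  ok <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    pops <- rep(sprintf("p%02d", 1:30), each = 4)
    X <- cbind(1, x = runif(120))
    d <- simulate_betabin_dataset(c(0, 1), 15, X, rep(20L, 120),
                                  groups = list(pop = pops), sd_groups = 1)
    fit <- fit_betabin_mixed(d$k, d$n, X, list(pop = pops))
    ok[r] <- fit$converged && fit$var_comp[1] > 0.5 && fit$var_comp[1] < 2
  }
  expect_gte(mean(ok), 0.8)
})

test_that("mixed fit agrees with an independent Laplace oracle", {
  skip_if_not_installed("glmmTMB")
  set.seed(13)
  pops <- rep(letters[1:8], each = 8)
  X <- cbind(1, x = runif(64))
  d <- simulate_betabin_dataset(c(0, 1.5), 6, X, rep(20L, 64),
                                groups = list(pop = pops), sd_groups = 0.8)
  fit <- fit_betabin_mixed(d$k, d$n, X, list(pop = pops))
  df <- data.frame(k = d$k, n = d$n, x = X[, 2], pop = pops)
  or <- glmmTMB::glmmTMB(cbind(k, n - k) ~ x + (1 | pop),
                         family = glmmTMB::betabinomial, data = df)
  expect_equal(unname(fit$coefficients),
               unname(glmmTMB::fixef(or)$cond), tolerance = 0.02)
  expect_equal(fit$logLik, as.numeric(logLik(or)), tolerance = 1e-3)
  expect_equal(unname(fit$var_comp[1]),
               attr(glmmTMB::VarCorr(or)$cond$pop, "stddev")[[1]],
               tolerance = 0.05)
})

test_that("Wald z-squared tracks the LRT statistic in large samples", {
  set.seed(55)
  X <- cbind(1, x = runif(400))
  d <- simulate_betabin_dataset(c(0, 0.8), 10, X, rep(25L, 400))
  full <- fit_betabin_regression(d$k, d$n, X)
  null <- fit_betabin_regression(d$k, d$n, X[, 1, drop = FALSE])
  x2 <- 2 * (full$logLik - null$logLik)
  expect_gt(unname(full$z[2])^2 / x2, 0.8)
  expect_lt(unname(full$z[2])^2 / x2, 1.2)
})

test_that("chi-square mixture p-values match published closed forms", {
  # dispersion on the boundary: df {0, 1} half-half
  expect_equal(
    round(mixture_lrt_stat(1.51, c("0" = 0.5, "1" = 0.5))$p_value, 2), 0.11)
  # two variance components: df {0, 1, 2} with weights 1/4, 1/2, 1/4
  expect_equal(
    round(mixture_lrt_stat(0.031,
                           c("0" = 0.25, "1" = 0.5, "2" = 0.25))$p_value, 2),
    0.68)
  # boundary statistic zero gives p = 1
  expect_equal(mixture_lrt_stat(0, c("0" = 0.5, "1" = 0.5))$p_value, 1)
  # wrapper from log-likelihoods, with noise tolerance
  expect_equal(mixture_lrt(-10, -10.755)$statistic, 1.51)
  expect_error(mixture_lrt(-11, -10), "below")
  expect_error(mixture_lrt_stat(1, c(0.5, 0.5)), "named")
})

test_that("likelihood-ratio pseudo R-squared follows its closed form", {
  expect_equal(pseudo_r2_lr(-5, -5, 20), 0)
  n <- 30
  expect_equal(pseudo_r2_lr(-10 + n / 2, -10, n), 1 - exp(-1))
  # toy logistic fit against hand formula
  set.seed(2)
  x <- rnorm(50); y <- rbinom(50, 1, plogis(x))
  f <- glm(y ~ x, family = binomial)
  f0 <- glm(y ~ 1, family = binomial)
  expect_equal(pseudo_r2_lr(logLik(f)[1], logLik(f0)[1], 50),
               1 - exp(-(2 / 50) * (logLik(f)[1] - logLik(f0)[1])),
               tolerance = 1e-10)
  # rescaled version is bounded by 1 and exceeds the raw version
  r <- pseudo_r2_lr(logLik(f)[1], logLik(f0)[1], 50, rescale = TRUE)
  expect_gte(r, pseudo_r2_lr(logLik(f)[1], logLik(f0)[1], 50))
  expect_lt(r, 1)
})

test_that("correlation helper matches cor.test and handles ranks", {
  x <- c(1, 4, 2, 8, 5, 7); y <- c(2, 3, 1, 9, 4, 8)
  pc <- pearson_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(pc$estimate, unname(ct$estimate))
  expect_equal(pc$p_value, ct$p.value)
  expect_equal(pearson_correlation(x, 2 * x + 1)$estimate, 1)
  rk <- pearson_correlation(x, y, method = "rank")
  expect_equal(rk$estimate, cor(x, y, method = "spearman"))
  expect_error(pearson_correlation(x, rep(1, 6)), "variance")
})

test_that("across-run summaries reproduce the t construction", {
  set.seed(8)
  s <- rnorm(40, 1.31, 3)
  su <- summarize_across_runs(s)
  expect_equal(su$mean, mean(s))
  expect_equal(su$sem, sd(s) / sqrt(40))
  expect_equal(su$t, su$mean / su$sem)
  tt <- t.test(s)
  expect_equal(su$p_value, tt$p.value)
  expect_equal(su$df, 39)
  # symmetric slopes give t = 0
  expect_equal(summarize_across_runs(c(-2, -1, 1, 2))$t, 0)
  # published summary scale: mean 1.31 with s.e.m. 0.47 has t ~ 2.80
  expect_equal(1.31 / 0.47, 2.80, tolerance = 0.01)
})
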