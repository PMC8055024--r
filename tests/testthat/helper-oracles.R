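# Independent brute-force oracles, deliberately written with different
# algorithms from the package implementations.

# ADI by explicit double loop over partners
oracle_adi <- function(counts) {
  n <- nrow(counts)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fr <- c()
    for (j in seq_len(n)) {
      if (j == i) next
      tot <- counts[i, j] + counts[j, i]
      if (tot > 0) fr <- c(fr, counts[i, j] / tot)
    }
    if (length(fr) > 0) out[i] <- sum(fr) / length(fr)
  }
  out
}

# FDI by explicit pair comparison on ADI values (ties share ranks)
oracle_fdi <- function(adi, sexes, tie_weight = 0, digits = 9) {
  a <- round(adi, digits)
  fa <- a[sexes == "female" & !is.na(a)]
  ma <- a[sexes == "male" & !is.na(a)]
  if (length(fa) == 0 || length(ma) == 0) return(NA_real_)
  per <- sapply(fa, function(x)
    (sum(ma < x) + tie_weight * sum(ma == x)) / length(ma))
  mean(per)
}

oracle_unknown <- function(counts) {
  n <- nrow(counts)
  silent <- 0; dyads <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dyads <- dyads + 1
    if (counts[i, j] + counts[j, i] == 0) silent <- silent + 1
  }
  silent / dyads
}

# beta-binomial pmf by numerical integration of the binomial over a
# beta mixing density
oracle_betabinom <- function(k, n, mu, theta) {
  stats::integrate(function(p)
    stats::dbinom(k, n, p) * stats::dbeta(p, mu * theta, (1 - mu) * theta),
    0, 1, rel.tol = 1e-12)$value
}

random_interaction_matrix <- function(n, max_count = 2) {
  sex <- sample(c("male", "female"), n, replace = TRUE)
  # ensure both sexes present for FDI checks
  sex[1] <- "male"; if (n > 1) sex[2] <- "female"
  ids <- paste0(ifelse(sex == "male", "m", "f"), seq_len(n))
  counts <- matrix(sample(0:max_count, n * n, replace = TRUE), n, n)
  diag(counts) <- 0L
  interaction_matrix(counts, ids = ids, sexes = sex)
}

fast_params <- function(...) {
  sim_params(n_periods = 60, burn_in_periods = 20, ...)
}
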