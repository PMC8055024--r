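#' Parameters of the latent-strength interaction generator
#'
#' Test-harness model for dyadic agonistic data: each individual gets a
#' latent strength on the logit scale drawn from a sex-specific normal
#' distribution, each dyad fights a Poisson number of times, and each
#' fight is won by `i` with probability
#' `plogis(steepness * (s_i - s_j))`. The default male/female mean gap
#' (0.7 on the logit scale, about a 2:1 odds advantage) loosely mirrors
#' the 2:1 male/female initial-dominance ratio used by the simulator; it
#' is a statistical stand-in for unavailable raw field matrices, not a
#' biological claim.
#'
#' @param mean_female,mean_male latent means (logit-strength scale).
#' @param sd_female,sd_male latent SDs, >= 0.
#' @param rate expected fights per dyad, >= 0.
#' @param steepness logistic slope on the latent difference.
#' @return An object of class `latent_model_params`.
#' @export
latent_model_params <- function(mean_female = 0, mean_male = 0.7,
                                sd_female = 1, sd_male = 1,
                                rate = 2, steepness = 1) {
  if (rate < 0) stop("rate must be >= 0")
  if (sd_female < 0 || sd_male < 0) stop("SDs must be >= 0")
  structure(list(mean_female = mean_female, mean_male = mean_male,
                 sd_female = sd_female, sd_male = sd_male,
                 rate = rate, steepness = steepness),
            class = "latent_model_params")
}

#' Generate a synthetic winner-loser interaction matrix
#'
#' Draws latent strengths, Poisson dyadic fight counts and
#' logistic-probability outcomes under [latent_model_params()].
#'
#' @param comp a [group_composition()].
#' @param params a [latent_model_params()].
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return A list with the [interaction_matrix()] (`matrix`) and the
#'   latent `strengths` (named, for recovery checks).
#' @examples
#' g <- generate_interaction_matrix(group_composition(3, 3),
#'                                  latent_model_params(rate = 5), seed = 1)
#' sum(g$matrix$counts)
#' @export
generate_interaction_matrix <- function(comp, params = latent_model_params(),
                                        seed = NULL) {
  if (!inherits(comp, "group_composition")) stop("comp must be a group_composition")
  if (!inherits(params, "latent_model_params"))
    stop("params must be latent_model_params")
  if (!is.null(seed)) set.seed(seed)
  n <- comp$n_males + comp$n_females
  sex <- rep(c("male", "female"), c(comp$n_males, comp$n_females))
  id <- c(sprintf("m%d", seq_len(comp$n_males)),
          sprintf("f%d", seq_len(comp$n_females)))
  s <- ifelse(sex == "male",
              stats::rnorm(n, params$mean_male, params$sd_male),
              stats::rnorm(n, params$mean_female, params$sd_female))
  counts <- matrix(0L, n, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      fights <- stats::rpois(1, params$rate)
      if (fights > 0) {
        wi <- stats::rbinom(1, fights,
                            stats::plogis(params$steepness * (s[i] - s[j])))
        counts[i, j] <- wi
        counts[j, i] <- fights - wi
      }
    }
  }
  list(matrix = interaction_matrix(counts, ids = id, sexes = sex),
       strengths = stats::setNames(s, id))
}

#' Simulate a grouped beta-binomial dataset with known parameters
#'
#' Validation harness for the regression machinery: draws optional
#' Gaussian random intercepts per grouping factor, sets
#' `mu = plogis(X beta + intercepts)` and draws
#' `k ~ BetaBinomial(n, mu, theta)` (via a beta draw per observation,
#' then a binomial; `theta = Inf` gives exact binomial data).
#'
#' @param beta coefficient vector matching the columns of `X`.
#' @param theta beta-binomial precision, > 0 or `Inf`.
#' @param X design matrix.
#' @param n integer vector of trials per row.
#' @param groups optional named list of grouping factors.
#' @param sd_groups numeric vector of random-intercept SDs, one per
#'   grouping factor.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return List with `k`, `n`, `X`, `groups`, and the drawn random
#'   effects `ranef`.
#' @examples
#' d <- simulate_betabin_dataset(c(0, 2), 10, cbind(1, runif(50)),
#'                               rep(20, 50), seed = 1)
#' head(d$k)
#' @export
simulate_betabin_dataset <- function(beta, theta, X, n,
                                     groups = NULL, sd_groups = NULL,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(theta <= 0)) stop("theta must be > 0")
  X <- as.matrix(X)
  if (length(beta) != ncol(X)) stop("length(beta) must equal ncol(X)")
  if (length(n) != nrow(X)) stop("length(n) must equal nrow(X)")
  eta <- drop(X %*% beta)
  ranef <- NULL
  if (!is.null(groups)) {
    groups <- as.list(groups)
    if (length(sd_groups) != length(groups))
      stop("sd_groups must match groups")
    ranef <- vector("list", length(groups))
    names(ranef) <- names(groups)
    for (gi in seq_along(groups)) {
      f <- factor(groups[[gi]])
      u <- stats::rnorm(nlevels(f), 0, sd_groups[gi])
      names(u) <- levels(f)
      ranef[[gi]] <- u
      eta <- eta + u[as.integer(f)]
    }
  }
  mu <- stats::plogis(eta)
  k <- if (is.infinite(theta)) {
    stats::rbinom(length(n), n, mu)
  } else {
    pr <- stats::rbeta(length(n), mu * theta, (1 - mu) * theta)
    stats::rbinom(length(n), n, pr)
  }
  list(k = k, n = n, X = X, groups = groups, ranef = ranef)
}
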