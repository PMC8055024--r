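#' Average dominance index (ADI)
#'
#' Per individual, the mean over its interaction partners of the
#' fraction of fights it won from that partner. Partners with whom an
#' individual never interacted are excluded from its average;
#' individuals with no interactions at all get `NA` (their dominance
#' position is unknown and they are dropped from rank-based statistics).
#'
#' @param m an [interaction_matrix()].
#' @return Named numeric vector of ADI values in `[0, 1]`, `NA` where
#'   undefined.
#' @examples
#' cnt <- matrix(0, 3, 3, dimnames = rep(list(c("m1", "f1", "f2")), 2))
#' cnt["m1", "f1"] <- 3; cnt["f1", "m1"] <- 1; cnt["f1", "f2"] <- 1
#' average_dominance_index(interaction_matrix(cnt))
#' @export
average_dominance_index <- function(m) {
  if (!inherits(m, "interaction_matrix")) stop("m must be an interaction_matrix")
  n <- length(m$ids)
  if (n < 2) stop("need at least two individuals")
  w <- m$counts
  tot <- w + t(w)                       # fights per dyad
  frac <- ifelse(tot > 0, w / tot, NA_real_)
  adi <- rowMeans(frac, na.rm = TRUE)
  adi[rowSums(tot) == 0] <- NA_real_    # never interacted at all
  names(adi) <- m$ids
  adi
}

#' Tie-aware ranking from dominance indices
#'
#' Orders individuals by descending ADI; individuals whose ADI values
#' coincide (after rounding to `digits` decimals, since ADIs are
#' rationals that may differ only by floating-point noise) share a rank
#' (competition ranking: 1, 2, 2, 4). Individuals with undefined ADI are
#' unranked (`NA`).
#'
#' @param adi named numeric vector as returned by
#'   [average_dominance_index()].
#' @param digits decimals used when comparing ADI values for ties.
#' @return Integer vector of ranks (1 = most dominant), `NA` where
#'   unranked.
#' @export
rank_individuals <- function(adi, digits = 9) {
  if (all(is.na(adi))) stop("all dominance indices are undefined")
  r <- round(adi, digits)
  ranks <- rep(NA_integer_, length(adi))
  ok <- !is.na(r)
  ranks[ok] <- as.integer(rank(-r[ok], ties.method = "min"))
  names(ranks) <- names(adi)
  ranks
}

#' Female dominance index (FDI)
#'
#' The average, over ranked females, of the proportion of ranked males
#' each female outranks: 0 when no female is dominant over any male, 1
#' when all females are dominant over all males. A male tied with a
#' female counts as `tie_weight` of a dominated male (default 0: a tie
#' is not dominance).
#'
#' @param ranks integer ranks as returned by [rank_individuals()].
#' @param sexes character vector parallel to `ranks`.
#' @param tie_weight weight in `[0, 1]` given to a male sharing a
#'   female's rank.
#' @return FDI in `[0, 1]`.
#' @export
female_dominance_index <- function(ranks, sexes, tie_weight = 0) {
  if (tie_weight < 0 || tie_weight > 1) stop("tie_weight must be in [0, 1]")
  ok <- !is.na(ranks)
  mr <- ranks[ok & sexes == "male"]
  fr <- ranks[ok & sexes == "female"]
  if (length(mr) == 0 || length(fr) == 0)
    stop("FDI needs at least one ranked male and one ranked female")
  per_female <- vapply(fr, function(r)
    (sum(mr > r) + tie_weight * sum(mr == r)) / length(mr), numeric(1))
  mean(per_female)
}

#' Success counts underlying the female dominance index
#'
#' For grouped-binomial modelling of female dominance: `total` is the
#' product of the numbers of ranked males and females, and `successes`
#' is the summed number of males ranked strictly below each female.
#' `successes / total` equals [female_dominance_index()] at
#' `tie_weight = 0`.
#'
#' @inheritParams female_dominance_index
#' @return List with integer `successes` and `total`.
#' @export
fdi_success_counts <- function(ranks, sexes) {
  ok <- !is.na(ranks)
  mr <- ranks[ok & sexes == "male"]
  fr <- ranks[ok & sexes == "female"]
  if (length(mr) == 0 || length(fr) == 0)
    stop("success counts need at least one ranked male and one ranked female")
  succ <- sum(vapply(fr, function(r) sum(mr > r), numeric(1)))
  list(successes = as.integer(succ),
       total = as.integer(length(mr) * length(fr)))
}

#' Proportion of dyads with unknown dominance relation
#'
#' The fraction of unordered pairs of individuals with zero recorded
#' agonistic interactions, over all possible pairs in the group.
#'
#' @param m an [interaction_matrix()].
#' @return Fraction in `[0, 1]`.
#' @export
unknown_relation_proportion <- function(m) {
  if (!inherits(m, "interaction_matrix")) stop("m must be an interaction_matrix")
  n <- length(m$ids)
  if (n < 2) stop("need at least two individuals")
  tot <- m$counts + t(m$counts)
  silent <- sum(tot[upper.tri(tot)] == 0)
  silent / (n * (n - 1) / 2)
}

#' Sex-classed aggression fractions
#'
#' Computes `mm_fraction` (male-to-male acts over all male-initiated
#' acts) and `fm_fraction` (female-to-male acts over all
#' female-initiated acts). For simulated data pass the
#' initiator-attributed `acts` matrix of a [run_simulation()] result;
#' for a bare winner-loser matrix each won fight is attributed to the
#' winner as the aggressor (`attribution = "winner"`).
#'
#' A fraction is `NA` when its denominator is zero. For a single-male
#' group `mm_fraction` is `NA` and flagged excluded: with no other male
#' present the male-male fraction is structurally zero and carries no
#' information about aggression patterning.
#'
#' @param m an [interaction_matrix()] (used for ids/sexes, and for
#'   counts under winner attribution).
#' @param acts optional directed acts matrix (initiator attribution).
#' @param attribution `"initiator"` (requires `acts`) or `"winner"`.
#' @return List with `mm_fraction`, `fm_fraction`, and logical
#'   `mm_excluded`.
#' @export
aggression_fractions <- function(m, acts = NULL,
                                 attribution = c("initiator", "winner")) {
  if (!inherits(m, "interaction_matrix")) stop("m must be an interaction_matrix")
  attribution <- match.arg(attribution)
  a <- if (attribution == "initiator") {
    if (is.null(acts)) stop("initiator attribution requires an acts matrix")
    acts
  } else m$counts
  male <- m$sexes == "male"
  female <- m$sexes == "female"
  mm_excluded <- sum(male) < 2
  male_tot <- sum(a[male, , drop = FALSE])
  fem_tot <- sum(a[female, , drop = FALSE])
  mm <- if (mm_excluded || male_tot == 0) NA_real_ else
    sum(a[male, male, drop = FALSE]) / male_tot
  fm <- if (fem_tot == 0) NA_real_ else
    sum(a[female, male, drop = FALSE]) / fem_tot
  list(mm_fraction = mm, fm_fraction = fm, mm_excluded = mm_excluded)
}

#' Hierarchy summary for one group(-period)
#'
#' Bundles all dominance statistics computed from one interaction
#' matrix: ADI per individual, tie-aware ranks, FDI with its
#' success/total counts, the unknown-relation proportion, and the
#' sex-classed aggression fractions.
#'
#' @param m an [interaction_matrix()].
#' @param acts optional initiator-attributed acts matrix (from
#'   [run_simulation()]); if absent, aggression is winner-attributed.
#' @param tie_weight tie weight passed to [female_dominance_index()].
#' @return An object of class `hierarchy_summary`.
#' @examples
#' p <- sim_params(n_periods = 60, burn_in_periods = 20)
#' r <- run_simulation(p, group_composition(2, 4), seed = 7)
#' hierarchy_summary(r$matrix, acts = r$acts)
#' @export
hierarchy_summary <- function(m, acts = NULL, tie_weight = 0) {
  adi <- average_dominance_index(m)
  ranks <- rank_individuals(adi)
  fdi <- female_dominance_index(ranks, m$sexes, tie_weight = tie_weight)
  sc <- fdi_success_counts(ranks, m$sexes)
  ag <- aggression_fractions(
    m, acts = acts,
    attribution = if (is.null(acts)) "winner" else "initiator")
  structure(list(
    adi = adi, ranks = ranks, fdi = fdi,
    fdi_successes = sc$successes, fdi_total = sc$total,
    unknown_proportion = unknown_relation_proportion(m),
    mm_fraction = ag$mm_fraction, fm_fraction = ag$fm_fraction,
    mm_excluded = ag$mm_excluded,
    n_males = sum(m$sexes == "male"),
    n_females = sum(m$sexes == "female"),
    tie_weight = tie_weight),
    class = "hierarchy_summary")
}

#' @export
print.hierarchy_summary <- function(x, ...) {
  cat(sprintf("Hierarchy summary: %d males, %d females\n",
              x$n_males, x$n_females))
  cat(sprintf("  FDI %.3f (%d / %d successes, tie weight %g)\n",
              x$fdi, x$fdi_successes, x$fdi_total, x$tie_weight))
  cat(sprintf("  unknown relations %.3f; MM fraction %s; FM fraction %s\n",
              x$unknown_proportion,
              if (is.na(x$mm_fraction)) "NA" else sprintf("%.3f", x$mm_fraction),
              if (is.na(x$fm_fraction)) "NA" else sprintf("%.3f", x$fm_fraction)))
  invisible(x)
}

#' @rdname hierarchy_summary
#' @param x a `hierarchy_summary`.
#' @param ... unused.
#' @export
as.data.frame.hierarchy_summary <- function(x, ...) {
  data.frame(n_males = x$n_males, n_females = x$n_females,
             prop_males = x$n_males / (x$n_males + x$n_females),
             fdi = x$fdi, fdi_successes = x$fdi_successes,
             fdi_total = x$fdi_total,
             unknown_proportion = x$unknown_proportion,
             mm_fraction = x$mm_fraction, fm_fraction = x$fm_fraction)
}
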