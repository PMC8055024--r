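---
title: "Winner-loser dynamics, female dominance and adult sex ratio: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Winner-loser dynamics, female dominance and adult sex ratio: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domhier)
```

## The scientific question

In sexually dimorphic group-living animals, males are usually assumed to
dominate females because they are larger. The winner-loser effect offers a
competing proximate account: winning a fight raises the probability of winning
the next one, losing lowers it, so dominance relations partly emerge from the
history of fights rather than from prior attributes alone. A long-standing
prediction of this account is demographic: in groups with a higher proportion
of males, males fight each other relatively more often, losers among them sink
in rank below females, and the degree of *female dominance over males* rises
with the adult sex ratio.

`domhier` implements the full computational chain needed to study this
prediction: (i) a spatially explicit agent-based simulation of grouping and
agonistic interactions with self-reinforcing dominance updating; (ii) the
matrix statistics that summarise a dominance hierarchy from winner-loser
counts; (iii) beta-binomial (mixed) regression machinery for grouped
proportions; and (iv) pipelines that run the simulation experiment across
realistic group compositions and analyse the packaged field summaries from
six wild groups of robust capuchin monkeys (*Sapajus* spp., three Brazilian
populations, 14 group-periods).

## The agent-based model

Agents live on a continuous `worldSize x worldSize` toroidal plane (default
200 x 200 world units). Each agent carries a dominance value `D > 0` and an
intensity of aggression `step_dom`. Defaults encode a dimorphic species:
males start at `D = 32`, females at `D = 16`; male fights shift dominance
values ten times more than female fights (`step_dom` 1 vs 0.1).

In every period each agent is activated once, in uniformly random order. An
activated agent reacts to the nearest other agent visible within its
`field_of_view` (120 degrees) and within `max_view` (48 units):

* **within `pers_space` (4 units)** it considers attacking. A *mental battle*
  first estimates the outcome: the agent attacks only if it wins
  `n_mental_battles` internal draws, each with probability
  `D_i / (D_i + D_j)`; this makes attack decisions risk-sensitive. A real
  fight is then won by the initiator with that same probability. After a
  fight both dominance values shift by the same damped amount
  `delta = (w - D_i / (D_i + D_j)) * S`: an expected win changes little, an
  upset changes much. The winner turns towards the loser and chases
  (`chase_dist` 1), the loser turns away and flees (`flee_dist` 2). If the
  mental battle is lost, the agent turns around (180 +/- 10 degrees) and
  withdraws `withdraw_dist` (0 by default, so it stays put);
* **within `near_view` (24 units)** it simply proceeds `move_dist` with a
  small heading wiggle (+/- 10 degrees);
* **within `max_view`** (beyond `near_view`) it turns towards the other and
  approaches - this is what keeps the group together;
* **nobody visible**: it turns `search_turn` (90 degrees) to a random side
  with +/- 10 degrees error and moves on.

Fights after a burn-in are tallied in two matrices: winner-loser counts
(entry `[i, j]` = fights `i` won over `j`) and initiator-attributed "acts"
(entry `[i, j]` = attacks by `i` on `j`), the latter used for the sex-classed
aggression fractions.

### Choices the behavioural rules leave open

Several ingredients are not fixed by the verbal description of this model
family; the package makes them explicit, configurable parameters and the
defaults are recorded in every result object:

* **World geometry.** A torus avoids edge artefacts; 200 units keeps the
  group (up to 16 agents here) dense enough to interact after clustering.
* **Initial placement.** Uniform in a 20-unit-radius disc, so everyone starts
  within `max_view` of the group; uniform placement over the whole torus
  would let singletons drift forever.
* **Activation scheme.** A fresh uniformly random permutation per period.
* **Whose intensity scales a mixed-sex fight.** The update `delta` needs one
  scale `S` per fight ("by the same amount"), but two agents with different
  `step_dom` meet. `step_dom_convention` selects `initiator`, `winner`,
  `opponent` or `mean`. The packaged default is `mean` (the fight is a joint
  event, so the symmetric choice uses the average intensity of the two
  parties). The `winner` convention practically abolishes female dominance -
  female wins then move values by only 0.1 - and is kept only for
  sensitivity analyses.
* **Dominance floor.** `D` is floored at 0.01; otherwise a long losing
  streak could push `D` to zero or below and break the win-probability ratio.
* **Run length and recording window.** These are genuine free parameters of
  the study design, and the hierarchy statistics depend on them: rank
  differentiation between the sexes accumulates slowly, and the average
  dominance index (below) is computed from fights pooled over the recording
  window, so a window that starts too early mixes epochs before and after
  rank reversals and washes female dominance out. The packaged configuration
  is `n_periods = 2000` with `burn_in_periods = 1400`: dominance values are
  quasi-stationary well before period 1400, and the 600-period recording
  window gives every dyad ample decided fights while still reflecting the
  settled hierarchy. Shorter runs (a few hundred periods) leave the female
  dominance index near zero under the default dimorphic parameters.

## Hierarchy statistics

From a winner-loser matrix the package computes:

* **Average dominance index (ADI)**: per individual, the mean over its
  interaction partners of the fraction of fights won against that partner;
  partners never met are excluded, individuals that never fought anyone get
  an undefined ADI and are unranked. ADI values are rationals; ties are
  declared after rounding to 9 decimals so that floating-point noise cannot
  split a genuine tie.
* **Ranks**: descending ADI with competition ranking (tied individuals share
  a rank).
* **Female dominance index (FDI)**: the average over ranked females of the
  proportion of ranked males below her; 0 means no female outranks any male,
  1 means all females outrank all males. A male tied with a female counts as
  `tie_weight` of a dominated male; the default `tie_weight = 0` treats a
  tie as "not dominant over" (consistent with groups that show co-dominant
  alpha pairs yet FDI < 1), and 0.5 is available. For grouped-binomial
  modelling the FDI is carried as counts: `successes` (male-female ordered
  pairs where the female ranks strictly higher) out of
  `n_males * n_females`.
* **Unknown-relation proportion**: the fraction of dyads with zero recorded
  interactions over all dyads - a data-sufficiency diagnostic.
* **Aggression fractions**: male-male acts out of all male-initiated acts
  (`mm_fraction`) and female-to-male acts out of all female-initiated acts
  (`fm_fraction`). Simulated data carry the true initiator; for a bare
  winner-loser matrix each won fight is attributed to the winner as
  aggressor, and the choice is explicit in the API. Single-male groups have
  a structurally empty male-male fraction and are flagged excluded.

## Beta-binomial regression machinery

Group-level dominance outcomes are proportions with denominators of a few
dozen at most and visible overdispersion, so the package models
`k ~ BetaBinomial(n, mu, theta)` with `logit(mu) = X beta + offset`, where
`theta` is the precision (beta shape sum; small `theta` = strong
overdispersion, `theta = Inf` recovers the binomial exactly).

* `fit_betabin_regression()` maximises the joint likelihood in
  `(beta, log theta)` by BFGS with an empirical-logit start, up to three
  jittered restarts on flagged non-convergence, standard errors from the
  inverse observed information.
* `fit_betabin_mixed()` adds Gaussian random intercepts per grouping factor,
  integrated by a Laplace approximation. The penalised-likelihood mode is
  found by damped Newton with analytic gradient and Hessian (digamma /
  trigamma terms), warm-started between outer iterations; the outer
  optimiser is box-constrained quasi-Newton with `log sd` bounded below at
  -6, i.e. a numerical zero boundary, and boundary estimates are reported as
  such. Estimation is plain maximum likelihood (no REML-style adjustment) so
  that likelihood-ratio tests and AIC comparisons are coherent. Nested
  designs are passed as outer factor plus outer:inner interaction. With all
  variance components at zero the marginal likelihood equals the
  fixed-effects likelihood (this degenerate equivalence is tested to 1e-6).
* `mixture_lrt()` implements boundary likelihood-ratio tests against
  chi-bar-square mixtures: weights `{0: 1/2, 1: 1/2}` for one boundary
  parameter (e.g. the overdispersion test) and `{0: 1/4, 1: 1/2, 2: 1/4}`
  for two nested variance components.
* `pseudo_r2_lr()` gives the likelihood-ratio pseudo R-squared
  `1 - exp(-(2/n) (logLik_full - logLik_null))`, with an optional
  Nagelkerke-style rescaling; both variants are reported because the choice
  is a convention, not a substantive claim.

Convergence criteria: relative objective change below 1e-12 inside BFGS,
maximum 500 iterations, non-convergence always flagged on the fit object and
never silently ignored; downstream pipelines drop failed per-run fits and
count them.

## The simulation experiment

`run_domworld_experiment()` simulates `n_runs` (default 40) independent
replicates of the 14 packaged group compositions (1-6 males, 3-10 females),
computes each group's hierarchy summary, and fits per run five beta-binomial
regressions: FDI counts on proportion of males; male-male aggression counts
(out of male acts) on proportion of males (single-male groups excluded);
female-to-male counts (out of female acts) on proportion of males; and FDI
counts on each aggression fraction. A sixth, the *docile-male check*,
regresses male-to-female acts (out of male acts) on proportion of males with
offset `logit(fraction of females among potential opponents)`; under purely
random target choice the offset is exact and the slope is zero, so a
negative slope would indicate males increasingly sparing females as male
numbers grow. Per-run slopes are averaged with one-sample t statistics
across runs - the per-run fits are fixed-effects regressions, because within
one run the 14 groups are independent simulations, not repeated measures.

Every experiment stores its full configuration and the per-run, per-group
seeds drawn from the master seed, so any single simulated group can be
regenerated in isolation and the whole experiment is byte-reproducible.

## The empirical arm and its reconstruction

The packaged tables carry, for 14 group-periods of wild capuchins, the adult
composition, observation hours, the FDI, the two aggression fractions, the
number of decided dyadic agonistic interactions and the percentage of dyads
with unknown relations. The raw interaction matrices behind those summaries
are not distributed, which forces two documented approximations:

* **Success counts are reconstructed** as
  `round(FDI * n_males * n_females)` (nearest integer, half away from zero)
  out of `n_males * n_females`. The printed FDI values are rounded to two
  decimals, so reconstructed counts can be off by one unit in either
  direction. All mixed-model results on these counts (sex-ratio slope,
  AIC comparison of proportion-of-males vs absolute-number-of-males,
  boundary tests of dispersion and variance components, pseudo R-squared)
  are therefore qualitative: sign, significance and ordering are
  meaningful, exact digits are not, and the report object carries a
  `reconstructed = TRUE` flag.
* **The unknown-relations association is rank-based.** On the printed table
  the product-moment correlation between the percentage of unknown relations
  and the number of adults is 0.68, while the correlation computed on ranks
  is 0.59 with a t-based p of 0.027. The published association is recovered
  by the rank-based statistic, so the report exposes that as the headline
  value (ranks are also the natural choice given that one variable is a
  rounded percentage with ties) and reports the product-moment value
  alongside.

The mixed model uses random intercepts for population and
group-within-population (3 populations, 6 groups, 14 rows). At this size the
variance components sit at the zero boundary; that is the expected outcome,
mirrored by the boundary LRT.

## The synthetic-data generator

Two generators make every stage testable without any external data:

* `generate_interaction_matrix()` draws latent strengths per individual on a
  logit scale (sex-specific means; the default male-female gap of 0.7
  loosely mirrors the 2:1 initial-dominance ratio of the simulator), fight
  counts per dyad as Poisson(`rate`), and fight outcomes by a logistic curve
  on latent-strength differences. It emulates the statistical skeleton of
  dyadic agonistic data - a latent hierarchy observed through binomial
  sampling - but none of the field realities (observation effort, scan
  sampling, coalitions, demography change within periods). Passing
  recovery tests on these matrices shows the metrics are correct, not that
  field data are this clean.
* `simulate_betabin_dataset()` draws grouped beta-binomial data with known
  coefficients, precision and random-intercept SDs, used for parameter
  recovery, CI coverage and power checks of the regression machinery.

## Problem sizes used in the test suite

The test suite runs everything at sizes chosen to exercise the full code
path while keeping a laptop run comfortable: Monte-Carlo probability checks
at 2 x 10^4 draws, metric-oracle sweeps over 300 random small matrices,
CI-coverage at 60 replicates of 120 groups, mixed-model recovery at 12
replicates of 30 populations, and simulation property checks at 60-200
periods. The acceptance-level experiment runs the full 40 x 14 design at
the packaged 2000-period configuration.

## Known limitations

* The simulation's absolute dominance scale and time unit are arbitrary;
  only rank-order statistics and cross-composition contrasts are
  interpretable. Slope magnitudes from the simulated arm depend on the run
  length and recording window (documented above) and on the `step_dom`
  convention; sign and significance are robust across all conventions
  except `winner`.
* Two of the simulated-arm slopes are sensitive to unreported details of
  this model family (activation timing, strength of spatial cohesion and
  centre-periphery sorting): the response of female-to-male aggression to
  sex ratio stays close to what random opponent availability predicts
  (slope ~4.3-4.6 on the logit scale), while the coupling of female
  dominance to female-to-male aggression is comparatively tight
  (~4.3-5.0). Reference values for this model family place the former
  slightly higher and the latter slightly lower; sign and significance
  are robust.
* The per-run slope distribution of the FDI-response models is heavy-tailed
  at these group sizes (FDI success counts are small and occasionally
  separate), so cross-run means at 40 runs retain visible Monte-Carlo
  spread; the experiment object keeps all per-run slopes so users can
  inspect or robustify the summary.
* The empirical reconstruction cannot recover per-individual hierarchies or
  the raw aggression counts; analyses needing those (e.g. refitting the
  aggression-fraction models on empirical counts) are out of scope.
* The Laplace approximation uses a single quadrature point; at the packaged
  data sizes it matches an independent implementation to ~1e-3 in
  log-likelihood, but very small clusters with large variance components
  would warrant adaptive quadrature, which is not provided.
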