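#' Simulation parameters for the winner-loser dominance model
#'
#' Constructs the parameter set controlling the spatially explicit
#' agent-based simulation. Agents move on a continuous toroidal plane,
#' group with others they see at medium (`near_view`) and long
#' (`max_view`) range, and compete when another agent enters their
#' personal space (`pers_space`). A potential fight starts with one or
#' more "mental battles" (risk-sensitive internal win estimates); a real
#' fight is won with probability proportional to relative dominance, and
#' the dominance values of winner and loser are then shifted by the same
#' damped amount scaled by `step_dom` (the intensity of aggression).
#'
#' Defaults reflect a sexually dimorphic species: males start with twice
#' the female dominance value (32 vs 16) and fight at ten times the
#' female intensity (`step_dom` 1 vs 0.1). All angles are degrees; all
#' distances are in world units. The default schedule (2000 periods with
#' a 1400-period burn-in) lets the hierarchy reach quasi-stationary
#' differentiation before fights are tallied, and the default `"mean"`
#' step-dom convention scales each fight by the average intensity of the
#' two parties; see the package vignette for the calibration rationale
#' and sensitivity of results to these choices.
#'
#' @param initial_dominance named numeric, initial dominance value per
#'   sex (`female`, `male`).
#' @param step_dom named numeric, per-sex intensity of aggression: the
#'   scale of the dominance update after a fight.
#' @param n_mental_battles integer >= 1, number of independent internal
#'   win estimates an agent must win before it attacks.
#' @param field_of_view total view angle in degrees (0, 360].
#' @param pers_space,near_view,max_view interaction radii, with
#'   `pers_space <= near_view <= max_view`.
#' @param flee_dist,withdraw_dist,chase_dist,move_dist displacement
#'   distances for fleeing after a lost fight, withdrawing after a lost
#'   mental battle, chasing after a won fight, and ordinary movement.
#' @param wiggle_turn,wiggle_turn_error,search_turn,search_turn_error,won_turn,won_turn_error,flee_turn,flee_turn_error
#'   turn angles and their uniform error half-widths (degrees) for
#'   forward motion, searching when no other is visible, winning, and
#'   fleeing.
#' @param world_size side length of the square toroidal world.
#' @param n_periods number of activation periods per run; in one period
#'   every agent is activated once, in random order.
#' @param burn_in_periods periods discarded before fights are tallied.
#' @param step_dom_convention whose `step_dom` scales a mixed-sex fight:
#'   `"initiator"` (default), `"winner"`, `"opponent"` or `"mean"`.
#' @param dominance_floor strictly positive lower bound kept on all
#'   dominance values so win probabilities stay defined.
#' @param compete_unseen if `TRUE`, an agent inside the personal space
#'   triggers competition even when outside the focal's field of view
#'   (proximity-triggered competition); vision still governs grouping.
#'
#' @return An object of class `sim_params` (a validated list).
#' @examples
#' p <- sim_params()
#' p$initial_dominance
#' @export
sim_params <- function(initial_dominance = c(female = 16, male = 32),
                       step_dom = c(female = 0.1, male = 1),
                       n_mental_battles = 1,
                       field_of_view = 120,
                       pers_space = 4, near_view = 24, max_view = 48,
                       flee_dist = 2, withdraw_dist = 0,
                       chase_dist = 1, move_dist = 1,
                       wiggle_turn = 0, wiggle_turn_error = 10,
                       search_turn = 90, search_turn_error = 10,
                       won_turn = 0, won_turn_error = 0,
                       flee_turn = 180, flee_turn_error = 10,
                       world_size = 200,
                       n_periods = 2000, burn_in_periods = 1400,
                       step_dom_convention = c("mean", "initiator",
                                               "winner", "opponent"),
                       dominance_floor = 0.01,
                       compete_unseen = FALSE) {
  step_dom_convention <- match.arg(step_dom_convention)
  p <- list(
    initial_dominance = initial_dominance, step_dom = step_dom,
    n_mental_battles = n_mental_battles, field_of_view = field_of_view,
    pers_space = pers_space, near_view = near_view, max_view = max_view,
    flee_dist = flee_dist, withdraw_dist = withdraw_dist,
    chase_dist = chase_dist, move_dist = move_dist,
    wiggle_turn = wiggle_turn, wiggle_turn_error = wiggle_turn_error,
    search_turn = search_turn, search_turn_error = search_turn_error,
    won_turn = won_turn, won_turn_error = won_turn_error,
    flee_turn = flee_turn, flee_turn_error = flee_turn_error,
    world_size = world_size, n_periods = n_periods,
    burn_in_periods = burn_in_periods,
    step_dom_convention = step_dom_convention,
    dominance_floor = dominance_floor,
    compete_unseen = compete_unseen)
  class(p) <- "sim_params"
  validate_sim_params(p)
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  need <- c("female", "male")
  if (!all(need %in% names(p$initial_dominance)) ||
      !all(need %in% names(p$step_dom)))
    stop("initial_dominance and step_dom need named 'female' and 'male' entries")
  if (any(p$initial_dominance <= 0)) stop("initial dominance values must be > 0")
  dists <- c(p$pers_space, p$near_view, p$max_view, p$flee_dist,
             p$withdraw_dist, p$chase_dist, p$move_dist)
  if (any(dists < 0)) stop("distances must be >= 0")
  if (!(p$pers_space <= p$near_view && p$near_view <= p$max_view))
    stop("need pers_space <= near_view <= max_view")
  if (p$field_of_view <= 0 || p$field_of_view > 360)
    stop("field_of_view must lie in (0, 360]")
  if (p$n_mental_battles < 1) stop("n_mental_battles must be >= 1")
  if (p$burn_in_periods >= p$n_periods)
    stop("burn_in_periods must be smaller than n_periods")
  if (p$dominance_floor <= 0) stop("dominance_floor must be > 0")
  if (p$world_size <= 0) stop("world_size must be > 0")
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Winner-loser simulation parameters\n")
  cat(sprintf("  initial dominance f/m : %g / %g\n",
              x$initial_dominance[["female"]], x$initial_dominance[["male"]]))
  cat(sprintf("  step_dom f/m          : %g / %g (convention: %s)\n",
              x$step_dom[["female"]], x$step_dom[["male"]],
              x$step_dom_convention))
  cat(sprintf("  radii pers/near/max   : %g / %g / %g\n",
              x$pers_space, x$near_view, x$max_view))
  cat(sprintf("  world %g x %g torus, %d periods (%d burn-in)\n",
              x$world_size, x$world_size, x$n_periods, x$burn_in_periods))
  invisible(x)
}

#' Group composition
#'
#' @param n_males,n_females adult counts; at least two adults in total.
#' @param label optional label; defaults to the `"<m>m<f>f"` convention.
#' @return An object of class `group_composition`.
#' @examples
#' group_composition(5, 4)$label
#' @export
group_composition <- function(n_males, n_females,
                              label = sprintf("%dm%df", n_males, n_females)) {
  if (n_males < 0 || n_females < 0 ||
      n_males %% 1 != 0 || n_females %% 1 != 0)
    stop("n_males and n_females must be non-negative integers")
  if (n_males + n_females < 1)
    stop("a group needs at least one member")
  structure(list(n_males = as.integer(n_males),
                 n_females = as.integer(n_females), label = label),
            class = "group_composition")
}

## internal: degree trig
.d2r <- pi / 180

#' Initialise a simulated group
#'
#' Places `n_males + n_females` agents uniformly at random inside a
#' 20-unit-radius disc at the centre of the toroidal world (so everyone
#' starts within visual range and the group does not disperse), with
#' uniformly random headings. Males receive the male initial dominance
#' and intensity of aggression, females the female values.
#'
#' @param params a [sim_params()] object.
#' @param comp a [group_composition()].
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return A data frame with one row per agent: `id`, `sex`, `x`, `y`,
#'   `heading` (degrees), `D` (dominance value), `step_dom`.
#' @examples
#' w <- init_world(sim_params(), group_composition(2, 4), seed = 1)
#' w$D
#' @export
init_world <- function(params, comp, seed = NULL) {
  validate_sim_params(params)
  if (!inherits(comp, "group_composition")) stop("comp must be a group_composition")
  if (!is.null(seed)) set.seed(seed)
  n <- comp$n_males + comp$n_females
  sex <- rep(c("male", "female"), c(comp$n_males, comp$n_females))
  id <- c(sprintf("m%d", seq_len(comp$n_males)),
          sprintf("f%d", seq_len(comp$n_females)))
  r <- 20 * sqrt(stats::runif(n))
  a <- stats::runif(n, 0, 2 * pi)
  W <- params$world_size
  data.frame(
    id = id, sex = sex,
    x = (W / 2 + r * cos(a)) %% W,
    y = (W / 2 + r * sin(a)) %% W,
    heading = stats::runif(n, 0, 360),
    D = unname(params$initial_dominance[sex]),
    step_dom = unname(params$step_dom[sex]),
    stringsAsFactors = FALSE)
}

#' Mental battle: should the focal agent attack?
#'
#' The focal agent runs `n_battles` independent internal estimates of
#' winning against an opponent; it attacks only if it wins every one.
#' Each estimate succeeds with probability `Di / (Di + Dj)`, so the
#' attack probability is `(Di / (Di + Dj))^n_battles`: agents are
#' risk-sensitive and rarely attack much stronger opponents.
#'
#' @param Di,Dj strictly positive dominance values of focal and opponent.
#' @param n_battles integer >= 1.
#' @return `TRUE` if the focal attacks.
#' @examples
#' set.seed(1); mean(replicate(1000, mental_battle(32, 16)))  # ~ 2/3
#' @export
mental_battle <- function(Di, Dj, n_battles = 1) {
  if (Di <= 0 || Dj <= 0) stop("dominance values must be > 0")
  if (n_battles < 1) stop("n_battles must be >= 1")
  p <- Di / (Di + Dj)
  all(stats::runif(n_battles) < p)
}

#' Fight outcome
#'
#' @param Di,Dj strictly positive dominance values of initiator and
#'   opponent.
#' @return 1 if the initiator wins (probability `Di / (Di + Dj)`),
#'   else 0.
#' @examples
#' set.seed(1); mean(replicate(1000, fight_outcome(32, 16)))  # ~ 2/3
#' @export
fight_outcome <- function(Di, Dj) {
  if (Di <= 0 || Dj <= 0) stop("dominance values must be > 0")
  as.integer(stats::runif(1) < Di / (Di + Dj))
}

#' Winner-loser update of dominance values
#'
#' After a fight the winner's dominance rises and the loser's falls by
#' the same amount `delta = (w - Di/(Di+Dj)) * S`: an expected win
#' changes values little, an upset changes them much (damped positive
#' feedback). `S` is the intensity-of-aggression scale chosen from the
#' two agents' `step_dom` values by `convention`. Values are floored at
#' `floor`; without flooring the update conserves `Di + Dj`.
#'
#' @param Di,Dj dominance values of initiator and opponent (> 0).
#' @param w fight outcome for the initiator, 0 or 1.
#' @param Si,Sj `step_dom` of initiator and opponent.
#' @param convention `"initiator"`, `"winner"`, `"opponent"` or `"mean"`.
#' @param floor lower bound kept on dominance values.
#' @return Numeric of length 2: updated `c(Di, Dj)`.
#' @examples
#' update_dominance(32, 32, 1, 1, 1)        # c(32.5, 31.5)
#' update_dominance(16, 32, 1, 1, 1)        # upset: c(16.667, 31.333)
#' @export
update_dominance <- function(Di, Dj, w, Si, Sj,
                             convention = "mean", floor = 0.01) {
  if (Di <= 0 || Dj <= 0) stop("dominance values must be > 0")
  if (!w %in% c(0, 1)) stop("w must be 0 or 1")
  S <- switch(convention,
              initiator = Si,
              winner    = if (w == 1) Si else Sj,
              opponent  = Sj,
              mean      = (Si + Sj) / 2,
              stop("unknown step_dom convention: ", convention))
  delta <- (w - Di / (Di + Dj)) * S
  c(max(floor, Di + delta), max(floor, Dj - delta))
}

## internal: toroidal displacement components from i to all others
.torus_delta <- function(z, zi, W) (z - zi + W / 2) %% W - W / 2

## internal mutable state used by the activation step; plain environment
## with vectors x, y, h, D, S and scalar floor_hit
.as_state <- function(world, params) {
  e <- new.env(parent = emptyenv())
  e$x <- world$x; e$y <- world$y; e$h <- world$heading
  e$D <- world$D; e$S <- world$step_dom
  e$sex <- world$sex; e$id <- world$id
  e$floor_hit <- FALSE
  e
}

.state_to_world <- function(e) {
  data.frame(id = e$id, sex = e$sex, x = e$x, y = e$y, heading = e$h,
             D = e$D, step_dom = e$S, stringsAsFactors = FALSE)
}

## internal: one activation of agent i. Mutates state `e`; returns an
## integer fight record c(initiator, opponent, winner) or NULL.
.activate <- function(e, i, P) {
  W <- P$world_size
  n <- length(e$x)
  rec <- NULL
  if (n > 1) {
    dx <- .torus_delta(e$x, e$x[i], W)
    dy <- .torus_delta(e$y, e$y[i], W)
    d2 <- dx * dx + dy * dy
    d2[i] <- Inf
    rel <- ((atan2(dy, dx) / .d2r - e$h[i] + 180) %% 360) - 180
    vis <- abs(rel) <= P$field_of_view / 2 & d2 <= P$max_view^2
    # proximity-triggered competition: agents inside the personal space
    # are reacted to whether or not they fall in the field of view
    if (isTRUE(P$compete_unseen)) vis <- vis | d2 <= P$pers_space^2
    vis[i] <- FALSE
  } else vis <- FALSE
  if (!any(vis)) {
    # nobody in sight: turn to a random side and search
    side <- if (stats::runif(1) < 0.5) -1 else 1
    e$h[i] <- e$h[i] + side * P$search_turn +
      stats::runif(1, -P$search_turn_error, P$search_turn_error)
    .advance(e, i, P$move_dist, W)
    return(NULL)
  }
  cand <- which(vis)
  j <- cand[which.min(d2[cand])]
  dj <- sqrt(d2[j])
  if (dj <= P$pers_space) {
    if (mental_battle(e$D[i], e$D[j], P$n_mental_battles)) {
      w <- fight_outcome(e$D[i], e$D[j])
      upd <- update_dominance(e$D[i], e$D[j], w, e$S[i], e$S[j],
                              P$step_dom_convention, P$dominance_floor)
      if (upd[1] == P$dominance_floor || upd[2] == P$dominance_floor)
        e$floor_hit <- TRUE
      e$D[i] <- upd[1]; e$D[j] <- upd[2]
      win <- if (w == 1) i else j
      los <- if (w == 1) j else i
      # both reorient relative to the direction winner -> loser
      ang_wl <- atan2(.torus_delta(e$y[los], e$y[win], W),
                      .torus_delta(e$x[los], e$x[win], W)) / .d2r
      e$h[win] <- ang_wl + P$won_turn +
        stats::runif(1, -P$won_turn_error, P$won_turn_error)
      .advance(e, win, P$chase_dist, W)
      e$h[los] <- ang_wl + P$flee_turn +
        stats::runif(1, -P$flee_turn_error, P$flee_turn_error)
      .advance(e, los, P$flee_dist, W)
      rec <- c(i, j, win)
    } else {
      # lost the mental battle: turn away and withdraw
      e$h[i] <- e$h[i] + 180 + stats::runif(1, -10, 10)
      .advance(e, i, P$withdraw_dist, W)
    }
  } else if (dj <= P$near_view) {
    # close enough to stay grouped: proceed with a small wiggle
    e$h[i] <- e$h[i] + P$wiggle_turn +
      stats::runif(1, -P$wiggle_turn_error, P$wiggle_turn_error)
    .advance(e, i, P$move_dist, W)
  } else {
    # visible only at long range: return towards the group
    e$h[i] <- atan2(dy[j], dx[j]) / .d2r
    .advance(e, i, P$move_dist, W)
  }
  rec
}

.advance <- function(e, i, dist, W) {
  if (dist > 0) {
    e$x[i] <- (e$x[i] + dist * cos(e$h[i] * .d2r)) %% W
    e$y[i] <- (e$y[i] + dist * sin(e$h[i] * .d2r)) %% W
  }
  invisible(e)
}

#' One activation of a focal agent
#'
#' Executes the behavioural rule of a single agent: it reacts to the
#' nearest other agent visible within its field of view and `max_view`.
#' Within `pers_space` it runs a mental battle and possibly fights
#' (winner chases, loser flees, dominance values updated); within
#' `near_view` it proceeds with a small wiggle; beyond `near_view` but
#' within `max_view` it turns towards the other and approaches; if it
#' sees nobody it turns a search angle to a random side and moves on.
#'
#' @param world agent data frame as returned by [init_world()].
#' @param focal integer index of the activated agent.
#' @param params a [sim_params()] object.
#' @return A list with `world` (updated data frame) and `record`:
#'   either `NULL` or a list `(initiator, opponent, winner)` of agent
#'   indices when a fight took place.
#' @export
resolve_activation <- function(world, focal, params) {
  validate_sim_params(params)
  if (focal < 1 || focal > nrow(world)) stop("focal index out of range")
  e <- .as_state(world, params)
  rec <- .activate(e, focal, params)
  list(world = .state_to_world(e),
       record = if (is.null(rec)) NULL else
         list(initiator = rec[1], opponent = rec[2], winner = rec[3]))
}

#' Run the winner-loser simulation for one group
#'
#' Simulates `params$n_periods` activation periods; in each period every
#' agent is activated once in uniformly random order. Fights occurring
#' after the burn-in are tallied into a winner-loser [interaction
#' matrix][interaction_matrix] and an initiator-attributed directed
#' "acts" matrix (entry `[i, j]` = attacks by `i` on `j`, whoever won).
#'
#' @param params a [sim_params()] object.
#' @param comp a [group_composition()].
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return An object of class `domworld_run`: a list with `matrix` (the
#'   post-burn-in [interaction_matrix()]), `acts` (directed attack
#'   counts), `d_series` (`n_periods` x n matrix of dominance values at
#'   the end of each period), `floor_hit` (was the dominance floor ever
#'   applied), plus `params`, `comp`, `seed`.
#' @examples
#' p <- sim_params(n_periods = 40, burn_in_periods = 10)
#' r <- run_simulation(p, group_composition(2, 4), seed = 42)
#' sum(r$matrix$counts)
#' @export
run_simulation <- function(params, comp, seed = NULL) {
  validate_sim_params(params)
  world <- init_world(params, comp, seed = seed)
  n <- nrow(world)
  e <- .as_state(world, params)
  counts <- matrix(0L, n, n, dimnames = list(world$id, world$id))
  acts <- matrix(0L, n, n, dimnames = list(world$id, world$id))
  d_series <- matrix(NA_real_, params$n_periods, n,
                     dimnames = list(NULL, world$id))
  for (period in seq_len(params$n_periods)) {
    ord <- if (n > 1) sample.int(n) else 1L
    for (i in ord) {
      rec <- .activate(e, i, params)
      if (!is.null(rec) && period > params$burn_in_periods) {
        win <- rec[3]
        los <- if (rec[3] == rec[1]) rec[2] else rec[1]
        counts[win, los] <- counts[win, los] + 1L
        acts[rec[1], rec[2]] <- acts[rec[1], rec[2]] + 1L
      }
    }
    d_series[period, ] <- e$D
  }
  structure(list(
    matrix = interaction_matrix(counts, ids = world$id, sexes = world$sex),
    acts = acts, d_series = d_series, floor_hit = e$floor_hit,
    params = params, comp = comp, seed = seed),
    class = "domworld_run")
}

#' @export
print.domworld_run <- function(x, ...) {
  cat(sprintf("Winner-loser simulation run: group %s, %d periods (%d burn-in)\n",
              x$comp$label, x$params$n_periods, x$params$burn_in_periods))
  cat(sprintf("  fights tallied after burn-in: %d\n", sum(x$matrix$counts)))
  invisible(x)
}
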