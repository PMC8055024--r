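test_that("parameter validation rejects inconsistent settings", {
  expect_error(sim_params(pers_space = 30), "pers_space")
  expect_error(sim_params(field_of_view = 0), "field_of_view")
  expect_error(sim_params(n_mental_battles = 0), "mental")
  expect_error(sim_params(n_periods = 10, burn_in_periods = 10), "burn_in")
  expect_error(sim_params(dominance_floor = 0), "floor")
  expect_error(group_composition(-1, 4), "non-negative")
})

test_that("world initialisation assigns sex-specific dominance", {
  w <- init_world(sim_params(), group_composition(2, 4), seed = 1)
  expect_equal(nrow(w), 6)
  expect_equal(w$D[w$sex == "male"], c(32, 32))
  expect_equal(w$D[w$sex == "female"], rep(16, 4))
  expect_equal(w$step_dom[w$sex == "male"], c(1, 1))
  # degenerate single-agent group
  w1 <- init_world(sim_params(), group_composition(1, 0), seed = 1)
  expect_equal(w1$D, 32)
  # determinism
  expect_identical(init_world(sim_params(), group_composition(3, 3), seed = 7),
                   init_world(sim_params(), group_composition(3, 3), seed = 7))
  # positions on the torus, headings in [0, 360)
  W <- sim_params()$world_size
  expect_true(all(w$x >= 0 & w$x < W & w$y >= 0 & w$y < W))
  expect_true(all(w$heading >= 0 & w$heading < 360))
})

test_that("mental battle and fight outcome follow relative dominance", {
  set.seed(1)
  n <- 2e4
  # equal dominance: attack probability one half with one battle
  p1 <- mean(replicate(n, mental_battle(10, 10, 1)))
  expect_equal(p1, 0.5, tolerance = 0.02)
  # two battles multiply: one quarter
  p2 <- mean(replicate(n, mental_battle(10, 10, 2)))
  expect_equal(p2, 0.25, tolerance = 0.02)
  # 2:1 dominance gives 2/3
  p3 <- mean(replicate(n, mental_battle(32, 16, 1)))
  expect_equal(p3, 2 / 3, tolerance = 0.02)
  w <- mean(replicate(n, fight_outcome(32, 16)))
  expect_equal(w, 2 / 3, tolerance = 0.02)
  # overwhelming dominance wins essentially always
  expect_equal(mean(replicate(2000, fight_outcome(1e6, 0.01))), 1,
               tolerance = 0.005)
  expect_error(mental_battle(-1, 2), "> 0")
  expect_error(fight_outcome(0, 2), "> 0")
})

test_that("dominance updates are damped, zero-sum and floored", {
  expect_equal(update_dominance(32, 32, 1, 1, 1), c(32.5, 31.5))
  # an unexpected win by the weaker party moves values more
  expect_equal(update_dominance(16, 32, 1, 1, 1),
               c(16 + 2 / 3, 32 - 2 / 3), tolerance = 1e-12)
  set.seed(4)
  for (rep in 1:50) {
    Di <- runif(1, 1, 50); Dj <- runif(1, 1, 50)
    w <- rbinom(1, 1, 0.5); S <- runif(1, 0.1, 2)
    out <- update_dominance(Di, Dj, w, S, S)
    expect_equal(sum(out), Di + Dj, tolerance = 1e-12)
  }
  # flooring prevents non-positive dominance
  out <- update_dominance(0.3, 0.3, 0, 1, 1)
  expect_equal(out[1], 0.01)
  expect_equal(out[2], 0.8)
  # conventions pick the right scale
  expect_equal(update_dominance(10, 10, 1, 1, 0.2, "initiator"), c(10.5, 9.5))
  expect_equal(update_dominance(10, 10, 1, 1, 0.2, "opponent"), c(10.1, 9.9))
  expect_equal(update_dominance(10, 10, 0, 1, 0.2, "winner"), c(9.9, 10.1))
  expect_equal(update_dominance(10, 10, 1, 1, 0.2, "mean"), c(10.3, 9.7))
  expect_error(update_dominance(10, 10, 1, 1, 1, "nobody"), "convention")
})

test_that("activation reacts to the nearest visible other as specified", {
  p <- sim_params()
  # two agents at medium range: focal turns towards the other, no record
  w <- data.frame(id = c("m1", "f1"), sex = c("male", "female"),
                  x = c(100, 130), y = c(100, 100),
                  heading = c(0, 180), D = c(32, 16), step_dom = c(1, 0.1))
  set.seed(2)
  res <- resolve_activation(w, 1, p)
  expect_null(res$record)
  expect_equal(res$world$heading[1] %% 360, 0)        # already facing it
  expect_equal(res$world$x[1], 101)                   # advanced move_dist
  # single agent searches and records nothing
  res1 <- resolve_activation(w[1, ], 1, p)
  expect_null(res1$record)
  # within personal space with equal D and a forced win: loser flees
  # flee_dist, winner chases chase_dist
  w2 <- w; w2$x <- c(100, 103); w2$D <- c(32, 32)
  repeat {
    before <- w2
    set.seed(sample.int(1e6, 1))
    res2 <- resolve_activation(w2, 1, p)
    if (!is.null(res2$record) && res2$record$winner == 1) break
  }
  expect_equal(res2$record$initiator, 1)
  expect_equal(res2$record$opponent, 2)
  dx_loser <- res2$world$x[2] - before$x[2]
  dy_loser <- res2$world$y[2] - before$y[2]
  expect_equal(sqrt(dx_loser^2 + dy_loser^2), p$flee_dist, tolerance = 1e-9)
  dx_win <- res2$world$x[1] - before$x[1]
  dy_win <- res2$world$y[1] - before$y[1]
  expect_equal(sqrt(dx_win^2 + dy_win^2), p$chase_dist, tolerance = 1e-9)
})

test_that("simulation runs are deterministic given a seed", {
  p <- fast_params()
  r1 <- run_simulation(p, group_composition(2, 3), seed = 123)
  r2 <- run_simulation(p, group_composition(2, 3), seed = 123)
  expect_identical(r1$matrix$counts, r2$matrix$counts)
  expect_identical(r1$d_series, r2$d_series)
  expect_error(run_simulation(sim_params(n_periods = 5, burn_in_periods = 9),
                              group_composition(2, 2)), "burn_in")
})

test_that("dominance is conserved while the floor is never hit", {
  p <- fast_params()
  consistent <- 0; checked <- 0
  for (s in 1:5) {
    r <- run_simulation(p, group_composition(3, 3), seed = s)
    if (r$floor_hit) next
    checked <- checked + 1
    tot0 <- sum(r$d_series[1, ])
    expect_equal(sum(r$d_series[p$n_periods, ]), tot0, tolerance = 1e-8)
    expect_true(all(abs(rowSums(r$d_series) - tot0) < 1e-8))
  }
  expect_gte(checked, 1)
  # and the floor is respected in all runs
  r <- run_simulation(fast_params(), group_composition(5, 4), seed = 2)
  expect_true(all(r$d_series >= sim_params()$dominance_floor))
})

test_that("sex labels are exchangeable under sex-symmetric parameters", {
  p <- fast_params(initial_dominance = c(female = 32, male = 32),
                   step_dom = c(female = 1, male = 1))
  # seed-paired runs with swapped compositions give identical dynamics
  # up to labels: male-count statistics of (2m, 3f) match female-count
  # statistics of (3m, 2f)
  fdis <- sapply(1:40, function(s) {
    r <- run_simulation(p, group_composition(2, 2), seed = s)
    hs <- tryCatch(hierarchy_summary(r$matrix, acts = r$acts),
                   error = function(e) NULL)
    if (is.null(hs)) NA else hs$fdi
  })
  expect_equal(mean(fdis, na.rm = TRUE), 0.5, tolerance = 0.15)
})

test_that("hierarchy differentiation grows between burn-in and run end", {
  p <- sim_params(n_periods = 200, burn_in_periods = 40)
  grew <- sapply(1:20, function(s) {
    r <- run_simulation(p, group_composition(4, 4), seed = 100 + s)
    cv <- function(v) sd(v) / mean(v)
    cv(r$d_series[200, ]) > cv(r$d_series[40, ])
  })
  # sign test: differentiation increases in a clear majority of runs
  expect_gt(mean(grew), 0.5)
  expect_lt(binom.test(sum(grew), length(grew), 0.5,
                       alternative = "greater")$p.value, 0.05)
})

test_that("mixed-sex groups under default parameters produce male-male fights", {
  r <- run_simulation(fast_params(), group_composition(5, 4), seed = 11)
  male <- r$matrix$sexes == "male"
  expect_gt(sum(r$acts[male, male]), 0)
  expect_gt(sum(r$matrix$counts), 0)
})
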