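test_that("reserve interpolation is exact at nodes, linear between, clamped", {
  grid <- seq(0, 10, by = 2)
  vals <- c(0, 1, 4, 9, 16, 25)
  expect_equal(interpolate_value(vals, grid, grid), vals)
  expect_equal(interpolate_value(c(0, 1, 0, 0, 0, 0), 1, grid), 0.5)
  expect_equal(interpolate_value(vals, 15, grid), 25)   # above the cap
  expect_equal(interpolate_value(vals, -3, grid), 0)    # below zero
})

test_that("tiny capital season is solved exactly: forage, lay, incubate", {
  # 6-day season, 2-day incubation, f(t) = (6 - t) / 5. The only optimal
  # plan from (S = 0, day 1) is forage day 1, lay day 2, incubate day 3,
  # hatch day 5: 1 egg x f(5) = 0.2 expected recruits (checked by hand and
  # by exhaustive enumeration).
  p <- tiny_params()
  d <- deterministic_food_gain(p)
  s <- recruitment_schedule(p)
  pol <- optimize_policy(p, d, s, "capital")
  expect_equal(pol$V[1, 1, 1], 0.2)
  expect_equal(brute_force_value(p, d, s, "capital"), 0.2)
  out <- simulate_female(pol, 1)
  expect_equal(out$recruits, 0.2)
  expect_equal(out$clutch, 1L)
  acts <- attr(out, "actions")[1, 1:3]
  expect_equal(acts, c(1L, 2L, 3L))  # forage, lay, incubate
})

test_that("dynamic program equals exhaustive enumeration on aligned grids", {
  p <- tiny_params()
  s <- recruitment_schedule(p)
  for (strat in c("capital", "income")) {
    for (d in list(deterministic_food_gain(p), two_point_gain())) {
      pol <- optimize_policy(p, d, s, strat)
      for (S0 in c(0, 1, 2)) for (t0 in 1:3) {
        S0s <- min(S0, pol$S_max)
        expect_equal(pol$V[match(S0s, pol$S_grid), t0, 1],
                     brute_force_value(p, d, s, strat, S0 = S0s, t0 = t0),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("value function respects terminal condition, bounds, monotonicity", {
  p <- model_params()
  d <- discretize_food_gain(3, p)
  for (strat in c("capital", "income")) {
    pol <- optimize_policy(p, d, strategy = strat)
    expect_true(all(pol$V[, p$T_end, ] == 0))
    expect_true(all(pol$V >= 0))
    expect_true(all(pol$V <= p$n_max * p$f_max + 1e-9))
    # more reserves never hurt
    expect_true(all(apply(pol$V, c(2, 3), diff) >= -1e-9))
  }
})

test_that("full clutches are incubated wherever incubation is available", {
  p <- model_params()
  d <- discretize_food_gain(0.5, p)
  for (strat in c("capital", "income")) {
    pol <- optimize_policy(p, d, strategy = strat)
    win <- p$b_s:(p$T_end - p$I)
    expect_true(all(pol$action[, win, p$n_max + 1] == 3L))
  }
})

test_that("income breeders never postpone laying under constant food", {
  p <- model_params()
  pol <- optimize_policy(p, deterministic_food_gain(p), strategy = "income")
  top <- length(pol$S_grid)             # the S = cE node
  days <- p$b_s:(p$T_end - p$I - 1)
  acts <- pol$action[top, days, 1:p$n_max]
  expect_true(all(acts %in% c(2L, 3L)))  # lay or incubate, never forage
})

test_that("near-deterministic beta matches the deterministic baseline", {
  p <- model_params()
  v_det <- optimize_policy(p, deterministic_food_gain(p),
                           strategy = "capital")$V[1, p$D_a, 1]
  v_500 <- optimize_policy(p, discretize_food_gain(500, p),
                           strategy = "capital")$V[1, p$D_a, 1]
  expect_lt(abs(v_500 - v_det) / v_det, 0.02)
})

test_that("degenerate configurations are refused", {
  p <- tiny_params()
  expect_error(optimize_policy(model_params(dS = 2),
                               deterministic_food_gain(p)), "divide")
  big <- model_params()
  expect_error(brute_force_value(big, deterministic_food_gain(big)),
               "too large")
})
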