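test_that("simulated trajectories respect the model's physical constraints", {
  p <- model_params(N_pop = 200)
  for (a in c(0.5, 3)) {
    d <- discretize_food_gain(a, p)
    for (strat in c("capital", "income")) {
      pol <- optimize_policy(p, d, strategy = strat)
      coh <- sample_arrival_days(p, seed = 21)
      out <- simulate_population(pol, coh, seed = 22, record = TRUE)
      res <- attr(out, "reserves")
      acts <- attr(out, "actions")
      expect_true(all(res >= -1e-9, na.rm = TRUE))
      expect_true(all(res <= pol$S_max + 1e-9, na.rm = TRUE))
      expect_true(all(out$clutch <= p$n_max))
      expect_true(all(out$t_hatch <= p$T_end, na.rm = TRUE))
      # recruits recomputed from clutch and hatch day
      h <- !is.na(out$t_hatch)
      expect_equal(out$recruits[h],
                   out$clutch[h] *
                     recruitment_probability(out$t_hatch[h], pol$sched))
      expect_true(all(out$recruits[!h] == 0))
      # hatch follows incubation onset by i_hatch days
      expect_true(all(out$t_hatch[h] - out$t_incubation[h] == p$i_hatch))
      # laying window and ordering
      b <- !is.na(out$t_first_egg)
      expect_true(all(out$t_first_egg[b] >= p$b_s))
      expect_true(all(out$t_first_egg[b] >= out$arrival[b]))
      if (strat == "capital") {
        # uninterrupted daily laying, then incubation the next day;
        # no foraging after the first egg
        expect_true(all(out$t_incubation[h] - out$t_first_egg[h] ==
                          out$clutch[h]))
        for (j in which(b)) {
          after <- acts[j, out$t_first_egg[j]:p$T_end]
          expect_false(any(after == 1L, na.rm = TRUE))
        }
      } else {
        expect_true(all(out$t_incubation[h] - out$t_first_egg[h] >=
                          out$clutch[h] - 1))
      }
    }
  }
})

test_that("simulation is reproducible and seed-sensitive", {
  p <- model_params(N_pop = 300)
  pol <- optimize_policy(p, discretize_food_gain(3, p), strategy = "capital")
  coh <- sample_arrival_days(p, seed = 5)
  o1 <- simulate_population(pol, coh, seed = 9)
  o2 <- simulate_population(pol, coh, seed = 9)
  expect_identical(o1, o2)
  expect_false(identical(o1$recruits, simulate_population(pol, coh,
                                                          seed = 10)$recruits))
})

test_that("under constant food each female realizes the optimal value", {
  p <- model_params()
  d <- deterministic_food_gain(p)
  for (strat in c("capital", "income")) {
    pol <- optimize_policy(p, d, strategy = strat)
    for (a in c(70L, 90L, 110L)) {
      out <- simulate_population(pol, a, seed = 1)
      expect_equal(out$recruits, pol$V[1, a, 1], tolerance = 1e-9)
    }
  }
})

test_that("population summaries compute the documented statistics", {
  p <- model_params()
  out <- data.frame(arrival = c(85L, 90L, 95L, 100L),
                    t_first_egg = c(100L, 102L, NA, 104L),
                    t_incubation = c(103L, 105L, NA, 107L),
                    clutch = c(3L, 3L, 0L, 3L),
                    t_hatch = c(129L, 131L, NA, 133L),
                    recruits = c(2.13, 2.07, 0, 2.01),
                    s_peak = c(500, 450, 300, 480))
  s <- summarize_population(out, p)
  expect_equal(s$onset_rel_bs, mean(c(0, 2, 4)))   # breeders only
  expect_equal(s$clutch_mean, mean(c(3, 3, 0, 3))) # all females
  expect_equal(s$recruits_mean, mean(out$recruits))
  expect_equal(s$frac_failed, 0.25)
  expect_equal(s$recruit_prob,
               mean(recruitment_probability(c(129, 131, 133),
                                            recruitment_schedule(p))))
  # degenerate cohort: identical birds, zero variance
  same <- out[c(1, 1, 1), ]
  expect_equal(summarize_population(same, p)$recruits_var, 0)
  expect_error(summarize_population(out[0, ], p), "no simulated females")
})
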