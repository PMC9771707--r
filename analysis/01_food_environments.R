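#!/usr/bin/env Rscript

# Step 1 — the stochastic food environments.
# Builds the discretized symmetric-beta distributions of net daily food
# gain used throughout the analysis (k = 20 outcomes on [-15, 45] g/day,
# mean pinned at 15 g/day) and records how their variance tracks the
# continuous beta parent.

library(breedopt)

params <- model_params()
alphas <- c(500, 50, 10, 3, 1, 0.5, 0.1)

dists <- lapply(alphas, discretize_food_gain, params = params)
tab <- do.call(rbind, Map(function(a, d) {
  cbind(alpha = a, as.data.frame(d))
}, alphas, dists))

dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/food_gain_distributions.csv", row.names = FALSE)

cat("Discretized daily food-gain environments (w_a = 15 g/day):\n")
for (d in dists) {
  v_cont <- ((params$x2 - params$x1) * params$w_a)^2 / (4 * (2 * d$alpha + 1))
  cat(sprintf(
    "  alpha %6.1f: mean %.4f g/day, sd %6.3f g/day (continuous beta sd %6.3f)\n",
    d$alpha, d$mean, sqrt(d$variance), sqrt(v_cont)))
}
cat("Every distribution keeps the 15 g/day mean; only the variance moves.\n")
cat("Written: results/food_gain_distributions.csv\n")
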