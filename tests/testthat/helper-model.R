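# Small instances shared across tests.

# Tiny season: 6 days, 2-day incubation, 1-gram eggs, 1 g/day gain.
# Small enough to enumerate every action sequence by hand or brute force.
tiny_params <- function(...) {
  base <- list(E = 1, c = 1, n_max = 2, I = 2, i_hatch = 2, w_a = 1,
               x1 = -1, x2 = 3, k = 2, b_s = 1, b_ref = 1, T_end = 6,
               M_L = 10, S_max_capital = 2, dS = 1, D_a = 1, SD_a = 0,
               N_pop = 1, seed = 1L)
  do.call(model_params, utils::modifyList(base, list(...)))
}

# Two-outcome gain: 0 or 2 g with equal probability (mean 1 = w_a above);
# all reachable reserve levels stay on the 1-g grid, so the dynamic program
# involves no interpolation and must match enumeration exactly.
two_point_gain <- function() food_gain_distribution(c(0, 2), c(0.5, 0.5))
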