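#' Run one scenario: optimize the policy and simulate a cohort
#'
#' Composes the full pipeline for one (strategy, spring onset, food
#' environment) cell: build the food-gain distribution, solve the backward
#' induction, draw an arrival cohort, simulate it forward and summarize.
#'
#' Randomness is derived from `seed` so that the arrival cohort depends
#' only on (`seed`, `b_s`) and the daily foraging luck only on (`seed`,
#' `strategy`, `b_s`) — not on `alpha`. Together with inverse-CDF gain
#' sampling this makes scenarios that differ only in food-gain variance
#' share cohorts and comonotone daily draws, which stabilizes ratios taken
#' against the deterministic baseline.
#'
#' @param strategy `"capital"` or `"income"`.
#' @param b_s first possible breeding day for this scenario.
#' @param alpha beta shape of the food-gain distribution, or `NA` for the
#'   deterministic baseline (every day yields exactly `w_a`).
#' @param params base [model_params()]; `b_s` above overrides its field.
#' @param seed integer master seed.
#' @param return_outcomes if `TRUE`, return the per-female outcomes and the
#'   policy alongside the summary.
#' @return The [summarize_population()] row augmented with `strategy`,
#'   `b_s` and `alpha` columns; or, with `return_outcomes = TRUE`, a list
#'   `(summary, outcomes, policy)`.
#' @export
run_scenario <- function(strategy, b_s, alpha = NA, params = model_params(),
                         seed = params$seed, return_outcomes = FALSE) {
  pars <- params
  pars$b_s <- as.integer(b_s)
  validate_params(pars)
  dist <- if (is.na(alpha)) deterministic_food_gain(pars)
          else discretize_food_gain(alpha, pars)
  sched <- recruitment_schedule(pars)
  policy <- optimize_policy(pars, dist, sched, strategy)
  cohort <- sample_arrival_days(pars, seed = child_seed(seed, b_s, 1L))
  strat_code <- if (strategy == "capital") 2L else 3L
  outcomes <- simulate_population(policy, cohort,
                                  seed = child_seed(seed, b_s, strat_code))
  summ <- summarize_population(outcomes, pars)
  summ <- cbind(data.frame(strategy = strategy, b_s = pars$b_s,
                           alpha = alpha), summ)
  if (return_outcomes) list(summary = summ, outcomes = outcomes,
                            policy = policy)
  else summ
}

# Deterministic child seed in [1, 2^31 - 2]; doubles are exact far beyond
# the magnitudes reached here.
child_seed <- function(seed, a, b) {
  as.integer((abs(seed) * 48271 + a * 9973 + b * 101) %% 2147483646) + 1L
}

#' Sweep spring onset against food-gain variance for both strategies
#'
#' Full factorial over `strategies` x `b_s_values` x food environments
#' (each `alpha` plus, when `include_deterministic`, the constant-gain
#' baseline). For every stochastic cell the mean recruits per female is
#' also expressed relative to the matched deterministic cell
#' (`rel_recruitment`), the model's measure of how food uncertainty helps
#' or hurts each strategy.
#'
#' `b_ref` (the anchor of the recruitment decline) is taken from `params`
#' and must not exceed the earliest `b_s` in the sweep, so all scenarios
#' share one recruitment schedule.
#'
#' @param strategies character vector among `"capital"`, `"income"`.
#' @param b_s_values integer vector of spring-onset days.
#' @param alphas numeric vector of beta shapes (variance axis; variance
#'   falls as alpha rises). The default spans near-deterministic
#'   (`alpha = 500`) to strongly bimodal daily outcomes (`alpha = 0.1`);
#'   the low-alpha end is where reserve storage pays off.
#' @param include_deterministic add the constant-gain baseline environment
#'   (required for `rel_recruitment`).
#' @param params base [model_params()].
#' @param seed master seed (cohorts shared across the variance axis).
#' @return A `scenario_table` data frame, one row per cell.
#' @export
run_sweep <- function(strategies = c("income", "capital"),
                      b_s_values = seq(100, 150, by = 10),
                      alphas = c(500, 50, 10, 3, 1, 0.5, 0.1),
                      include_deterministic = TRUE,
                      params = model_params(), seed = params$seed) {
  stopifnot(length(strategies) >= 1, length(b_s_values) >= 1)
  if (min(b_s_values) < params$b_ref)
    stop("b_ref must not exceed the earliest b_s in the sweep")
  envs <- c(if (include_deterministic) NA_real_, alphas)
  if (!length(envs)) stop("no food environments requested")
  cells <- expand.grid(strategy = strategies, b_s = b_s_values,
                       alpha = envs, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(j)
    run_scenario(cells$strategy[j], cells$b_s[j], cells$alpha[j],
                 params = params, seed = seed))
  tab <- do.call(rbind, rows)
  tab$rel_recruitment <- NA_real_
  if (include_deterministic) {
    det <- tab[is.na(tab$alpha), ]
    key <- paste(tab$strategy, tab$b_s)
    base <- det$recruits_mean[match(key, paste(det$strategy, det$b_s))]
    tab$rel_recruitment <- mapply(relative_recruitment, tab$recruits_mean,
                                  base)
  }
  class(tab) <- c("scenario_table", "data.frame")
  tab
}

#' Recruitment relative to the deterministic-food baseline
#'
#' @param stochastic_mean mean recruits per female in a stochastic cell.
#' @param deterministic_mean mean recruits in the matched deterministic
#'   cell (same strategy and `b_s`).
#' @return Their ratio, or `NA` when the baseline is 0 (flagged missing
#'   rather than an error).
#' @export
relative_recruitment <- function(stochastic_mean, deterministic_mean) {
  if (!length(deterministic_mean) || is.na(deterministic_mean) ||
      deterministic_mean == 0)
    return(NA_real_)
  stochastic_mean / deterministic_mean
}
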