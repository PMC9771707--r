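#' Seasonal decline of offspring recruitment
#'
#' The probability that a hatchling recruits falls linearly with its hatch
#' date: it is `f_max` up to the anchor day `b_ref` (the earliest spring
#' onset considered) and reaches 0 at the season end `T_end`, the last date
#' by which young can develop before autumn migration.
#'
#' @param params a [model_params()] object (`b_ref`, `T_end`, `f_max`), or
#'   pass the three fields directly.
#' @return A `recruitment_schedule` object.
#' @export
recruitment_schedule <- function(params = model_params()) {
  s <- list(b_ref = params$b_ref, T_end = params$T_end, f_max = params$f_max)
  stopifnot(s$b_ref < s$T_end, s$f_max > 0, s$f_max <= 1)
  class(s) <- "recruitment_schedule"
  s
}

#' Recruitment probability of an offspring hatched on day t
#'
#' Linear decline clamped to \[0, `f_max`\]: `f(t) = f_max` for
#' `t <= b_ref`, 0 for `t >= T_end`, linear in between.
#'
#' @param t hatch day (integer day of year; vectorized).
#' @param sched a [recruitment_schedule()].
#' @return Recruitment probability in \[0, `f_max`\].
#' @export
recruitment_probability <- function(t, sched) {
  f <- sched$f_max * (sched$T_end - t) / (sched$T_end - sched$b_ref)
  pmin(pmax(f, 0), sched$f_max)
}

#' Expected recruits from starting incubation
#'
#' Terminal payoff of the incubate action: a female that starts incubating
#' `n` eggs on day `t` hatches them on `t + i_hatch` and expects
#' `n * f(t + i_hatch)` recruits. Incubation is only available in the
#' window `b_s <= t <= T_end - I` (the clutch must be incubated for `I`
#' days within the season); outside it the payoff is `-Inf` so the action
#' drops out of the Bellman maximum.
#'
#' @param t day incubation starts (vectorized).
#' @param n clutch size (eggs), `0 <= n <= n_max`.
#' @param params a [model_params()] object.
#' @param sched a [recruitment_schedule()].
#' @return Expected number of recruits, or `-Inf` where unavailable.
#' @export
incubation_payoff <- function(t, n, params, sched) {
  if (any(n < 0) || any(n > params$n_max))
    stop("clutch size must be between 0 and n_max")
  pay <- n * recruitment_probability(t + params$i_hatch, sched)
  pay[t < params$b_s | t > params$T_end - params$I] <- -Inf
  pay
}
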