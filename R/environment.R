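#' Discretize the stochastic daily food gain
#'
#' The net daily food gain of a foraging female takes one of `k` values
#' `w_i` with probabilities `p_i`. The probabilities are bin masses of a
#' symmetric beta(`alpha`, `alpha`) distribution over `k` equal-width bins
#' of \[0, 1\]; the gains are the bin midpoints rescaled to the interval
#' \[`x1 * w_a`, `x2 * w_a`\]. A final constant shift (numerically
#' negligible for the symmetric beta) pins the probability-weighted mean to
#' exactly `w_a`, so stochastic and deterministic scenarios share the same
#' average gain. Larger `alpha` means a narrower distribution; the variance
#' of the continuous parent is `((x2 - x1) * w_a)^2 / (4 * (2 * alpha + 1))`.
#'
#' @param alpha positive shape parameter (both shapes of the beta are equal,
#'   keeping the distribution symmetric about `w_a`).
#' @param params a [model_params()] object supplying `w_a`, `x1`, `x2`, `k`.
#' @return A `food_gain_distribution`: list with `support` (g/day), `probs`,
#'   `mean`, `variance` and the `alpha` used (`NA` for the deterministic
#'   baseline).
#' @examples
#' d <- discretize_food_gain(3, model_params())
#' sum(d$probs * d$support)  # 15 g/day exactly
#' @seealso [deterministic_food_gain()], [sample_daily_gain()]
#' @export
discretize_food_gain <- function(alpha, params) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0)
    stop("alpha must be a positive number")
  if (params$k < 2) stop("k must be at least 2")
  k <- params$k
  breaks <- seq(0, 1, length.out = k + 1)
  probs <- diff(stats::pbeta(breaks, alpha, alpha))
  probs <- probs / sum(probs)
  mid <- (breaks[-1] + breaks[-(k + 1)]) / 2
  support <- (params$x1 + (params$x2 - params$x1) * mid) * params$w_a
  support <- support + (params$w_a - sum(probs * support))
  new_food_gain_distribution(support, probs, alpha)
}

#' Deterministic food-gain baseline
#'
#' Single-atom distribution: every foraging day yields exactly `w_a` grams.
#' This is the constant-food reference against which the fitness of the
#' stochastic scenarios is expressed.
#'
#' @inheritParams discretize_food_gain
#' @return A degenerate `food_gain_distribution`.
#' @export
deterministic_food_gain <- function(params) {
  new_food_gain_distribution(params$w_a, 1, NA_real_)
}

#' Construct a food-gain distribution from explicit outcomes
#'
#' Mostly useful for small hand-built instances; the model's own
#' distributions come from [discretize_food_gain()] and
#' [deterministic_food_gain()].
#'
#' @param support daily net gains `w_i` (g/day).
#' @param probs matching probabilities `p_i` (must sum to 1).
#' @return A `food_gain_distribution`.
#' @export
food_gain_distribution <- function(support, probs) {
  new_food_gain_distribution(support, probs, NA_real_)
}

new_food_gain_distribution <- function(support, probs, alpha) {
  stopifnot(length(support) == length(probs), all(probs >= 0),
            abs(sum(probs) - 1) < 1e-12)
  m <- sum(probs * support)
  structure(list(support = support, probs = probs, mean = m,
                 variance = sum(probs * (support - m)^2), alpha = alpha),
            class = "food_gain_distribution")
}

#' @export
print.food_gain_distribution <- function(x, ...) {
  cat(sprintf(
    "Daily food gain: %d outcome(s)%s, mean %.4g g/day, sd %.4g g/day\n",
    length(x$support),
    if (is.na(x$alpha)) " (deterministic)" else sprintf(" (alpha = %g)", x$alpha),
    x$mean, sqrt(x$variance)))
  invisible(x)
}

#' Convert a food-gain distribution to a data frame
#'
#' @param x a `food_gain_distribution`.
#' @param ... unused.
#' @return Data frame with columns `i`, `w_i` (g/day), `p_i`.
#' @export
as.data.frame.food_gain_distribution <- function(x, ...) {
  data.frame(i = seq_along(x$support), w_i = x$support, p_i = x$probs)
}

#' Draw daily net food gains
#'
#' Samples outcomes `w_i` with probabilities `p_i` by inverting the
#' cumulative distribution over uniform draws, so two distributions sampled
#' from the same uniform stream are comonotone (a lucky day is lucky in
#' every scenario). This is what couples scenarios that differ only in
#' `alpha` in the sweep.
#'
#' @param dist a `food_gain_distribution`.
#' @param n number of draws.
#' @param u optional vector of `n` uniforms in \[0, 1); drawn from the
#'   current RNG if omitted.
#' @return Numeric vector of daily gains (g/day).
#' @export
sample_daily_gain <- function(dist, n = 1, u = NULL) {
  if (is.null(u)) u <- stats::runif(n)
  dist$support[findInterval(u, cumsum(dist$probs)) + 1L]
}

#' Simulate the arrival days of a cohort
#'
#' Arrival days are Normal(`D_a`, `SD_a`) rounded to the nearest integer
#' day and clamped to \[1, `T_end`\]. The spread in arrival dates is what
#' generates variation in body condition at spring onset: all females
#' arrive lean (reserves `S_min` = 0) but early arrivals get more
#' pre-breeding foraging days.
#'
#' @param params a [model_params()] object (`D_a`, `SD_a`, `N_pop`, `T_end`).
#' @param seed optional integer; when given, draws use an isolated RNG
#'   stream so the cohort is reproducible and independent of downstream
#'   simulation randomness.
#' @return Integer vector of `N_pop` arrival days.
#' @export
sample_arrival_days <- function(params, seed = NULL) {
  draw <- function() {
    d <- round(stats::rnorm(params$N_pop, params$D_a, params$SD_a))
    as.integer(pmin(pmax(d, 1), params$T_end))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
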