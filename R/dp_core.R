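#' Linear interpolation of a value slice in reserves
#'
#' Reserves are continuous but the value function is stored on a uniform
#' grid; values between nodes are linearly interpolated and queries outside
#' \[0, S_max\] are clamped to the boundary (a bird cannot hold negative
#' reserves nor store beyond its cap). The same interpolation is used in
#' the backward induction and in the forward simulation.
#'
#' @param values numeric vector of values on the grid nodes.
#' @param S reserve levels to evaluate (g; vectorized).
#' @param S_grid uniform grid of reserve nodes starting at 0.
#' @return Interpolated values, exact at nodes.
#' @export
interpolate_value <- function(values, S, S_grid) {
  nS <- length(S_grid)
  dS <- S_grid[2] - S_grid[1]
  pos <- pmin(pmax(S, 0), S_grid[nS]) / dS
  lo <- pmin(floor(pos), nS - 2)      # keep a right bracket at the cap
  fr <- pos - lo
  values[lo + 1L] * (1 - fr) + values[lo + 2L] * fr
}

# Interpolation bracket for a set of target reserve levels, precomputed as
# index/weight triples so the backward loop is pure arithmetic.
interp_brackets <- function(S_target, S_grid) {
  nS <- length(S_grid)
  dS <- S_grid[2] - S_grid[1]
  pos <- pmin(pmax(S_target, 0), S_grid[nS]) / dS
  lo <- pmin(floor(pos), nS - 2)
  list(lo = as.integer(lo) + 1L, hi = as.integer(lo) + 2L, fr = pos - lo)
}

action_levels <- c("none", "forage", "lay", "incubate")

#' Optimal state-dependent breeding policy by backward induction
#'
#' Solves the Bellman recursion for the expected number of recruits
#' `V(S, t, n)` over reserves `S`, day `t` and eggs laid `n`, for either
#' breeding strategy. Each day a female takes exactly one action:
#'
#' * **forage** — reserves move to `min(max(S + w_i, 0), S_max)` with
#'   probability `p_i`; available to capital breeders only before the first
#'   egg (`n = 0`) and to income breeders at any `n < n_max`.
#' * **lay** — available from `b_s` on while `S >= c*E` and `n < n_max`;
#'   costs `c*E` grams (egg material plus prepaid incubation surcharge) and
#'   increments the clutch.
#' * **incubate** — terminal; available for `n >= 1` in
#'   `b_s <= t <= T_end - I`, paying `n * f(t + i_hatch)` expected
#'   recruits.
#'
#' At `n = n_max` incubation is forced (wherever available). The two
#' strategies also differ in the reserve cap: capital breeders store up to
#' `S_max_capital`, income breeders only one egg's cost (`c*E`). Exact ties
#' are resolved incubate > lay > forage, so under indifference reproduction
#' happens as early as possible. States where no action is feasible are
#' absorbing failures with value 0.
#'
#' @param params a [model_params()] object.
#' @param dist a [discretize_food_gain()] or [deterministic_food_gain()]
#'   distribution.
#' @param sched a [recruitment_schedule()]; defaults to the one implied by
#'   `params`.
#' @param strategy `"capital"` or `"income"`.
#' @return A `breeding_policy` object: list with the value array `V` and
#'   action array `action` (`nodes x days x clutch`, actions coded
#'   none/forage/lay/incubate), the reserve grid `S_grid`, and the
#'   `params`, `sched`, `dist` and `strategy` it was built from.
#' @examples
#' p <- model_params(N_pop = 100)
#' pol <- optimize_policy(p, deterministic_food_gain(p), strategy = "income")
#' pol$V[1, p$D_a, 1]  # expected recruits of a lean female present on day D_a
#' @export
optimize_policy <- function(params, dist, sched = recruitment_schedule(params),
                            strategy = c("capital", "income")) {
  strategy <- match.arg(strategy)
  cE <- params$c * params$E
  S_max <- if (strategy == "capital") params$S_max_capital else cE
  if (cE > S_max + 1e-9)
    stop("reserve cap below the cost of one egg: no clutch is feasible")
  if (abs(S_max / params$dS - round(S_max / params$dS)) > 1e-9)
    stop("dS must divide the reserve cap so the grid ends exactly at S_max")
  S_grid <- seq(0, S_max, by = params$dS)
  nS <- length(S_grid)
  Tn <- params$T_end
  nN <- params$n_max + 1L

  # forage transition: bracket of min(max(S_j + w_i, 0), S_max), nS x k
  k <- length(dist$support)
  targ <- outer(S_grid, dist$support, "+")
  fb <- interp_brackets(targ, S_grid)
  LO <- matrix(fb$lo, nS, k); HI <- matrix(fb$hi, nS, k)
  FR <- matrix(fb$fr, nS, k)
  # lay transition: bracket of S - cE, plus feasibility by reserves
  lb <- interp_brackets(S_grid - cE, S_grid)
  can_lay_S <- S_grid >= cE - 1e-9

  V <- array(0, dim = c(nS, Tn, nN))
  act <- array(0L, dim = c(nS, Tn, nN))
  p_i <- dist$probs
  inc_window <- function(t) t >= params$b_s && t <= Tn - params$I

  for (t in (Tn - 1L):1L) {
    for (ni in seq_len(nN)) {
      n <- ni - 1L
      q_inc <- if (n >= 1L && inc_window(t))
        n * recruitment_probability(t + params$i_hatch, sched) else -Inf
      if (n < params$n_max && t >= params$b_s) {
        vn <- V[, t + 1L, ni + 1L]
        q_lay <- vn[lb$lo] * (1 - lb$fr) + vn[lb$hi] * lb$fr
        q_lay[!can_lay_S] <- -Inf
      } else q_lay <- rep(-Inf, nS)
      forage_ok <- if (strategy == "capital") n == 0L else n < params$n_max
      if (forage_ok) {
        vf <- V[, t + 1L, ni]
        q_for <- (matrix(vf[LO], nS, k) * (1 - FR) +
                  matrix(vf[HI], nS, k) * FR) %*% p_i
        q_for <- as.vector(q_for)
      } else q_for <- rep(-Inf, nS)

      best <- pmax(q_inc, q_lay, q_for)
      a <- integer(nS)                      # none
      a[is.finite(best) & q_for >= best] <- 1L
      a[is.finite(best) & q_lay >= best] <- 2L
      a[is.finite(best) & q_inc >= best] <- 3L
      V[, t, ni] <- ifelse(is.finite(best), best, 0)
      act[, t, ni] <- a
    }
  }

  structure(list(strategy = strategy, V = V, action = act, S_grid = S_grid,
                 S_max = S_max, params = params, sched = sched, dist = dist),
            class = "breeding_policy")
}

#' @export
print.breeding_policy <- function(x, ...) {
  cat(sprintf(
    "Optimal %s-breeding policy: %d reserve nodes x %d days x clutch 0..%d\n",
    x$strategy, length(x$S_grid), x$params$T_end, x$params$n_max))
  cat(sprintf("  b_s = %d, reserve cap %g g, food gain%s\n",
              x$params$b_s, x$S_max,
              if (is.na(x$dist$alpha)) " deterministic"
              else sprintf(" alpha = %g", x$dist$alpha)))
  invisible(x)
}

#' Export a policy's value function and actions as a long data frame
#'
#' @param policy a `breeding_policy`.
#' @param days optional subset of days to export (default all).
#' @return Data frame with columns `strategy`, `S`, `t`, `n`, `V`, `action`.
#' @export
policy_to_df <- function(policy, days = seq_len(policy$params$T_end)) {
  g <- expand.grid(S = policy$S_grid, t = as.integer(days),
                   n = 0:policy$params$n_max)
  idx <- cbind(match(g$S, policy$S_grid), g$t, g$n + 1L)
  data.frame(strategy = policy$strategy, g,
             V = policy$V[idx],
             action = action_levels[policy$action[idx] + 1L])
}

#' Exhaustive-enumeration value oracle for tiny instances
#'
#' Computes the maximal expected number of recruits from state
#' `(S0, t0, n0)` by recursively enumerating every feasible action sequence
#' and taking exact expectations over the foraging outcomes — no reserve
#' grid and no interpolation. Intended as an independent check of
#' [optimize_policy()] on instances small enough to enumerate; refuses
#' larger ones.
#'
#' @inheritParams optimize_policy
#' @param S0,t0,n0 starting reserves (g), day and eggs laid.
#' @return Maximal expected recruits (a single number).
#' @export
brute_force_value <- function(params, dist, sched = recruitment_schedule(params),
                              strategy = c("capital", "income"),
                              S0 = 0, t0 = 1, n0 = 0) {
  strategy <- match.arg(strategy)
  if (params$T_end > 14 || length(dist$support) > 3 || params$n_max > 4)
    stop("instance too large to enumerate exhaustively")
  cE <- params$c * params$E
  S_max <- if (strategy == "capital") params$S_max_capital else cE
  memo <- new.env(parent = emptyenv())
  value <- function(S, t, n) {
    key <- sprintf("%.9g_%d_%d", S, t, n)
    if (!is.null(memo[[key]])) return(memo[[key]])
    cand <- numeric(0)
    if (n >= 1 && t >= params$b_s && t <= params$T_end - params$I)
      cand <- c(cand, n * recruitment_probability(t + params$i_hatch, sched))
    if (t < params$T_end) {
      if (n < params$n_max && t >= params$b_s && S >= cE - 1e-9)
        cand <- c(cand, value(S - cE, t + 1L, n + 1L))
      forage_ok <- if (strategy == "capital") n == 0 else n < params$n_max
      if (forage_ok)
        cand <- c(cand, sum(dist$probs * vapply(
          pmin(pmax(S + dist$support, 0), S_max),
          function(s2) value(s2, t + 1L, n), numeric(1))))
    }
    v <- if (length(cand)) max(cand) else 0
    memo[[key]] <- v
    v
  }
  value(S0, as.integer(t0), as.integer(n0))
}
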