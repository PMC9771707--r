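#' Simulate a cohort of females following the optimal policy
#'
#' Each female arrives lean (`S = 0`) on her arrival day and on every
#' subsequent day evaluates the feasible actions at her current continuous
#' reserve level — using the same linear interpolation of the value table
#' as the backward induction — and takes the best one (ties resolved
#' incubate > lay > forage, as in [optimize_policy()]). Foraging days draw
#' an independent gain from the policy's food distribution; laying costs
#' `c*E`; incubation is terminal and yields `n * f(hatch day)` recruits.
#' Females that never incubate end the season with 0 recruits.
#'
#' Daily foraging luck is sampled by inverse CDF from a pregenerated
#' female-by-day uniform matrix, so runs with the same seed and cohort are
#' coupled across food distributions (used for common-random-number
#' comparisons along the variance axis).
#'
#' @param policy a `breeding_policy` from [optimize_policy()]; supplies the
#'   parameters, schedule and food distribution it was built with.
#' @param arrival_days integer vector of arrival days (one female each),
#'   e.g. from [sample_arrival_days()].
#' @param seed optional integer seed for the foraging uniforms (isolated
#'   from the caller's RNG state).
#' @param record if `TRUE`, also return per-day reserve and action
#'   matrices (memory ~ `N * T_end`; meant for diagnostics at small `N`).
#' @return A data frame of class `female_outcomes`, one row per female:
#'   `arrival`, `t_first_egg`, `t_incubation`, `clutch`, `t_hatch`,
#'   `recruits`, `s_peak` (highest reserves held, g). With `record = TRUE`
#'   the matrices are attached as attributes `reserves` and `actions`
#'   (rows = females, columns = days).
#' @export
simulate_population <- function(policy, arrival_days, seed = NULL,
                                record = FALSE) {
  p <- policy$params
  sched <- policy$sched
  dist <- policy$dist
  N <- length(arrival_days)
  Tn <- p$T_end
  cE <- p$c * p$E
  stopifnot(all(arrival_days >= 1), all(arrival_days <= Tn))

  draw_u <- function() matrix(stats::runif(N * Tn), N, Tn)
  U <- if (is.null(seed)) draw_u() else withr::with_seed(seed, draw_u())
  cum_p <- cumsum(dist$probs)

  S <- numeric(N); n <- integer(N); done <- logical(N)
  t_first <- rep(NA_integer_, N); t_inc <- rep(NA_integer_, N)
  t_hatch <- rep(NA_integer_, N); recruits <- numeric(N); s_peak <- numeric(N)
  if (record) {
    res_mat <- matrix(NA_real_, N, Tn)
    act_mat <- matrix(NA_integer_, N, Tn)
  }

  for (t in seq(min(arrival_days), Tn)) {
    active <- which(!done & arrival_days <= t)
    if (!length(active)) next
    act_t <- integer(length(active))    # none
    q_best <- rep(-Inf, length(active))
    q_lay_a <- rep(-Inf, length(active))
    q_for_a <- rep(-Inf, length(active))
    q_inc_a <- rep(-Inf, length(active))

    for (nv in unique(n[active])) {
      g <- which(n[active] == nv)
      ga <- active[g]
      if (nv >= 1L && t >= p$b_s && t <= Tn - p$I)
        q_inc_a[g] <- nv * recruitment_probability(t + p$i_hatch, sched)
      if (t < Tn) {
        if (nv < p$n_max && t >= p$b_s) {
          q <- interpolate_value(policy$V[, t + 1L, nv + 2L],
                                 S[ga] - cE, policy$S_grid)
          q[S[ga] < cE - 1e-9] <- -Inf
          q_lay_a[g] <- q
        }
        forage_ok <- if (policy$strategy == "capital") nv == 0L
                     else nv < p$n_max
        if (forage_ok) {
          vf <- policy$V[, t + 1L, nv + 1L]
          qf <- 0
          for (i in seq_along(dist$support))
            qf <- qf + dist$probs[i] *
              interpolate_value(vf, S[ga] + dist$support[i], policy$S_grid)
          q_for_a[g] <- qf
        }
      }
    }
    q_best <- pmax(q_inc_a, q_lay_a, q_for_a)
    ok <- is.finite(q_best)
    act_t[ok & q_for_a >= q_best] <- 1L
    act_t[ok & q_lay_a >= q_best] <- 2L
    act_t[ok & q_inc_a >= q_best] <- 3L

    inc <- active[act_t == 3L]
    if (length(inc)) {
      done[inc] <- TRUE
      t_inc[inc] <- t
      t_hatch[inc] <- t + p$i_hatch
      recruits[inc] <- n[inc] * recruitment_probability(t + p$i_hatch, sched)
    }
    lay <- active[act_t == 2L]
    if (length(lay)) {
      S[lay] <- S[lay] - cE
      t_first[lay] <- ifelse(is.na(t_first[lay]), t, t_first[lay])
      n[lay] <- n[lay] + 1L
    }
    fo <- active[act_t == 1L]
    if (length(fo)) {
      w <- dist$support[findInterval(U[cbind(fo, t)], cum_p) + 1L]
      S[fo] <- pmin(pmax(S[fo] + w, 0), policy$S_max)
      s_peak[fo] <- pmax(s_peak[fo], S[fo])
    }
    done[active[act_t == 0L]] <- TRUE    # no feasible action: failed breeder
    if (record) {
      res_mat[cbind(active, t)] <- S[active]
      act_mat[cbind(active, t)] <- act_t
    }
  }

  out <- data.frame(arrival = as.integer(arrival_days),
                    t_first_egg = t_first, t_incubation = t_inc,
                    clutch = n, t_hatch = t_hatch, recruits = recruits,
                    s_peak = s_peak)
  class(out) <- c("female_outcomes", "data.frame")
  if (record) {
    attr(out, "reserves") <- res_mat
    attr(out, "actions") <- act_mat
  }
  out
}

#' Simulate a single female (with full trajectory)
#'
#' Convenience wrapper around [simulate_population()] for one female with
#' recording enabled; useful for inspecting example reserve trajectories.
#'
#' @inheritParams simulate_population
#' @param arrival arrival day of the female.
#' @return A one-row `female_outcomes` data frame with `reserves` and
#'   `actions` attributes (1 x `T_end` matrices).
#' @export
simulate_female <- function(policy, arrival, seed = NULL) {
  simulate_population(policy, arrival, seed = seed, record = TRUE)
}

#' Population summary of simulated breeding outcomes
#'
#' Means are taken over all simulated females except where noted: nesting
#' onset (reported relative to the first possible breeding day `b_s`) is
#' averaged over females that laid at least one egg, and the recruitment
#' probability at hatching over females that incubated. Mean recruits per
#' female counts failed breeders as 0. Each mean carries its Monte-Carlo
#' standard error.
#'
#' @param outcomes a `female_outcomes` data frame.
#' @param params the [model_params()] the simulation was run under.
#' @return One-row data frame: `n_females`, `onset_rel_bs` (+`onset_se`),
#'   `clutch_mean` (+`clutch_se`), `clutch_max`, `recruit_prob`,
#'   `recruits_mean` (+`recruits_se`), `recruits_var`, `frac_failed`.
#' @export
summarize_population <- function(outcomes, params) {
  if (!nrow(outcomes)) stop("no simulated females to summarize")
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  nested <- !is.na(outcomes$t_first_egg)
  hatched <- !is.na(outcomes$t_hatch)
  onset <- outcomes$t_first_egg[nested] - params$b_s
  fprob <- if (any(hatched))
    recruitment_probability(outcomes$t_hatch[hatched],
                            recruitment_schedule(params)) else NA_real_
  data.frame(
    n_females = nrow(outcomes),
    onset_rel_bs = if (any(nested)) mean(onset) else NA_real_,
    onset_se = if (any(nested)) se(onset) else NA_real_,
    clutch_mean = mean(outcomes$clutch),
    clutch_se = se(outcomes$clutch),
    clutch_max = max(outcomes$clutch),
    recruit_prob = mean(fprob),
    recruits_mean = mean(outcomes$recruits),
    recruits_se = se(outcomes$recruits),
    recruits_var = stats::var(outcomes$recruits),
    frac_failed = mean(!hatched))
}
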