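---
title: "A dynamic state variable model of capital and income breeding under stochastic food gain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dynamic state variable model of capital and income breeding under stochastic food gain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the model

Migratory birds that produce a single clutch per year face a seasonal race:
arriving females must convert food into eggs and incubate them early enough
for the young to develop before autumn. Strategies differ in how
reproduction is financed. A *capital* breeder (common-eider-like) stores
large reserves before nesting and stops foraging once laying starts; an
*income* breeder (king-eider-like) holds at most one egg's worth of
reserves and keeps foraging between laying days. `breedopt` asks how these
two designs fare when daily foraging success fluctuates stochastically and
when the onset of spring — the first possible breeding day `b_s` — moves.

The model is a dynamic state variable model solved by backward induction.
A female is described by her energy reserves `S` (g), the day `t` and the
number of eggs laid `n`. Each day she takes exactly one action:

* **forage**: `S` moves to `min(max(S + w, 0), S_max)` where the net daily
  gain `w` is drawn from a discrete distribution (below). Reserves cannot
  go negative — a bad day at empty reserves is simply lost — and cannot
  exceed the strategy's storage cap.
* **lay** (from `b_s` on, while `S >= cE` and `n < n_max`): one egg per
  day; each egg withdraws `cE` grams of reserves, the egg material `E`
  plus a prepaid 50% incubation surcharge (`c = 1.5`).
* **incubate** (from `b_s` to `T - I`): terminal. A clutch of `n` eggs
  started on day `t` hatches on `t + I` and yields `n * f(t + I)` expected
  recruits, where `f` is the seasonal recruitment decline.

Fitness is the expected number of recruits,

```
V(S, t, n) = max{ V_forage, V_lay, V_incubate },
```

with the forage option restricted to `n = 0` for capital breeders (laying
terminates foraging) and available at any `n < n_max` for income breeders;
at `n = n_max` incubation is forced. The storage cap is `S_max = 1155` g
for capital breeders (30% of lean mass, exactly a full clutch's cost
`n_max * cE`) and `S_max = cE = 165` g for income breeders. Recruitment
declines linearly, `f(t) = f_max * (T - t) / (T - b_ref)` clamped to
`[0, f_max]`, anchored at the earliest spring onset `b_ref` considered in
a sweep and hitting zero at the season end `T`.

The recursion runs from `V(., T, .) = 0` backwards; the induced policy is
then applied forward to a cohort of 10,000 females with Normal(90, 10)
arrival days (rounded to days, all arriving lean, `S = 0`), each
experiencing independent daily food draws.

## The stochastic food environment

Daily net gain takes one of `k = 20` values with probabilities from a
symmetric beta(α, α) distribution: the unit interval is cut into 20
equal-width bins, each bin's probability is its beta mass, and its gain is
the bin midpoint rescaled to `[x1 w_a, x2 w_a] = [-15, 45]` g/day. A final
constant shift (numerically negligible for a symmetric beta) pins the mean
to exactly `w_a = 15` g/day, so every environment — including the
single-atom constant-food baseline — offers the same average food and
differs only in variance. The variance of the continuous parent is
`(60 g)^2 / (4 (2α + 1))`; the discretization stays within 10% of it for
α ≤ 50 and is strictly decreasing in α. At α = 500 days are nearly
constant; at α = 0.1 they are close to a coin flip between losing 15 g and
gaining 45 g.

Alternative discretizations (conditional bin means, quantile atoms) were
considered; bin-midpoint masses are the simplest scheme that satisfies all
of the above and the choice does not affect any qualitative conclusion.

What the generator emulates: short-term weather-driven luck in diving
foraging, iid across days and females, with a hard floor at zero reserves.
What it does not: serial correlation in weather, depletion of food patches,
condition-dependent foraging skill, and any arrival–condition correlation
(all females arrive lean; variation in condition at `b_s` arises only from
arrival spread and foraging luck). Conclusions from passing tests
therefore speak to the consequences of *independent* daily variation, not
to autocorrelated food shortages.

## Parameters

| symbol | meaning | default | units |
|---|---|---|---|
| `E` | egg mass | 110 | g |
| `c` | reserve cost multiplier per egg | 1.5 | — |
| `n_max` | maximal clutch | 7 | eggs |
| `I` = `i_hatch` | incubation; laying-end to hatch | 26 | d |
| `w_a` | mean net daily gain | 15 | g/d |
| `x1`, `x2` | gain bounds (× `w_a`) | −1, 3 | — |
| `k` | foraging outcome types | 20 | — |
| `alpha` | beta shape (= both shapes) | sweep | — |
| `b_s` | first possible breeding day | sweep (100–150) | d |
| `b_ref` | recruitment anchor (earliest `b_s`) | 100 | d |
| `T_end` | season end, `f = 0` | 200 | d |
| `M_L` | lean mass | 3850 | g |
| `S_max_capital` | capital storage cap | 1155 (= 0.3 `M_L`) | g |
| `D_a`, `SD_a` | arrival mean, SD | 90, 10 | d |
| `N_pop` | cohort size | 10,000 | — |
| `dS` | reserve grid step | 1 | g |

The egg economics, foraging bounds, incubation length, arrival
distribution and cohort size describe a large Arctic sea duck. The
seasonal clock (`T_end`, `b_ref`) and lean mass are not independently
measured quantities; they were fixed once, before any sweep was run, by
two regime requirements that define the comparison the model is built for:
at the earliest spring onset a constant-food forager should afford a
moderate clutch (3–4 eggs) from pre-breeding foraging, leaving headroom to
`n_max` for lucky foragers, while at the latest onsets most females should
approach the storage cap before breeding opens. With `w_a = 15` g/day and
eggs costing 165 g (11 foraging days each), `T_end = 200` and
`b_ref = 100` place the sweep `b_s ∈ {100, …, 150}` across exactly that
transition. The variance axis `alpha ∈ {500, 50, 10, 3, 1, 0.5, 0.1}`
spans near-constant to strongly bimodal daily gain; the low-alpha end is
essential, because the fitness consequences of storage only separate the
strategies once daily outcomes are strongly dispersed.

## Numerical choices

* **Reserve grid and interpolation.** Reserves are continuous; values are
  stored on a 1-g grid and linearly interpolated (in `S` only — `t` and
  `n` are exact indices), with queries clamped to `[0, S_max]`. The value
  function is step-like in `S` where an extra egg becomes affordable, so a
  coarse grid systematically overestimates values near those kinks; at 1 g
  the backward values agree with what the simulated policy actually
  achieves to within Monte-Carlo error (asserted by the test suite), and a
  full backward induction still takes well under a second.
* **Forward decisions.** Simulated females re-evaluate the interpolated
  action values at their current continuous reserves rather than looking
  up the nearest node's stored action, matching the backward induction's
  treatment of off-grid states.
* **Tie-breaking.** Exact ties resolve incubate > lay > forage: under a
  non-increasing `f`, reproducing earlier is weakly better, and a fixed
  order prevents policy churn between adjacent days. Incubation requires
  `n ≥ 1`; a zero-egg "incubation" would be a failed breeder either way
  and is excluded so the tie-break cannot park females on it.
* **Infeasible actions** are excluded from the maximum (not clamped to 0);
  states with no feasible action are absorbing failures with `V = 0`.
* **Mean pinning.** The discretized gain mean is shifted to `w_a` exactly
  so deterministic and stochastic scenarios share the average food budget;
  without it the relative-recruitment ratios would confound variance with
  a (tiny) mean offset.
* **Degenerate inputs.** `dS` must divide the cap so the grid ends exactly
  at `S_max`; a cap below one egg's cost is refused; a cap below
  `n_max * cE` only warns (a full clutch then being unattainable is a
  legitimate, if odd, configuration).

## Randomness and coupling

One master seed drives everything. Arrival cohorts derive their stream
from (seed, `b_s`) and daily foraging luck from (seed, strategy, `b_s`) —
deliberately *not* from `alpha`. Gains are sampled by inverse CDF over a
pregenerated female-by-day uniform matrix, so scenarios along the variance
axis see the same cohort and comonotone daily luck (a lucky day is lucky
in every environment). This common-random-numbers coupling stabilizes the
ratios against the constant-food baseline far beyond what 10,000
independent females would give. Scenario summaries carry Monte-Carlo
standard errors for every mean.

## Model behaviour

Under constant food, income breeders lay as soon as they can afford an
egg — nesting tracks `b_s` within a day for on-time arrivals — and their
clutch shrinks as spring onset moves later. Capital breeders postpone
nesting after early spring onsets to keep foraging (the earlier `b_s`,
the longer the delay), and lay *larger* clutches in later springs, when
the long pre-breeding season has filled their stores. Fluctuating food
always costs income breeders recruits and inflates the spread in
recruitment among females; capital breeders, in contrast, gain from
strong fluctuations when spring onset is early (lucky foragers convert
windfalls into large early clutches; unlucky ones keep foraging under the
protection of the zero floor) and lose when it is late (stores are near
the cap, so fluctuations have downside only). All of these statements are
asserted quantitatively by the test suite and recomputed by the analysis
scripts; `analysis/04_scenario_sweep.R` writes the full scenario table.

## Problem sizes

The default lattice is 1156 reserve nodes × 200 days × 8 clutch states
(capital; 166 nodes for income) with 20 foraging outcomes, solved in
about half a second. The shipped analysis sweep runs 96 scenarios of
10,000 females in a few minutes on one core. The test suite exercises the
same code on 4,000-female sweeps over `b_s ∈ {100, 130, 150}` and a
compact variance axis, plus 10,000-female runs for the policy-achievement
checks, and validates the optimizer exactly against exhaustive enumeration
on a 6-day toy season small enough to enumerate every action sequence.

## Limitations

* One clutch per season; no re-nesting after failure, no adult mortality,
  no predation, no density dependence.
* Day is the atomic time step; one action per day. Income breeders
  "forage during laying" by alternating days, so their minimal inter-egg
  interval is set by `cE / w_a` rather than by physiology.
* The incubation surcharge is prepaid at laying (`cE` per egg); there is
  no separate reserve requirement or drain during incubation, and no
  metabolic drain on non-foraging days (maintenance is folded into the
  *net* gain `w`).
* Recruitment declines linearly and deterministically with hatch date;
  no year effects, no stochastic recruitment.
* The seasonal constants are regime-defining choices, not estimates;
  quantitative outputs (e.g. recruits per female) should be read as
  model-relative quantities, with only their comparative patterns
  interpretable.
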