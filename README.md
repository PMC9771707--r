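# breedopt

Optimal breeding phenology for capital and income breeding birds under
stochastically fluctuating food gain.

Many migratory birds produce a single clutch per year under a hard
seasonal deadline: offspring hatched late have little chance to recruit.
Strategies for financing that clutch differ. *Capital breeders* (e.g.
common eiders) store large energy reserves before nesting and stop
foraging once the first egg is laid; *income breeders* (e.g. king eiders)
hold at most one egg's worth of reserves and forage between laying days.
`breedopt` is for behavioural and life-history ecologists who want to ask
how these designs respond — in nesting onset, clutch size and
recruitment — when the onset of spring shifts and when daily foraging
success becomes uncertain.

## The model

A female is described by reserves *S* (g), day *t* and eggs laid *n*.
Each day she forages, lays or incubates; fitness is the expected number
of recruits

V(S, t, n) = max{ V_forage, V_lay, V_incubate }

with

* V_forage(S, t, n) = Σᵢ pᵢ V(min(max(S + wᵢ, 0), S_max), t+1, n) —
  capital breeders only while n = 0, income breeders at any n < n_max;
* V_lay(S, t, n) = V(S − cE, t+1, n+1) for S ≥ cE, t ≥ b_s (one 110-g egg
  per day, costing cE = 165 g of reserves: material plus a prepaid 50%
  incubation surcharge);
* V_incubate(t, n) = n · f(t + I) for b_s ≤ t ≤ T − I (terminal; I = 26
  days of incubation), where f declines linearly from the earliest spring
  onset b_ref to zero at the season end T.

Daily net gain wᵢ takes one of k = 20 values on [−15, 45] g/day weighted
by a symmetric beta(α, α): mean fixed at 15 g/day, variance set by α.
Storage caps: S_max = 1155 g (30% of lean mass; exactly a 7-egg clutch)
for capital, S_max = cE for income breeders. The Bellman recursion is
solved backward on a 1-g reserve lattice with linear interpolation; a
cohort of 10,000 females (arrival ~ Normal(90, 10), arriving lean) is
then simulated forward under the induced policy, and scenario sweeps
cross both strategies with spring-onset dates b_s and food-gain variance.

## Worked example

Compare capital breeders between constant food and strongly fluctuating
food (α = 0.1) at an early (day 100) and a late (day 150) spring onset:

```r
library(breedopt)
p <- model_params(N_pop = 2000)
res <- run_sweep("capital", b_s_values = c(100, 150), alphas = 0.1,
                 params = p, seed = 1)
res[, c("strategy", "b_s", "alpha", "onset_rel_bs", "clutch_mean",
        "recruits_mean", "recruits_var", "rel_recruitment")]
```

```
  strategy b_s alpha onset_rel_bs clutch_mean recruits_mean recruits_var
1  capital 100    NA       28.297        3.45         1.470       0.1284
2  capital 150    NA        0.282        5.19         0.953       0.0153
3  capital 100   0.1       29.204        3.52         1.483       0.2532
4  capital 150   0.1        0.365        5.04         0.926       0.0336
  rel_recruitment
1           1.000
2           1.000
3           1.008
4           0.972
```

Reading the rows: after an early spring onset (b_s = 100) capital
breeders keep foraging for ~28 days past b_s and lay ~3.5 eggs; after a
late onset (150) they nest almost immediately with larger clutches
(~5.2 eggs) because the long pre-breeding season filled their stores, but
earn fewer recruits (0.95 vs 1.47) since their young hatch close to the
season's end. Strong food fluctuations (α = 0.1 rows) raise mean
recruitment above the constant-food baseline in the early spring
(`rel_recruitment` = 1.008 > 1: lucky foragers convert windfalls into
large early clutches, while the zero-reserve floor shields the unlucky)
but depress it after a late spring (0.972 < 1: stores are near the cap,
so fluctuations only have downside). Income breeders, simulated the same
way with `run_sweep("income", ...)`, lose recruitment in *every*
fluctuating cell — they have no reserve buffer to exploit.

The `analysis/` scripts run the full study: food environments (`01`),
optimal policies (`02`), cohort simulation (`03`), the 96-scenario sweep
(`04`, a few minutes; writes `results/scenario_table.csv`) and figures
(`05`).

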