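# amews

Agent-based early-warning simulation of household food security and child
acute malnutrition.

Sentinel nutrition surveillance in arid and semi-arid lands tracks small
fixed panels of households (30 per site, monthly) and screens children by
mid-upper arm circumference (MUAC); ward-level prevalence is classified on
the five-phase IPC acute-malnutrition scale. `amews` is for modellers and
early-warning analysts who want a *mechanistic* counterpart to the usual
correlational forecasts: it simulates the households themselves and
reproduces exactly the ward-month statistics surveillance yields, so the
model can be calibrated on them, validated out of sample, and interrogated
with counterfactual shock scenarios.

## The model in brief

Each household holds a set of livelihood strategies
*s* = (own production, local networks, buy/barter), weights on the
2-simplex. Every month it selects a strategy in proportion to smoothed past
performance, realises per-child nutrition

&nbsp;&nbsp;&nbsp;&nbsp;*n*<sub>s</sub> = ( Σ<sub>d</sub> *s*<sub>d</sub> ·
*h*<sub>s,d</sub> · *x*<sub>d</sub> / *c* ) · *h*<sub>p</sub> · *h*<sub>a</sub>,

where *h*<sub>s</sub> is its capability profile, *x* the ward-month
effectiveness factors derived from NDVI anomalies and staple-price
deviations, *c* its number of children, and *h*<sub>p</sub>, *h*<sub>a</sub>
multiplicative health and asset factors. The household is *insufficient*
when *n*<sub>s</sub> < *n*<sub>0</sub>, acutely malnourished after *K*
consecutive insufficient months, and — only when insufficient — adapts by
hill climbing: with learning rate *λ* it copies the strategy of the
best-performing geographic neighbour, and with a spawn rate it mutates its
active strategy. Ward prevalence is the children-weighted share of
malnourished households, classified into IPC phases; validation uses macro
F1, Hamming loss, RMSD (proportion scale) and the joint rule
F1 > 0.5 ∧ RMSD < 0.2. See `vignette("amews-model")` for the full account.

## Worked example

Generate a synthetic sentinel world with known truth (λ\* = 0.05,
*n*<sub>0</sub> = 0.04), calibrate the learning rate on the "observed"
prevalence it emits, and compare a combined climate + economic shock
against baseline:

```r
library(amews)

cfg <- generator_config(n_wards = 3, months = 24, seed = 2024)
gt  <- generate_ground_truth(cfg)
head(gt$observed, 4)
#>   ward_id   month prevalence_pct ipc_phase
#> 1     W01 2017-01       0.000000         1
#> 2     W01 2017-02       5.882353         2
#> 3     W01 2017-03       5.882353         2
#> 4     W01 2017-04       5.882353         2

cal <- calibrate(gt$observed,
                 list(households = gt$households, stressors = gt$stressors),
                 calibration_grid(lambda = c(0.03, 0.05, 0.07), replicates = 5),
                 seed = 7, base_params = sim_params(n_0 = 0.04))
cal
#> <amews_calibration> best lambda=0.05 spawn=0.05 n_0=0.04
#> Validation report (54 ward-months)
#>   macro F1     0.494   (valid if > 0.5)
#>   Hamming loss 0.296
#>   RMSD         0.0429  (valid if < 0.2, proportion scale)
#>   jointly valid: no
```

The grid search lands on the generating λ; the replicate-mean trajectory
deviates from the single observed realisation by 4.3 prevalence points
RMSD (well under the 0.2 validity cut-off), while the macro F1 of 0.49
reflects how easily 30-household ward-months hop IPC phase boundaries.

```r
tr <- run_counterfactuals(cal$best_params,
        list(households = gt$households, stressors = gt$stressors),
        list(build_scenario("baseline"), build_scenario("combined")),
        replicates = 10, seed = 99)
sm  <- summarize_counterfactuals(tr)
win <- tail(sort(unique(sm$month)), 4)          # the 4-month forecast window
aggregate(mean_pct ~ scenario, sm[sm$month %in% win, ], mean)
#>            scenario mean_pct
#> 1 baseline_baseline 20.29998
#> 2 combined_baseline 41.15439
```

A combined shock — own-production food −20%, household income −50% over
the final four months — roughly doubles mean prevalence in the forecast
window relative to the paired baseline runs.

A command-line wrapper with `synth`, `simulate`, `calibrate`,
`split-eval`, `forecast`, `scenario` and `score` subcommands is installed
at `exec/amews` (see `run_cli()`); every run writes a manifest with seed,
config hash and input checksums.

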