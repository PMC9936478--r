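---
title: "The amews household model: mechanics, calibration and scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The amews household model: mechanics, calibration and scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amews)
```

## The problem

Child acute malnutrition (wasting) in arid and semi-arid lands is monitored
through sentinel surveillance: small fixed panels of households — typically
30 per site — visited monthly, with child nutrition screened by mid-upper
arm circumference (MUAC). Ward-level prevalence from such panels feeds the
five-phase IPC acute-malnutrition (AMN) scale that drives humanitarian
decisions. Correlational early-warning models predict prevalence at coarse
units and mask the household heterogeneity that determines who is actually
at risk. `amews` takes the complementary, mechanism-first route: it
simulates the households themselves — how they choose and adapt livelihood
strategies under climate and market stress — and aggregates the simulated
outcomes back to the ward-month statistics surveillance produces, so that
the model can be calibrated against, and validated on, exactly the data an
early-warning system has.

## The household model

**Actors and state.** Each household $i$ lives in a ward, at planar
coordinates used only to define its social neighbourhood. It carries

* a capability profile $h_s \in [0,1]^3$ over the three food-access
  dimensions *(own production, local networks, buy/barter)* — whether the
  household is actually able to grow food, draw on kin and community, or
  earn and trade;
* a health factor $h_p \in [0,1]$ and an asset factor $h_a \in [0,1]$,
  both acting multiplicatively (the sicker the child or the thinner the
  assets, the larger the reduction);
* $c_i \ge 1$ children;
* a strategy set $S_i$: up to `max_size` strategy vectors
  $s \in \Delta^2$ (non-negative weights over the three dimensions summing
  to 1), each with a smoothed performance memory.

**External conditions.** Every ward-month has an effectiveness vector
$x \in (0,1]^3$. Below-baseline vegetation (drought) reduces the
own-production component; above-baseline staple prices reduce the
buy/barter component (see *Stressors* below). Counterfactual shocks
compose multiplicatively onto $x$.

**The monthly round.** Households update once per month, in a freshly
shuffled random order. Household $i$:

1. **selects** a strategy from $S_i$ with probability proportional to
   `memory + epsilon * mean(memory)`; the floor `epsilon` keeps a residual
   exploration probability, and an all-zero memory falls back to a uniform
   draw;
2. **acts**: per-child food availability is
   $f = \sum_d s_d\, h_{s,d}\, x_d \,/\, c_i$, normalised so a fully
   capable, unshocked, single-child household on any pure strategy attains
   1; realised nutrition is $n_s = f\, h_p\, h_a$, and the round is
   *sufficient* when $n_s \ge n_0$;
3. **records**: the selected strategy's memory moves by an exponential
   moving average with weight `ema_alpha` toward the realised $n_s$; the
   household is acutely malnourished ($w = 1$) after $K$ consecutive
   insufficient rounds;
4. **adapts** (only if this round was insufficient — sufficiency removes
   the motive): with probability $\lambda$ it looks at its
   `neighborhood_k` nearest same-ward households and copies the strategy
   most recently used by the neighbour with the highest last realised
   $n_s$, provided that value strictly exceeds its own (ties broken
   uniformly); the copied strategy enters the set with its memory seeded
   at the observed neighbour performance and becomes active. Copying is
   deliberately independent of the household's own $h_s$ — imitation does
   not check transferability, which is how maladaptive copying can occur.
   Independently, with probability `spawn_rate`, the household mutates its
   active strategy (Gaussian perturbation of the weights with scale
   `spawn_scale`, truncated at zero and renormalised) and appends it; if
   the set exceeds `max_size`, the lowest-memory strategy is evicted.

Ward-month prevalence is the children-weighted share of households with
$w=1$: $W = 100 \cdot \sum_{i \in \text{ward}} c_i w_i / \sum c_i$.
Weighting by children keeps the simulated statistic aligned with
child-level MUAC prevalence; the alternative reading — each child as a
separate agent — collapses to the same statistic when siblings share the
household outcome, which is what the per-child division assumes.

### Parameters

| Parameter | Default | Units / range | Role |
|---|---|---|---|
| `lambda` | 0.05 | probability/round, calibration box [0.01, 0.1] | imitation (hill-climbing) rate; the main calibrated quantity |
| `spawn_rate` | 0.05 | probability/round, box [0.01, 0.1] | novel-strategy generation rate |
| `n_0` | 0.5 | normalised food/child | sufficiency threshold; calibratable. On real data its scale is set by the survey normalisation; the synthetic world uses 0.04 (below) |
| `K` | 2 | rounds | "sustained" insufficiency window defining acute malnutrition; the smallest plural reading of consecutive, configurable |
| `neighborhood_k` | 8 | households | nearest same-ward households visible for imitation |
| `epsilon` | 0.05 | — | selection floor; keeps exploration alive |
| `ema_alpha` | 0.3 | — | memory smoothing; ~3-round half-life |
| `memory_prior` | 0 | — | common initial memory. Zero makes the first selection uniform and lets observed performance dominate immediately; any optimistic prior would out-rank a copied neighbour strategy (whose memory is seeded with a realised, hence smaller, $n_s$) and silently disable imitation |
| `max_size` | 8 | strategies | set cap with lowest-memory eviction |
| `spawn_scale` | 0.1 | weight units | mutation spread |

The strategy catalog is the simplex grid with step 0.25 (15 strategies);
livelihood-zone masks can remove locally implausible combinations (e.g.
high own-production weights in purely pastoral drylands). When the
(possibly masked) catalog exceeds `max_size`, each household holds a
uniform random subset, which also makes sets household-specific; the
initial active strategy is a uniform draw either way. One global RNG
stream, seeded once per run, drives everything, so identical inputs,
parameters and seed give bit-identical trajectories.

## Stressors

Raw series are *deviations from long-term ward baselines*, converted to
factors by two deliberately simple, monotone, capped forms:

* climate: $z = (\mathrm{NDVI} - \mu_{lt})/\sigma_{lt}$, factor
  $\mathrm{clip}(1 + \beta_c \min(z, 0),\ \text{floor},\ 1)$ — greener
  than usual never helps beyond 1;
* market: $r = (p - p_{10yr})/p_{10yr}$, factor
  $\mathrm{clip}(1 - \beta_m \max(r, 0),\ \text{floor},\ 1)$ — cheap food
  never helps beyond 1.

Defaults $\beta_c = 0.25$, $\beta_m = 0.5$, floors 0.1 (a floor prevents a
data artefact from annihilating a dimension). The climate factor acts on
own production, the market factor on buy/barter, local networks carry no
exogenous stressor; the mapping is configurable. These functional forms
are the package's own: the choice is constrained by monotonicity in
severity, identity at zero deviation, and interpretability of the slope
(effectiveness lost per z-unit or per unit relative price deviation), not
by a published curve.

## Validation metrics and calibration

Predicted and observed ward-month prevalence are compared after mapping to
IPC AMN phases (default GAM bands 5/10/15/30%, configurable — published
threshold dialects differ):

* **macro F1** — unweighted mean over phases of the per-class balanced
  precision/recall mean. Classes absent from both vectors are dropped; a
  class with no true positives and no predictions contributes 0 (matching
  the common `zero_division = 0` convention, so external cross-checks can
  be configured identically);
* **Hamming loss** — misclassified fraction;
* **RMSD** on the *proportion* scale (0.10, not 10) — the scale on which
  the joint-validity cut-off is defined;
* **joint validity** — strict `F1 > 0.5` and strict `RMSD < 0.2`.

Calibration is a grid search over the box $[0.01, 0.1]^2$ for
$(\lambda, \text{spawn})$, optionally $n_0$: each cell runs `replicates`
simulations with a common replicate seed set (common random numbers, so
cells are compared under matched noise), discards a 6-month burn-in (the
malnutrition state needs history before it is meaningful), and is scored
by the RMSD of the *replicate-mean* trajectory against the observations,
with mean macro F1 breaking ties. Scoring the replicate mean, rather than
averaging single-replicate RMSDs, matters: a single run carries the full
simulation noise in every cell, which is flat in $\lambda$ and drowns the
systematic component the objective is meant to measure; the mean
trajectory shrinks that noise roughly as $1/R$. Grid search rather than
gradients because the simulator is stochastic and the plausible parameter
ranges are small boxes.

Out-of-sample machinery follows surveillance practice: a **temporal
split** calibrates on everything before a cut month and scores the
subsequent year with frozen parameters; **leading-edge** evaluation tiles
the post-training months into consecutive non-overlapping windows of 2 or
4 months, re-calibrating before each window on everything observed so far
and pooling per-ward-month forecast errors — 12 test months at horizon 4
give exactly the three windows January–April, May–August,
September–December.

## Counterfactual scenarios

Scenario presets cross a shock with an adaptive-capacity setting:

* *climate* — early lean-season onset: own-production food reduced by 20%
  (dimension multiplier 0.8, composed onto whatever the observed stressor
  factors already are);
* *economic* — pandemic-style restrictions: household income generation
  halved. This targets the asset factor $h_a$ (the wording is about
  income, not food-market functioning); a configuration toggle can
  instead hit the buy/barter dimension;
* *combined* — both;
* adaptation *constrained* / *baseline* / *enabled* — the calibrated
  $\lambda$ scaled by 0.5 / 1 / 1.5. The scaled value is not clipped to
  the calibration box; leaving the box is reported, not hidden.

All modifiers switch on at the start of the forecast window (default: the
final 4 months of the simulated span). Replicate $r$ of every scenario
shares a seed, so the baseline preset reproduces the plain simulation
bit-for-bit and scenario contrasts are paired. Summaries report the
replicate mean with a 2.5–97.5 percentile interval.

## The synthetic sentinel world

`generator_config()` emulates the *structure* of sentinel surveillance
with known ground truth: wards with livelihood-zone capability archetypes,
30-household site panels placed around site centres (so the neighbourhood
graph has real geometry), assets from a rich/poor Beta mixture
(Beta(5,2) with weight 0.4 vs Beta(2,5) with weight 0.6), health
Beta(18,2), child counts truncated-Poisson(2) on 1–6, seasonal NDVI and
drifting prices around constant ward baselines, and a scheduled shock
calendar.

Defaults were chosen once, as the study conditions, with three aims —
realistic prevalence magnitudes, multi-phase IPC variation, and episodes
in which adaptation genuinely matters:

* **truth `n_0 = 0.04`**: because food is divided per child, any
  threshold above $1/6$ would make six-child families structurally
  malnourished whatever they do; 0.04 puts a well-matched strategy within
  reach of large families while a shocked, mismatched one fails, and
  yields ~9–12% baseline ward prevalence with drought excursions across
  phases — the magnitude range of ASAL GAM surveillance;
* **overlapping capability archetypes** (pastoral (0.85, 0.75, 0.6),
  agro-pastoral (0.8, 0.75, 0.7), mixed (0.7, 0.75, 0.85), spread 0.1):
  strategy switching must be materially possible. With strongly
  specialised profiles a copied strategy is useless to the copier —
  adoption ignores own $h_s$ — and the learning rate has no leverage at
  all;
* **two 6-month −3z droughts and a 3-month +80% price spike** in 24
  months: the consecutive-failed-rains pattern of recent East African
  droughts, and recurring episodes in which strategy adaptation is
  exercised.

What the generator does **not** emulate: MUAC measurement error, survey
non-response or panel attrition, migration, cross-ward interaction,
conflict, or geographic realism beyond ward labels and planar
coordinates. Tests passing on this world therefore demonstrate the
mechanics and statistics of the pipeline — determinism, schema fidelity,
metric correctness, shock monotonicity, adaptation benefit — not that the
behavioural model is true of any real population.

## Numerical choices and degenerate inputs

Strategy weights are validated to sum to 1 within $10^{-9}$ and
duplicates are detected component-wise at the same tolerance. Shock
composition is exact to $10^{-12}$. A sufficiency history shorter than
$K$ counts missing leading rounds as sufficient. An empty neighbourhood
(singleton wards) silently disables the imitation branch, never the spawn
branch. A degenerate all-zero spawn perturbation falls back to the
uniform strategy. If eviction would remove the strategy just adopted (it
can, when its seeded memory is the set minimum), the household keeps the
best remaining strategy active. Prevalence on a phase boundary classifies
into the higher phase.

## Known limitations

* **$\lambda$ is weakly identified at sentinel scale.** In every world
  configuration we examined, the derivative of mean prevalence with
  respect to $\lambda$ is of the order of 0.1 percentage points per 0.01
  of $\lambda$, while a single realisation of a 30-household ward-month
  carries percentage-point-scale noise. Two mechanism features cap the
  leverage of imitation: households re-select from their whole set every
  round, so escape from a failing strategy already happens through the
  selection floor and memory decay regardless of $\lambda$; and the
  copy-gate compares raw $n_s$ across households, confounding strategy
  quality with the neighbour's own $h_p h_a / c$. Grid calibration
  therefore localises $\lambda$ only to a few grid steps on data of NDMA
  scale (5 wards, 24 months); the packaged recovery experiment measures
  exactly this, and we report the result rather than resize the
  experiment until it flatters the method.
* Validation experiments in the test suite run at deliberately small
  problem sizes (2–5 wards, 12–24 months, 1–20 replicates), the package's
  choice for routine checking; the machinery itself has no such limits.
* The economic scenario's income interpretation, the IPC threshold
  dialect, and the stressor-to-factor slopes are configurable assumptions,
  not estimates.
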