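---
title: "Multi-criteria drug prioritization with a hybrid PSO-EAVOA optimizer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-criteria drug prioritization with a hybrid PSO-EAVOA optimizer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugsel)
```

## The problem

Patient-generated drug reviews carry three complementary signals about a
drug: how well it worked (the user rating), how badly it was tolerated
(the side-effect description) and how much evidence backs either claim
(the number of reviews). `drugsel` frames drug prioritization as a
constrained combinatorial problem: from a table of `D` drugs, choose a
subset `x = (d_1, ..., d_k)` of exactly `k` distinct drugs maximizing

```
f(x) = alpha * mean(rating_norm)  -  beta * mean(severity_norm)
       + gamma * mean(reviews_norm)
```

with all three criteria min-max scaled to [0, 1] and non-negative weights
(defaults `alpha = 0.5, beta = 0.3, gamma = 0.2`). The search space of
`choose(D, k)` subsets is explored by population metaheuristics; a
brute-force enumerator provides ground truth on small instances.

Because every criterion is a mean over the selected drugs, the fitness of
a subset equals the mean of a *per-drug* composite score, so the global
optimum is always the top-`k` drugs by that score. This makes planted
synthetic instances exactly verifiable, while the optimizers themselves
never exploit the separability — they treat `f` as a black box, as they
must on objectives where criteria interact.

## Preprocessing

`prepare_drug_table()` chains three steps:

1. **Loading** (`read_drug_table()`): rows missing the drug name, rating
   or review count are dropped (the count is kept as metadata); nominal
   fields (condition, drug class) are label-encoded in first-appearance
   order, which makes codes reproducible without any external ordering.
2. **Severity scoring** (`compute_severity()`): side-effect text is
   lower-cased, stripped of punctuation and lemmatized by a small
   rule-based de-pluralizer (its behaviour is frozen by golden-file
   tests). Each record's severity is the frequency-weighted mean lexicon
   weight `S = sum_j w_j f_j / sum_j f_j`. The shipped lexicon is a
   ~40-term three-tier toy (mild = 1, moderate = 2, severe = 3) standing
   in for licensed clinical terminologies; any two-column TSV can replace
   it via `read_lexicon()`. Out-of-lexicon tokens take the lexicon's
   `default_weight` (1) and count in the denominator, so unknown terms
   dilute rather than inflate severity. A `token_count` metric is
   available for the alternative reading of "side-effect length" as the
   number of reported keywords; the severity reading is the default
   because it is the quantity the scoring model is built around.
3. **Normalization** (`normalize_features()`): min-max scaling per
   feature; a degenerate feature (max = min) maps to 0 everywhere.
   Normalization statistics are stored on the table, and re-applying
   stored statistics is exactly idempotent. All three criteria are
   normalized — including review counts, whose raw scale (1 to
   thousands) would otherwise dominate the objective.

Indices are 1-based throughout, the natural convention in R; a selection
is feasible iff it holds exactly `k` distinct integers in `[1, D]`.

## Constraints and penalties

Infeasible candidates are never fatal. `selection_fitness()` counts
violations — wrong length or out-of-bounds indices (`P_equality`, with
out-of-bounds indices clamped for the component means) and duplicates
(`P_uniqueness`) — and reports

```
f_pen(x) = f(x) - lambda1 * P_equality - lambda2 * P_uniqueness .
```

Penalties are *subtracted* in this maximization problem so that a
violation always hurts; with criteria bounded by 1 the unit defaults
`lambda1 = lambda2 = 1` make any violation dominate any possible
criterion gain. In practice the optimizers never produce infeasible
candidates: every continuous position is decoded by
`repair_selection()` — round to the nearest integer, clamp to `[1, D]`,
then replace duplicates (left-to-right) with uniformly random unused
indices — which is the identity on feasible integer positions and always
yields a feasible subset. Whether out-of-bounds coordinates should be
clamped, resampled or penalized is genuinely open; clamp-then-count was
chosen because it keeps decoding deterministic given the RNG stream and
never discards the feasible part of a position.

## The optimizers

All three optimizers share the continuous-encode/repair-decode contract,
draw every random number from one seeded session RNG (a run is a pure
function of table, settings and seed), and record the best-so-far
fitness each iteration, so convergence curves are non-decreasing by
construction.

**PSO** (`pso_run()`) is the canonical baseline: inertia decaying
linearly 0.9 to 0.4, constant `c1 = c2 = 2` (standard values; the
baseline is deliberately vanilla), velocity attraction towards the
personal and global bests.

**EAVOA** (`eavoa_run()`) drives each particle by a starvation rate
`F = (2 rand + 1) z (1 - t/T) + dt`, `z ~ U(-1, 1)`, with trend
`dt = h (sin(pi t / 2T) + cos(pi t / 2T) - 1)` (`h = 0.5`; `sinpi`/
`cospi` keep the endpoints exactly zero). Large `|F| >= 1` triggers the
exploration move — a stochastic jump toward a leader, or a uniform
random point, each with probability 0.5; `0.5 <= |F| < 1` the
accumulation move (SAM); `|F| < 0.5` the rotating spiral flight (RFS).
Both exploitation operators generate two candidates and keep the fitter
(greedy). Leaders are drawn from the best three by fitness-proportional
shares after shifting the three values to be non-negative — better
leaders lead more often, and equal fitness degenerates to 1/3 each; the
inverse-fitness transcription is kept behind `weighting = "inverse"`.
Three numerical choices deserve a note. The spiral trig argument is the
elementwise product `2 * P * R` clipped to ±10π before the trig call
(unclipped products of large indices would alias meaninglessly); a
`trig = "uniform"` variant using `2 pi u` is provided. The ± sign of
each spiral candidate is drawn uniformly per candidate. And the SAM
correction `C_m = BV_m - (BV_m * x) / ((BV_m - x)^2 + eps) * F` uses
`eps = 1e-12` for near-zero displacements, with exactly-zero
displacement coordinates contributing no correction at all — this keeps
a fully converged swarm (all elites equal to the particle) a true fixed
point instead of diverging by `BV^2 / eps`; the uncorrected asymmetric
transcription is available as `sam_form = "literal"`.

**Hybrid** (`hybrid_run()`) is the core method. Initialization is
opposition-based: `pop` uniform positions plus their coordinate mirrors
`(D + 1) - x`, all `2 pop` evaluated, best `pop` kept. Each iteration
then applies exactly one phase branch per particle:

* **early** (`t <= 0.4 T`): with probability 0.5 a PSO-style velocity
  update in which the personal best is replaced by a vulture leader
  drawn from the swarm's personal-best pool (`c1 = 2.5 - 2 t/T` decaying,
  `c2 = 0.5 + 2 t/T` growing, inertia 0.9 to 0.4); otherwise integer
  noise in [-5, 5] per gene;
* **balanced** (`0.4 T < t <= 0.7 T`): contraction towards the global
  best, `x <- x + 0.7 (gbest - x) + (2 - 2 t/T) * perturb`, with integer
  perturbations in [-3, 3] drawn per gene;
* **late** (`t > 0.7 T`): with probability 0.5 two random genes are
  overwritten by the corresponding global-best genes, otherwise the
  position takes a Levy perturbation.

Every 20th iteration all particles get an extra Levy mutation
(Mantegna construction, `beta = 1.5`, unit scale: `u / |v|^(1/beta)`
with `u ~ N(0, sigma_u^2)`, `sigma_u ~= 0.6966`); a particle that has
not improved its personal best for 6 iterations is reinitialized
uniformly at random; after the particle loop the worst particle is
replaced by the global best and the top-2 elite snapshots are re-inserted
over the worst remaining slots if their scores would otherwise be lost.
Elites plus best-so-far bookkeeping make the global best monotone.

Two control-flow details are under-determined in the published
pseudocode and were fixed here: the Levy perturbation in the late phase
is the *alternative* to the gene swap (a dangling `else` otherwise), and
the mid-phase perturbation is drawn per gene rather than once per
particle (per-gene noise is what keeps duplicate genes from moving in
lock-step). The "vulture population" feeding the early-phase leader is
the swarm itself ranked by personal-best score — no second population is
maintained anywhere in the printed procedure.

The per-iteration cost is exactly `pop` fitness evaluations (the
branches never evaluate extra candidates), so total work is
`O(pop * T * D)`; the evaluation counters in every `swarm_run` let tests
assert this as an exact counting contract rather than a wall-clock
claim.

## Synthetic data

`generate_drug_table()` emulates the drug-review schema with known
ground truth: ratings as Beta(5, 2) scaled to [0, 10] (left-skewed, as
review sites are), review counts as negative binomial (size 2,
prob 0.1) — strongly over-dispersed, matching the orders-of-magnitude
spread of real review counts — and side-effect texts composed of actual
lexicon terms so severity has a known value. Planted instances make a
chosen subset strictly dominate every other record on each normalized
criterion by at least `dominance_margin` (default 0.2): planting is
construction-then-verification — generate, push the planted records to
the top of the rating/review ranges and mild-only side-effect terms,
normalize through the standard pipeline, check the margins, and retry
with boosted separation (up to 20 attempts) if violated. Strict
per-criterion dominance makes the planted subset the unique optimum for
*any* weights with `alpha, gamma > 0` and `beta >= 0`, which the test
suite verifies by enumeration. `generate_unplanted()` keeps the
marginals and drops the structure.

What the generator does **not** emulate: free-text side effects beyond
lexicon terms (no grammar, negation or misspellings), correlations
between rating and review count, condition-specific rating scales, or
missing data. Passing tests therefore demonstrate the optimization and
scoring machinery, not robustness to the messiness of scraped review
text.

## Benchmarking and sensitivity

`run_benchmark()` runs each algorithm over a common seed block and
reports mean, sample (n-1) standard deviation, max and a weighted
composite score `0.5 mean + 0.3 max + 0.2 (1 - std)`; algorithms are
ranked by that score (ties break alphabetically). The composite formula
is a package convention — reported league tables of this kind rarely
define theirs — and is configurable via `score_weights`.

The weight-sensitivity suite mirrors standard global-sensitivity
practice: `one_way_sweep()` varies one coefficient over [0, 1] with the
others at base values; `simplex_grid()` enumerates all unit-sum triples
at a given step (66 at step 0.1); `sobol_indices()` implements the
Saltelli A/B/AB_i estimators for first-order and total indices (the
analytic test `f = 2 alpha + beta` with variance shares 0.8/0.2/0 is the
frozen correctness anchor); and `kruskal_wallis()` is a hand-built
rank-based H with tie correction, cross-checked against
`stats::kruskal.test` to 1e-9 — the comparison of optimizer output
distributions is rank-based by default because final fitness values are
bounded and skewed. For Sobol on the real pipeline,
`hybrid_objective_fn()` folds optimizer noise into the objective by
fixing one seed per sample point (`n_rep` averages over seeds instead).

## Problem sizes and numerical choices

The shipped test and acceptance workloads use instances the enumeration
oracle can certify: the planted-small preset (D = 12, k = 3; 220
subsets) with population 20 over 200 iterations for hit-rate checks, and
the planted-medium preset (D = 60, k = 5) with population 30 over 500
iterations — the standard configuration for the benchmark league table —
across 20 common seeds. Larger tables (the unplanted preset has
D = 200) run through the same interfaces.

Other fixed choices: rounding uses R's `round()` (half-to-even);
feasibility is asserted on every decoded candidate; Levy and
perturbation moves clamp positions to `[1, D]` before repair;
brute-force ties break to the lexicographically smallest subset;
`sinpi`/`cospi` keep starvation endpoints exact; and every stochastic
draw of a run flows from `set.seed(seed)` in a fixed order, so two runs
with equal inputs are bit-identical.

## Limitations

* The weighted-sum scalarization cannot reach non-convex parts of the
  Pareto front; it is the modelling choice here, not a recommendation
  against multi-objective treatments.
* The severity lexicon is a toy; clinical use requires a curated
  terminology and the scores are only as good as its weights.
* On tables where `choose(D, k)` is small enough to enumerate, the
  metaheuristics are conveniences, not necessities; their value is on
  instances beyond the enumeration budget, where no optimality
  certificate exists.
* Mean-based criteria make the objective separable per drug; objectives
  with interactions (e.g. condition coverage or drug-drug interactions)
  would exercise the optimizers harder and are not modelled.

## A worked example

```{r, eval = FALSE}
gen <- generate_drug_table(synth_preset("planted-small", seed = 7))
tab <- prepare_drug_table(gen$table)
fit <- drug_select(tab, k = 3, algorithm = "hybrid",
                   pop = 20, iters = 200, seed = 1)
summary(fit)
plot(fit)

# certify against the enumeration oracle
brute_force_optimum(tab, 3)$selection
gen$ground_truth
```
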