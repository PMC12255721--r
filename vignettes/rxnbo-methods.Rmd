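---
title: "rxnbo: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rxnbo: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rxnbo` optimizes chemical reaction conditions over large discrete
combinatorial spaces with batched, multi-objective Bayesian optimization.
This vignette is the package's account of its science: the model and its
assumptions, every tunable default and why it is set where it is, what the
synthetic benchmark emulates (and what it cannot show about real
chemistry), and the numerical decisions a maintainer would want written
down.

## The optimization problem

A *condition* is one full assignment of reaction parameters — e.g. ligand,
precatalyst, base, solvent, co-solvent, temperature. The search space is
the Cartesian product of the per-parameter value lists, pruned by
feasibility rules; the two objectives (by convention area-percent yield and
area-percent selectivity, both in [0, 100]) are measured only in plates of
`q` wells (24/48/96), a few plates per campaign. Quality is judged by the
**hypervolume** dominated by the observed Pareto front relative to a
reference point, and in benchmarks by **hypervolume-%**: 100 ×
HV(front(found)) / HV(front(truth)).

## Search-space encoding

* Enumeration is lexicographic in parameter-definition order with stable
  0-based ids, so the same YAML file always produces the same pool and
  `run_mask` bookkeeping is reproducible.
* The temperature rule keeps a condition when its temperature is *less than
  or equal to* each in-scope solvent boiling point: "exceeds" is a strict
  comparison, so refluxing at the boiling point remains feasible. Which
  solvent-like parameters are in scope is configurable per space file —
  co-solvents with boiling points can be included or not; the package does
  not hard-code a choice.
* Featurization: one-hot columns for plain categoricals, descriptor vectors
  for parameters with descriptor tables, optionally PCA-reduced to the
  smallest number of components reaching an explained-variance threshold
  (`fit_pca_reduction`), and a single numeric column for temperature. PCA
  projections are fitted once on a parameter's *full* value table, not per
  iteration, so feature meanings stay fixed across a campaign.
* All columns are min-max scaled to [0, 1] **over the feasible pool** (not
  the unfiltered product): the surrogate should see the geometry of the
  candidates it can actually choose. Constant columns are dropped and
  recorded. Temperature shares the same [0, 1] scaling as every other
  column; the GP's per-dimension length scales are free to give it its own
  effective bandwidth, which makes a separate scaling convention
  unnecessary.

## Gaussian-process surrogates

Each objective gets an independent GP (multi-task models are out of scope):

* **Kernel**: Matérn-5/2 with automatic relevance determination (one length
  scale per encoded feature) — twice differentiable, the default choice of
  the field's Bayesian-optimization toolkits for this kind of landscape.
* **Normalization contract**: inputs live in the pool's [0, 1] cube;
  targets are standardized per objective (mean 0, sd 1) before fitting and
  every prediction is de-standardized back to AP units, variances by the
  squared scale.
* **Hyperparameters** are fitted by maximizing the log marginal likelihood
  with analytic gradients (L-BFGS-B, bounds in log space). Length scales
  are bounded to [0.05, 30]: the lower bound keeps the kernel from
  collapsing on one-hot geometry, where distinct candidates sit at distance
  √2 and a tiny length scale would make every candidate look independent.
  The noise variance has a floor of 10⁻⁴ (standardized units) — replicate
  wells on real plates scatter, and an exactly-zero noise estimate is
  numerically and scientifically implausible. Fitting restarts from one
  fixed default plus seed-derived random points (`n_restarts = 2` by
  default), so refitting with the same data and seed reproduces the same
  model bit-for-bit.
* **Replicates** stay as separate rows; the fitted noise term absorbs
  their scatter. Averaging them first would understate observation noise.
* **Degenerate inputs**: constant targets get unit scale (centering only),
  producing a flat posterior at the constant; near-singular kernel matrices
  receive escalating jitter from 10⁻⁸ up to a hard cap of 10⁻², beyond
  which fitting errors out rather than silently regularizing.
* **Joint sampling** factorizes the posterior covariance restricted to the
  requested ids (never the full pool × pool matrix). Id sets larger than
  `max_joint = 4096` are handled by an exactly-factorized random subset
  with conditional-marginal sampling for the remainder — a documented
  sketch, adequate because selection decisions only need faithful
  correlation against the data and pending picks, not among all 10⁵
  candidates at once.

## Acquisition strategies

All strategies operate on the un-run candidates only, break ties toward the
lowest pool id, and are deterministic given (model, pool, configuration,
seed).

* **Sobol initialization** draws scrambled Sobol points in the encoded
  feature cube and maps each to the nearest un-run candidate (Euclidean
  distance), skipping duplicates. Direction numbers are the standard
  Joe–Kuo table (up to 100 dimensions); scrambling is a seeded random
  digital shift, which preserves the sequence's equidistribution. Other
  scrambling variants exist; the digital shift was chosen for simplicity
  and exact reproducibility.
* **q-NEHVI**. For each slot, every candidate's expected hypervolume
  improvement is estimated by Monte Carlo over joint posterior samples that
  *include the observed conditions*, so the incumbent front is itself
  treated as a noisy realisation — re-evaluating noisy-but-promising
  regions costs acquisition value rather than being assumed known. The
  batch is built greedy-sequentially: the per-sample non-dominated
  staircases are updated incrementally with each pick's sampled values
  (cached box decompositions in the two-objective case are exactly these
  sorted staircases). The Monte-Carlo machinery draws the joint posterior
  at the observed locations once per iteration, then candidate values from
  the conditional posterior given those draws. Candidate-to-baseline and
  candidate-to-pending correlations are therefore exact; correlations
  *among* candidates are not materialised — they never enter a
  one-candidate-at-a-time greedy argmax — and a pending pick's fantasy
  values are its own already-drawn samples. `mc_samples = 128` by default;
  below 8 the estimator is unusable and the package warns.
* **q-NParEgo**. Each slot draws a weight vector from the unit simplex,
  floored at ε = 0.01 (a zero weight would let one objective vanish from
  the scalarization entirely) and renormalized. Objectives are normalized
  to [0, 1] by the observed per-objective range, frozen for the iteration;
  a degenerate range maps to constant 0.5 with a warning. The augmented
  Chebyshev scalarization s(ỹ) = minᵢ(wᵢỹᵢ) + ρ Σᵢ wᵢỹᵢ uses ρ = 0.05, the
  classic ParEGO convention. Candidates are scored by Monte-Carlo noisy
  expected improvement of s over the per-sample best of observed ∪ pending.
* **TS-HVI** draws `q` joint posterior realisations over the candidates;
  realisation *j* contributes the candidate maximizing hypervolume
  improvement of its sampled objective vector over the observed front. If a
  realisation sees zero improvement everywhere, the pick falls back to the
  maximal sampled objective sum and the fallback is recorded.
* **Utopia exploitation** ranks candidates by Euclidean distance of the
  posterior-mean vector to an ideal point, default (110, 110) AP — placed
  *outside* the attainable [0, 100]² square so that improving either
  objective always reduces the distance. No uncertainty term: this is the
  deliberately exploitative final-round strategy.
* **Reference point**: the paper-style hypervolume bookkeeping needs a
  point dominated by everything of interest. The package uses the
  componentwise minimum of the relevant set (ground truth for benchmark
  scoring, observations to date for within-campaign acquisition, frozen per
  iteration) minus 1 % of each objective's range — dominated by
  construction, comparable across algorithms sharing a dataset. Monte-Carlo
  samples that fall below the reference are clamped to it, contributing
  zero volume.

## Temperature-constrained batches

Heating decks hold few distinct temperatures, so batches may use at most
`k` unique levels. Two wrappers around any inner strategy:

* **naive** — run the inner strategy unrestricted; as soon as the picks
  span `k` distinct temperatures, restrict the remaining slots to those
  levels.
* **nested** — score every temperature level by the *mean single-point
  acquisition value* of its un-run candidates (levels with more than 5,000
  candidates are scored on a seeded random subsample of 5,000), keep the
  top `k`, then run the inner strategy on the restricted pool. With a Sobol
  inner strategy there are no acquisition values; `k` levels are chosen
  uniformly at random (seeded), which is also how constrained campaigns are
  initialized.

For the Utopia strategy under a constraint, the kept temperatures are those
of the top-ranked candidates, in rank order, until `k` distinct levels
appear — the exploitative analogue of the nested rule.

## The synthetic benchmark laboratory

Real benchmark campaigns in this field replay *emulated* datasets —
regressors trained on lab data, tabulated over an expanded grid. The
package supports exactly that (`train_emulator`, a deterministic
single-hidden-layer feed-forward regressor per objective, predictions
clamped to objective bounds). For a self-contained test bed that needs no
external data, `generate_synthetic_landscape` builds ground truth directly:

* per-categorical-value main effects (Gaussian, sd 1), sparse pairwise
  interactions (sd 0.5, 15 % density), a smooth quadratic response around a
  random optimal temperature (curvature 1.5 in scaled units), and two
  high-magnitude "cliff" interactions (+2.5) — the isolated optima that
  make reaction landscapes hard for grid intuition;
* latent fields standardized and squashed through a logistic map (gain 1.5)
  to [0, 100], matching the bounded, plateau-prone character of AP
  measurements;
* a second objective sharing the first's latent field with correlation
  −0.4, giving a genuine yield/selectivity trade-off and a true front of
  several points (the generator refuses landscapes whose exact front is
  smaller than `min_front_size = 3`);
* the default space — 7 ligands × 4 precatalysts × 4 bases × 5 solvents
  (boiling points 65–153 °C) × 5 temperatures (30–110 °C), 2,128 feasible
  conditions after the boiling-point rule — sized so a full repeated-seed
  study runs in minutes on one CPU while remaining far too large to
  exhaust in a campaign (120 of 2,128 wells ≈ 5.6 %). Effect scales were
  chosen once so that model-guided selection separates measurably from a
  quasi-random baseline across 20 seeds, which is the property the harness
  exists to detect.

Observation noise is independent Gaussian per objective, clamped to the
objective bounds (a 95-AP truth observed with +10 noise reads 100, never
105). The optimizer only ever sees noisy values; hypervolume-% is always
computed from the noise-free truth of the selected conditions — the
benchmark asks "what did you actually find", not "what did you think you
found".

What passing these benchmarks does *not* show: the synthetic landscape has
exchangeable categorical labels, additive-plus-sparse-interaction
structure, homoscedastic noise and no plate/batch effects, drift, or
failed-well censoring. Results on it demonstrate the optimizer's mechanics,
not chemistry-specific performance.

## Problem sizes in the test suite

The repeated-seed studies in the acceptance tests use the field's standard
protocol — batch 24, 5 iterations, seeds 1–20 — on the default landscape;
the package's own scaled-down smoke protocol (batch 24, 3 iterations, 5
seeds) is what `scripts/acceptance.R` runs, chosen as the smallest study
that still exercises initialization, model-guided iterations, constraints
and noise together. Unit tests use 12–24-condition toy pools where every
selection can be checked against exhaustive enumeration.

## Known limitations

* Hypervolume is exact but exponential-ish in dimension beyond the 2-D
  sweep; intended for d ≤ 4 (the package's campaigns have 2 objectives).
* q-NEHVI and TS-HVI are implemented for exactly two objectives (the
  staircase decomposition); q-NParEgo and Utopia ranking accept any number.
* The GP kernel settings are the package's own general-purpose defaults;
  no claim of equivalence with any other toolkit's hyperpriors.
* Permutation importance (`feature_importance`) ranks feature influence on
  a random-forest fit; it is not a Shapley decomposition, though for the
  ranking use case the two typically agree on dominant features.
* No automatic stopping rule: campaigns end by operator decision
  (convergence, stagnation, or budget), as in practice.
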