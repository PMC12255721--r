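# rxnbo — batch multi-objective Bayesian optimization for reaction screening

Process chemists optimizing a new reaction face a discrete combinatorial
search space — ligands × precatalysts × bases × solvents × temperatures can
easily exceed 10⁵ candidate conditions — and a robotic
high-throughput-experimentation (HTE) platform that evaluates them only in
plates of 24/48/96 wells, a handful of iterations per campaign. Two
objectives (typically area-percent, "AP", yield and AP selectivity from
liquid chromatography, both in [0, 100]) usually trade off against each
other, so the goal is a good **Pareto front**, not a single optimum.

`rxnbo` implements the full closed-loop workflow for this setting:

- **Search spaces**: declare categorical/temperature parameters, filter
  infeasible conditions (e.g. reaction temperature above the solvent's
  boiling point, forbidden reagent combinations), and encode candidates as
  one-hot flags, DFT-descriptor vectors (optionally PCA-reduced to an
  explained-variance threshold), and a numeric temperature, min-max scaled
  to the unit cube.
- **Surrogates**: one independent Gaussian-process regressor per objective
  (Matérn-5/2 kernel with per-feature length scales, fitted by marginal
  likelihood), with posterior means, variances and joint posterior samples
  over the candidate pool.
- **Acquisition**: scrambled-Sobol initialization mapped onto the discrete
  pool, then scalable batch strategies — **q-NEHVI** (Monte-Carlo noisy
  expected hypervolume improvement with greedy-sequential batch
  construction), **q-NParEgo** (per-slot random-weight augmented Chebyshev
  scalarization, s(ỹ) = minᵢ wᵢỹᵢ + ρ Σᵢ wᵢỹᵢ, with noisy expected
  improvement), **TS-HVI** (Thompson draws, one hypervolume-improvement
  argmax per draw), and a purely exploitative **Utopia-point** ranking
  (distance of posterior means to an ideal point, default (110, 110) AP) for
  final rounds. `naive` and `nested` wrappers cap the number of unique
  temperatures per plate for decks with limited heating wells.
- **Benchmarking**: synthetic reaction landscapes with known exact Pareto
  fronts (categorical main effects, sparse interactions, smooth temperature
  response, isolated "reactivity cliffs"), emulator oracles trained on seed
  datasets, clamped Gaussian observation noise, and a repeated-seed harness
  reporting **hypervolume-%** — 100 × HV(front found) / HV(true front) —
  per iteration.
- **Campaigns**: a suggest → measure → ingest state machine with SURF-style
  (tab-separated reaction table) I/O, directory persistence, exact replay
  from a seed, and post-campaign permutation feature importance.

## Worked example

A simulated campaign on the default synthetic landscape (2128 feasible
conditions after the boiling-point filter of a 7 × 4 × 4 × 5 × 5 space),
batch size 24, five iterations, q-NEHVI after the Sobol plate:

```r
library(rxnbo)

oracle <- generate_synthetic_landscape(seed = 1)   # ground truth + pool
camp <- new_campaign(oracle$pool, c("AP_yield", "AP_selectivity"),
                     q = 24, strategy = "qnehvi", seed = 7)
res <- run_simulated_campaign(camp, oracle, n_iterations = 5)
res$trajectory
#>   iteration hv_percent
#> 1         1   78.23208
#> 2         2   92.06134
#> 3         3   93.53031
#> 4         4   96.83718
#> 5         5   98.85668
```

The trajectory is the fraction of the true front's hypervolume captured by
everything measured so far: the Sobol plate alone reaches 78 %, and four
model-guided plates (120 of 2128 conditions, ~5.6 % of the space) recover
98.9 %. The campaign's own observed front spans the yield/selectivity
trade-off:

```r
head(camp$Y[pareto_front(camp$Y), ], 4)
#>      AP_yield AP_selectivity
#> [1,]     97.8           10.2
#> [2,]     97.7           13.5
#> [3,]     96.4           28.2
#> [4,]     96.4           29.9
```

For a real campaign, replace the oracle by the lab: `suggest_next()` writes
a plate, `write_surf()` exports it for fill-in, `ingest_results()` reads
the measured table back, and `save_campaign()`/`load_campaign()` persist
the state between iterations. A thin command-line wrapper is provided in
`exec/rxnbo` (`space build`, `campaign init/suggest/ingest`, `bench run`,
`analyze importance`).

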