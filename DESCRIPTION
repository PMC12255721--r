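Package: rxnbo
Title: Batch Multi-Objective Bayesian Optimization for High-Throughput
    Reaction Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for optimizing chemical reaction conditions over large
    discrete combinatorial search spaces with batched, multi-objective
    Bayesian optimization. Provides search-space definition, enumeration,
    feasibility filtering (e.g. reaction temperature versus solvent boiling
    point) and featurization (one-hot, descriptor tables, PCA reduction);
    independent Gaussian-process surrogates with ARD Matern kernels;
    Pareto-front and exact hypervolume computations; scalable batch
    acquisition strategies (Sobol initialization, q-NEHVI, q-NParEgo,
    TS-HVI, Utopia-point exploitation) with naive and nested wrappers for
    plate-level temperature constraints; a synthetic-landscape and
    emulator benchmark harness with clamped Gaussian observation noise;
    and campaign orchestration with SURF-style tabular I/O and
    permutation-based feature-importance analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    nnet,
    ranger,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
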