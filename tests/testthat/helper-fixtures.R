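# Shared fixtures: all built in code, sized for fast unit tests.

# Minimal categorical space: 3 x 2 one-hot values + 3 temperatures.
toy_space <- function(temps = c(25, 60, 100), bp = NULL) {
  solvent <- param_def("solvent", "categorical", c("MeOH", "tol"),
                       boiling_points = bp)
  rules <- if (!is.null(bp)) list(rule_temperature_le_bp("solvent"))
           else list()
  search_space(list(
    param_def("base", "categorical", c("K3PO4", "KOtBu", "NaOtBu")),
    solvent,
    param_def("temperature", "temperature", temps)
  ), feasibility = rules)
}

toy_pool <- function(...) build_pool(toy_space(...))

# Small landscape for acquisition tests: 2 ligands x 3 bases x 2 temps.
tiny_space <- function() {
  search_space(list(
    param_def("ligand", "categorical", c("PPh3", "XPhos")),
    param_def("base", "categorical", c("B1", "B2", "B3")),
    param_def("temperature", "temperature", c(40, 80))
  ))
}

# Deterministic truth over an encoded pool: two objectives trading off
# along the ligand axis, with every parameter contributing (no ties).
tiny_truth <- function(pool) {
  x <- pool$X
  tc <- ncol(x)
  f1 <- 18 + 52 * x[, 1] + 11 * x[, tc] + 7 * x[, "base=B2"] +
    3 * x[, "base=B1"]
  f2 <- 88 - 46 * x[, 1] + 6 * x[, "base=B3"] + 2.5 * x[, "base=B1"] -
    3 * x[, tc]
  cbind(AP_yield = f1, AP_selectivity = f2)
}

# Fit a near-noiseless surrogate on every pool condition (low posterior
# variance everywhere) without marking anything as run.
saturated_model <- function(pool, truth, seed = 1L) {
  ids <- seq_len(nrow(pool$X)) - 1L
  fit_surrogate(pool, observation_set(ids, truth), seed = seed)
}

# O(n^2) reference implementation of Pareto extraction (maximization).
pareto_oracle <- function(Y) {
  n <- nrow(Y)
  keep <- vapply(seq_len(n), function(i) {
    !any(vapply(seq_len(n), function(j) {
      if (i == j) return(FALSE)
      all(Y[j, ] >= Y[i, ]) && any(Y[j, ] > Y[i, ])
    }, logical(1)))
  }, logical(1))
  which(keep)
}

# Monte-Carlo estimate of the dominated area (2-D, maximization).
hv2d_mc <- function(Y, ref, n = 200000L, seed = 42L) {
  set.seed(seed)
  hi <- apply(Y, 2L, max)
  u1 <- runif(n, ref[1], hi[1]); u2 <- runif(n, ref[2], hi[2])
  inside <- rep(FALSE, n)
  for (i in seq_len(nrow(Y)))
    inside <- inside | (u1 <= Y[i, 1] & u2 <= Y[i, 2])
  area_box <- prod(hi - ref)
  p <- mean(inside)
  list(est = p * area_box,
       se = sqrt(p * (1 - p) / n) * area_box)
}

default_oracle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_synthetic_landscape(seed = 1L)
    cache
  }
})
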