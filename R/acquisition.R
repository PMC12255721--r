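#' Acquisition configuration
#'
#' @param strategy one of `"sobol"`, `"qnehvi"`, `"qnparego"`, `"tshvi"`,
#'   `"utopia_exploit"`.
#' @param q batch size (wells per plate: typically 24, 48 or 96).
#' @param mc_samples Monte-Carlo samples for the noisy strategies.
#' @param rho augmented-Chebyshev scalarization weight (q-NParEgo).
#' @param utopia ideal objective vector for the exploitative final round,
#'   default `(110, 110)` AP.
#' @param seed RNG seed.
#' @export
acq_config <- function(strategy = c("sobol", "qnehvi", "qnparego", "tshvi",
                                    "utopia_exploit"),
                       q = 24L, mc_samples = 128L, rho = 0.05,
                       utopia = c(110, 110), seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(q >= 0, mc_samples >= 1, rho >= 0)
  list(strategy = strategy, q = as.integer(q),
       mc_samples = as.integer(mc_samples), rho = rho, utopia = utopia,
       seed = as.integer(seed))
}

#' Temperature (or other parameter) batch constraint
#'
#' Caps the number of unique values of one parameter within a batch —
#' typically the number of distinct reaction temperatures a robotic deck of
#' heating wells can hold.
#'
#' @param k maximum unique values per batch.
#' @param mode `"naive"` (restrict once the cap is first hit) or `"nested"`
#'   (pre-select the top-scoring k levels, then acquire within them).
#' @param parameter constrained parameter name; defaults to the space's
#'   temperature parameter.
#' @export
batch_constraint <- function(k, mode = c("nested", "naive"),
                             parameter = NULL) {
  mode <- match.arg(mode)
  stopifnot(k >= 1)
  structure(list(parameter = parameter, max_unique = as.integer(k),
                 mode = mode),
            class = "rxnbo_constraint")
}

.batch_selection <- function(ids, acq_values, strategy, info = list()) {
  structure(list(condition_ids = as.integer(ids),
                 acq_values = as.numeric(acq_values),
                 strategy = strategy, info = info),
            class = "rxnbo_batch")
}

#' @export
print.rxnbo_batch <- function(x, ...) {
  cat("rxnbo batch (", x$strategy, "): ", length(x$condition_ids),
      " conditions\n", sep = "")
  invisible(x)
}

.unrun_mask <- function(pool, allowed_ids = NULL) {
  mask <- !pool$run_mask
  if (!is.null(allowed_ids)) {
    keep <- rep(FALSE, nrow(pool$X))
    keep[.pool_rows(pool, allowed_ids)] <- TRUE
    mask <- mask & keep
  }
  mask
}

.constraint_values <- function(pool, constraint) {
  pn <- constraint$parameter %||% .temperature_param(pool$space)
  if (is.null(pn)) stop("no temperature parameter to constrain")
  pool$conditions[[pn]]
}

# Naive-mode hook: once the picks span k distinct levels, restrict the
# remaining slots to those levels. Returns the updated allowed mask.
.naive_update <- function(mask, picked_rows, levels, k) {
  seen <- unique(levels[picked_rows])
  if (length(seen) >= k) mask & (levels %in% seen) else mask
}

#' Sobol initialization batch
#'
#' Draws scrambled Sobol points in the encoded-feature unit hypercube and
#' maps each to the nearest un-run candidate by Euclidean distance, skipping
#' candidates already chosen; blocks of points are drawn until the batch is
#' filled. This spreads the first plate across the whole feasible space.
#'
#' @param pool a `rxnbo_pool`.
#' @param q batch size.
#' @param seed RNG seed.
#' @param allowed_temperatures optional numeric vector restricting the
#'   candidates' temperature levels (e.g. `c(70, 100)` for the first plate).
#' @param allowed_ids optional explicit candidate restriction (0-based ids).
#' @return a `rxnbo_batch`.
#' @export
sobol_batch <- function(pool, q, seed = 1L, allowed_temperatures = NULL,
                        allowed_ids = NULL) {
  mask <- .unrun_mask(pool, allowed_ids)
  if (!is.null(allowed_temperatures)) {
    temps <- pool_temperatures(pool)
    if (is.null(temps)) stop("pool has no temperature parameter")
    mask <- mask & (temps %in% allowed_temperatures)
  }
  if (q == 0L) return(.batch_selection(integer(0), numeric(0), "sobol",
                                       list(seed = seed)))
  if (sum(mask) < q)
    stop("q = ", q, " exceeds the ", sum(mask), " available candidates")
  d <- ncol(pool$X)
  picked <- integer(0)
  block <- 0L
  while (length(picked) < q) {
    P <- sobol_points(2L * q, d, seed = seed + block)
    for (i in seq_len(nrow(P))) {
      avail <- which(mask)
      if (!length(avail)) break
      d2 <- colSums((t(pool$X[avail, , drop = FALSE]) - P[i, ])^2)
      j <- avail[which.min(d2)]
      picked <- c(picked, j)
      mask[j] <- FALSE
      if (length(picked) == q) break
    }
    block <- block + 1L
  }
  .batch_selection(picked - 1L, rep(NA_real_, q), "sobol", list(seed = seed))
}

# Shared setup for the model-based strategies: un-run candidates, frozen
# reference point and observed-range normalization.
.acq_setup <- function(model, pool, allowed_ids) {
  mask <- .unrun_mask(pool, allowed_ids)
  cand_rows <- which(mask)
  if (!length(cand_rows)) stop("pool exhausted: no un-run candidates")
  Yobs <- model$Y
  list(cand_rows = cand_rows, cand_ids = cand_rows - 1L,
       ref = reference_point(Yobs), Yobs = Yobs)
}

# Per-sample Pareto fronts of the observed baseline draws (list of matrices).
.sample_fronts <- function(base, S) {
  lapply(seq_len(S), function(j) {
    P <- cbind(base[[1]]$obs[j, ], base[[2]]$obs[j, ])
    P[which(cpp_pareto_mask(P)), , drop = FALSE]
  })
}

.check_two_objectives <- function(model, what) {
  if (length(model$models) != 2L)
    stop(what, " is implemented for exactly 2 objectives")
}

#' q-NEHVI batch: noisy expected hypervolume improvement, greedy-sequential
#'
#' For each batch slot the expected joint hypervolume improvement of every
#' candidate is estimated by Monte Carlo over joint posterior samples that
#' include the observed conditions (so the Pareto front itself is treated
#' as a noisy realisation) and all pending picks; the argmax joins the
#' batch and the per-sample non-dominated boxes are updated incrementally.
#' Ties break to the lowest pool id.
#'
#' @param model a fitted `rxnbo_surrogate` (2 objectives).
#' @param pool the pool.
#' @param q batch size.
#' @param mc_samples Monte-Carlo sample count (>= 8 for a usable estimator).
#' @param seed RNG seed.
#' @param allowed_ids optional candidate restriction (0-based ids).
#' @param constraint_hook internal: function(mask_over_candidates,
#'   picked_candidate_indices) -> updated mask, used by [constrained_batch()].
#' @export
qnehvi_batch <- function(model, pool, q, mc_samples = 128L, seed = 1L,
                         allowed_ids = NULL, constraint_hook = NULL) {
  .check_two_objectives(model, "qnehvi_batch")
  if (mc_samples < 8L) warning("mc_samples < 8: estimator unusable")
  st <- .acq_setup(model, pool, allowed_ids)
  if (length(st$cand_rows) < q) stop("pool exhausted: need ", q,
                                     " candidates, have ", length(st$cand_rows))
  S <- as.integer(mc_samples)
  base <- .acq_base_samples(model, pool, st$cand_ids, S, seed)
  fronts <- .sample_fronts(base, S)
  c1 <- base[[1]]$cand; c2 <- base[[2]]$cand     # S x n_cand
  alive <- rep(TRUE, length(st$cand_rows))
  picks <- integer(0); vals <- numeric(0)
  for (t in seq_len(q)) {
    scores <- cpp_mean_hvi(c1, c2, fronts, st$ref)
    scores[!alive] <- -Inf
    i <- which.max(scores)                        # first max = lowest id
    picks <- c(picks, i); vals <- c(vals, scores[i])
    alive[i] <- FALSE
    if (t < q) {
      for (j in seq_len(S)) {
        P <- rbind(fronts[[j]], c(c1[j, i], c2[j, i]))
        fronts[[j]] <- P[which(cpp_pareto_mask(P)), , drop = FALSE]
      }
      if (!is.null(constraint_hook)) alive <- constraint_hook(alive, picks)
      if (!any(alive)) stop("constraint left no candidates to fill the batch")
    }
  }
  .batch_selection(st$cand_ids[picks], vals, "qnehvi",
                   list(seed = seed, mc_samples = S, ref = st$ref))
}

# Augmented Chebyshev scalarization on [0,1]-normalized objectives:
# s(y) = min_i(w_i y_i) + rho * sum_i(w_i y_i).
.chebyshev <- function(Ynorm, w, rho) {
  W <- sweep(Ynorm, 2L, w, `*`)
  apply(W, 1L, min) + rho * rowSums(W)
}

# Observed per-objective normalization (frozen per iteration): maps AP units
# to [0,1] by the observed range; a degenerate range maps to constant 0.5.
.obs_norm_params <- function(Yobs) {
  lo <- apply(Yobs, 2L, min); hi <- apply(Yobs, 2L, max)
  degenerate <- hi - lo <= 0
  if (any(degenerate))
    warning("degenerate observed range for objective(s): ",
            paste(colnames(Yobs)[degenerate], collapse = ", "))
  list(lo = lo, rng = pmax(hi - lo, .Machine$double.eps),
       degenerate = degenerate)
}

.norm_matrix <- function(M, np, k) {
  if (np$degenerate[k]) return(array(0.5, dim(M)))
  (M - np$lo[k]) / np$rng[k]
}

# Scalarize S x n sample matrices (one per objective) in one shot.
.chebyshev_matrices <- function(mats, np, w, rho) {
  terms <- lapply(seq_along(mats), function(k)
    w[k] * .norm_matrix(mats[[k]], np, k))
  Reduce(pmin, terms) + rho * Reduce(`+`, terms)
}

#' q-NParEgo batch: randomized Chebyshev scalarization with noisy EI
#'
#' Each batch slot draws its own weight vector from the unit simplex
#' (floored at 0.01), scalarizes the objectives — normalized to `[0,1]`
#' over the observed range, frozen for the iteration — with the augmented
#' Chebyshev rule, and picks the candidate maximizing a Monte-Carlo noisy
#' expected-improvement estimate of the scalarized value, conditioning on
#' pending picks through the shared posterior samples.
#'
#' @inheritParams qnehvi_batch
#' @param rho augmentation weight (default 0.05).
#' @export
qnparego_batch <- function(model, pool, q, rho = 0.05, mc_samples = 128L,
                           seed = 1L, allowed_ids = NULL,
                           constraint_hook = NULL) {
  st <- .acq_setup(model, pool, allowed_ids)
  if (length(st$cand_rows) < q) stop("pool exhausted: need ", q,
                                     " candidates, have ", length(st$cand_rows))
  S <- as.integer(mc_samples)
  m <- length(model$models)
  base <- .acq_base_samples(model, pool, st$cand_ids, S, seed)
  np <- .obs_norm_params(st$Yobs)
  n_cand <- length(st$cand_rows)
  obs_mats <- lapply(base, `[[`, "obs")
  cand_mats <- lapply(base, `[[`, "cand")
  alive <- rep(TRUE, n_cand)
  picks <- integer(0); vals <- numeric(0); weights <- list()
  # baseline_j tracks max scalarized value per sample over observed + pending
  for (t in seq_len(q)) {
    w <- .with_seed(seed + 31L * t, {
      w0 <- stats::rexp(m); w0 / sum(w0)
    })
    w <- pmax(w, 0.01); w <- w / sum(w)
    weights[[t]] <- w
    s_obs <- .chebyshev_matrices(obs_mats, np, w, rho)
    s_cand <- .chebyshev_matrices(cand_mats, np, w, rho)
    baseline <- apply(s_obs, 1L, max)
    if (length(picks))
      baseline <- pmax(baseline,
                       apply(s_cand[, picks, drop = FALSE], 1L, max))
    impr <- pmax(s_cand - baseline, 0)
    scores <- colMeans(impr)
    scores[!alive] <- -Inf
    i <- which.max(scores)
    picks <- c(picks, i); vals <- c(vals, scores[i])
    alive[i] <- FALSE
    if (t < q && !is.null(constraint_hook)) {
      alive <- constraint_hook(alive, picks)
      if (!any(alive)) stop("constraint left no candidates to fill the batch")
    }
  }
  .batch_selection(st$cand_ids[picks], vals, "qnparego",
                   list(seed = seed, rho = rho, weights = weights))
}

#' TS-HVI batch: Thompson sampling with hypervolume improvement
#'
#' Draws `q` joint posterior function realisations over the un-run
#' candidates; each realisation contributes the candidate whose sampled
#' objective vector has maximal hypervolume improvement over the observed
#' Pareto front. If a realisation assigns zero improvement everywhere, the
#' pick falls back to the maximal sampled objective sum (recorded).
#'
#' @inheritParams qnehvi_batch
#' @export
tshvi_batch <- function(model, pool, q, seed = 1L, allowed_ids = NULL,
                        constraint_hook = NULL) {
  .check_two_objectives(model, "tshvi_batch")
  st <- .acq_setup(model, pool, allowed_ids)
  if (length(st$cand_rows) < q) stop("pool exhausted: need ", q,
                                     " candidates, have ", length(st$cand_rows))
  frontY <- st$Yobs[pareto_front(st$Yobs), , drop = FALSE]
  draws <- sample_posterior(model, pool, st$cand_ids, n_samples = q,
                            seed = seed)
  alive <- rep(TRUE, length(st$cand_rows))
  picks <- integer(0); vals <- numeric(0); fallback <- logical(0)
  for (t in seq_len(q)) {
    hv <- cpp_hvi2d_many(cbind(draws[t, , 1L], draws[t, , 2L]),
                         frontY, st$ref)
    hv[!alive] <- -Inf
    if (max(hv) > 0) {
      i <- which.max(hv); fb <- FALSE
    } else {
      tot <- draws[t, , 1L] + draws[t, , 2L]
      tot[!alive] <- -Inf
      i <- which.max(tot); fb <- TRUE
    }
    picks <- c(picks, i); vals <- c(vals, max(hv[i], 0)); fallback <- c(fallback, fb)
    alive[i] <- FALSE
    if (t < q && !is.null(constraint_hook)) {
      alive <- constraint_hook(alive, picks)
      if (!any(alive)) stop("constraint left no candidates to fill the batch")
    }
  }
  .batch_selection(st$cand_ids[picks], vals, "tshvi",
                   list(seed = seed, fallback = fallback, ref = st$ref))
}

#' Utopia-point exploitation batch
#'
#' Purely exploitative final-round strategy: ranks un-run candidates by the
#' Euclidean distance of their posterior-mean objective vector to the Utopia
#' point (default `(110, 110)` AP) and returns the `q` closest. No
#' uncertainty term is used.
#'
#' @inheritParams qnehvi_batch
#' @param utopia ideal objective vector.
#' @export
utopia_exploit_batch <- function(model, pool, q, utopia = c(110, 110),
                                 allowed_ids = NULL, constraint_hook = NULL) {
  st <- .acq_setup(model, pool, allowed_ids)
  if (length(st$cand_rows) < q) stop("pool exhausted: need ", q,
                                     " candidates, have ", length(st$cand_rows))
  mu <- predict_surrogate(model, pool, st$cand_ids)$mean
  dist <- sqrt(rowSums(sweep(mu, 2L, utopia)^2))
  alive <- rep(TRUE, length(st$cand_rows))
  picks <- integer(0)
  for (t in seq_len(q)) {
    d2 <- dist; d2[!alive] <- Inf
    i <- which.min(d2)
    picks <- c(picks, i)
    alive[i] <- FALSE
    if (t < q && !is.null(constraint_hook)) {
      alive <- constraint_hook(alive, picks)
      if (!any(alive)) stop("constraint left no candidates to fill the batch")
    }
  }
  .batch_selection(st$cand_ids[picks], -dist[picks], "utopia_exploit",
                   list(utopia = utopia))
}

# Slot-1 ("single-point") acquisition scores over all un-run candidates,
# used by the nested constraint to rank temperature levels.
.acq_point_scores <- function(strategy, model, pool, mc_samples, rho,
                              utopia, seed, allowed_ids = NULL) {
  st <- .acq_setup(model, pool, allowed_ids)
  S <- as.integer(mc_samples)
  if (strategy == "qnehvi") {
    base <- .acq_base_samples(model, pool, st$cand_ids, S, seed)
    fronts <- .sample_fronts(base, S)
    scores <- cpp_mean_hvi(base[[1]]$cand, base[[2]]$cand, fronts, st$ref)
  } else if (strategy == "qnparego") {
    m <- length(model$models)
    base <- .acq_base_samples(model, pool, st$cand_ids, S, seed)
    np <- .obs_norm_params(st$Yobs)
    w <- .with_seed(seed + 31L, { w0 <- stats::rexp(m); w0 / sum(w0) })
    w <- pmax(w, 0.01); w <- w / sum(w)
    s_obs <- .chebyshev_matrices(lapply(base, `[[`, "obs"), np, w, rho)
    s_cand <- .chebyshev_matrices(lapply(base, `[[`, "cand"), np, w, rho)
    scores <- colMeans(pmax(s_cand - apply(s_obs, 1L, max), 0))
  } else if (strategy == "tshvi") {
    frontY <- st$Yobs[pareto_front(st$Yobs), , drop = FALSE]
    draws <- sample_posterior(model, pool, st$cand_ids, n_samples = S,
                              seed = seed)
    acc <- numeric(length(st$cand_ids))
    for (j in seq_len(S))
      acc <- acc + cpp_hvi2d_many(cbind(draws[j, , 1L], draws[j, , 2L]),
                                  frontY, st$ref)
    scores <- acc / S
  } else if (strategy == "utopia_exploit") {
    mu <- predict_surrogate(model, pool, st$cand_ids)$mean
    scores <- -sqrt(rowSums(sweep(mu, 2L, utopia)^2))
  } else stop("no pointwise scores for strategy: ", strategy)
  list(ids = st$cand_ids, scores = scores)
}

#' Batch selection under a unique-temperature constraint
#'
#' Wraps any inner strategy so the resulting batch uses at most `k` unique
#' temperature levels. `naive`: the inner strategy runs unrestricted until
#' its picks span `k` distinct temperatures, after which the remaining slots
#' are restricted to those levels. `nested`: every temperature level is
#' first scored by the mean single-point acquisition value of its un-run
#' candidates (levels with more than 5000 candidates are scored on a seeded
#' random subsample of 5000), the top `k` levels are kept, and the inner
#' strategy runs on the restricted pool. With an inner Sobol strategy
#' (no acquisition values) the nested mode selects `k` levels uniformly at
#' random, matching how constrained campaigns are initialized.
#'
#' @param strategy inner strategy name (see [acq_config()]).
#' @param constraint a [batch_constraint()].
#' @param model fitted `rxnbo_surrogate` (ignored for `strategy = "sobol"`).
#' @param pool the pool.
#' @param q batch size.
#' @param mc_samples,rho,utopia,seed forwarded to the inner strategy.
#' @export
constrained_batch <- function(strategy, constraint, model, pool, q,
                              mc_samples = 128L, rho = 0.05,
                              utopia = c(110, 110), seed = 1L) {
  stopifnot(inherits(constraint, "rxnbo_constraint"))
  levels_all <- .constraint_values(pool, constraint)
  k <- constraint$max_unique
  unrun_levels <- unique(levels_all[!pool$run_mask])
  if (length(unrun_levels) < 1L) stop("pool exhausted")
  run_inner <- function(allowed_ids = NULL, hook = NULL) {
    switch(strategy,
      sobol = .sobol_with_hook(pool, q, seed, allowed_ids, hook),
      qnehvi = qnehvi_batch(model, pool, q, mc_samples, seed,
                            allowed_ids, hook),
      qnparego = qnparego_batch(model, pool, q, rho, mc_samples, seed,
                                allowed_ids, hook),
      tshvi = tshvi_batch(model, pool, q, seed, allowed_ids, hook),
      utopia_exploit = utopia_exploit_batch(model, pool, q, utopia,
                                            allowed_ids, hook),
      stop("unknown strategy: ", strategy))
  }
  if (constraint$mode == "naive") {
    # hook sees candidate-index masks; translate to temperature levels
    make_hook <- function(cand_ids) {
      lv <- levels_all[cand_ids + 1L]
      function(alive, picks) {
        seen <- unique(lv[picks])
        if (length(seen) >= k) alive & (lv %in% seen) else alive
      }
    }
    mask <- .unrun_mask(pool)
    cand_ids <- which(mask) - 1L
    batch <- run_inner(allowed_ids = cand_ids, hook = make_hook(cand_ids))
  } else {
    if (strategy == "sobol") {
      keep <- .with_seed(seed + 47L,
                         sample(unrun_levels, min(k, length(unrun_levels))))
    } else {
      ps <- .acq_point_scores(strategy, model, pool, mc_samples, rho,
                              utopia, seed)
      lv <- levels_all[ps$ids + 1L]
      level_score <- vapply(unrun_levels, function(L) {
        idx <- which(lv == L)
        if (length(idx) > 5000L)
          idx <- .with_seed(seed + 53L, sample(idx, 5000L))
        mean(ps$scores[idx])
      }, numeric(1))
      ord <- order(level_score, decreasing = TRUE)
      keep <- unrun_levels[ord][seq_len(min(k, length(unrun_levels)))]
    }
    allowed <- which(.unrun_mask(pool) & (levels_all %in% keep)) - 1L
    if (length(allowed) < q)
      stop("infeasible fill: only ", length(allowed), " candidates at the ",
           length(keep), " allowed level(s), need ", q)
    batch <- run_inner(allowed_ids = allowed)
  }
  n_lv <- length(unique(levels_all[batch$condition_ids + 1L]))
  if (n_lv > k) stop("internal error: constraint violated")   # defensive
  batch$info$constraint <- list(mode = constraint$mode, k = k)
  batch
}

# Sobol selection with a slot-wise constraint hook (used only by the naive
# wrapper; plain Sobol goes through sobol_batch()).
.sobol_with_hook <- function(pool, q, seed, allowed_ids, hook) {
  mask0 <- .unrun_mask(pool, allowed_ids)
  cand_rows <- which(mask0)
  if (length(cand_rows) < q) stop("q = ", q, " exceeds the ",
                                  length(cand_rows), " available candidates")
  if (q == 0L) return(.batch_selection(integer(0), numeric(0), "sobol",
                                       list(seed = seed)))
  d <- ncol(pool$X)
  alive <- rep(TRUE, length(cand_rows))
  picks <- integer(0)
  block <- 0L
  Xc <- pool$X[cand_rows, , drop = FALSE]
  while (length(picks) < q) {
    P <- sobol_points(2L * q, d, seed = seed + block)
    for (i in seq_len(nrow(P))) {
      avail <- which(alive)
      if (!length(avail)) stop("constraint left no candidates to fill the batch")
      d2 <- colSums((t(Xc[avail, , drop = FALSE]) - P[i, ])^2)
      j <- avail[which.min(d2)]
      picks <- c(picks, j)
      alive[j] <- FALSE
      if (!is.null(hook) && length(picks) < q) alive <- hook(alive, picks)
      if (length(picks) == q) break
    }
    block <- block + 1L
  }
  .batch_selection(cand_rows[picks] - 1L, rep(NA_real_, q), "sobol",
                   list(seed = seed))
}
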