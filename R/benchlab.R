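# Stand-in for the laboratory: ground-truth objective landscapes over
# discrete condition spaces, clamped Gaussian observation noise, and the
# repeated-seed benchmark harness.

.mix_seed <- function(...) {
  v <- c(...)
  as.integer((sum(as.double(v) * (1000003^seq_along(v) %% 2147483647)) +
                sum(v)) %% 2147483563) + 1L
}

#' Default synthetic reaction space for benchmarking
#'
#' Seven ligands, four precatalysts, four bases, five solvents (with boiling
#' points 65--153 degrees C) and five temperatures (30--110 degrees C); the
#' boiling-point rule leaves 2128 of the 2800 raw combinations feasible —
#' the scale of one plate-robot campaign.
#'
#' @export
default_benchmark_space <- function() {
  search_space(
    list(
      param_def("ligand", "categorical", paste0("L", 1:7)),
      param_def("precatalyst", "categorical", paste0("P", 1:4)),
      param_def("base", "categorical", paste0("B", 1:4)),
      param_def("solvent", "categorical", paste0("S", 1:5),
                boiling_points = stats::setNames(c(65, 80, 100, 132, 153),
                                                 paste0("S", 1:5))),
      param_def("temperature", "temperature", c(30, 50, 70, 90, 110))
    ),
    feasibility = list(rule_temperature_le_bp("solvent"))
  )
}

#' Generate a synthetic reaction landscape with a known Pareto front
#'
#' Builds a ground-truth oracle over a discrete condition space: each latent
#' objective is a sum of seeded random categorical main effects, sparse
#' pairwise interactions, a smooth quadratic temperature response and a few
#' high-magnitude "cliff" interactions (isolated optima, the hallmark of
#' reactivity landscapes), standardized and squashed through a logistic map
#' to `[0, 100]`. The second objective shares the first's latent field with
#' correlation `tradeoff_cor` (negative values create a yield/selectivity
#' trade-off), so the exact Pareto front — computed by full enumeration —
#' has several points.
#'
#' @param space a `rxnbo_space`; default [default_benchmark_space()].
#' @param effect_params list overriding any of: `main_sd` (categorical
#'   main-effect scale, 1), `interaction_sd` (pairwise scale, 0.5),
#'   `interaction_density` (fraction of nonzero pair cells, 0.15),
#'   `n_cliffs` (2), `cliff_scale` (2.5), `temp_curvature` (1.5),
#'   `tradeoff_cor` (-0.4), `gain` (logistic steepness, 1.5),
#'   `min_front_size` (3).
#' @param seed integer; the whole truth table is deterministic in it.
#' @param noise_sd default observation-noise standard deviation (AP units)
#'   used by [observe()] when not overridden.
#' @return a `rxnbo_oracle`: pool, `truth` matrix (AP units), true front
#'   ids, reference point, objective bounds.
#' @export
generate_synthetic_landscape <- function(space = default_benchmark_space(),
                                         effect_params = list(),
                                         seed = 1L, noise_sd = 0) {
  ep <- utils::modifyList(list(main_sd = 1, interaction_sd = 0.5,
                               interaction_density = 0.15, n_cliffs = 2L,
                               cliff_scale = 2.5, temp_curvature = 1.5,
                               tradeoff_cor = -0.4, gain = 1.5,
                               min_front_size = 3L),
                          effect_params)
  pool <- build_pool(space)
  cond <- pool$conditions
  cat_params <- Filter(function(p) p$role == "categorical", space$parameters)
  tp <- .temperature_param(space)
  latent_field <- function(sub_seed) {
    z <- numeric(nrow(cond))
    s <- 0L
    for (p in cat_params) {
      eff <- .with_seed(.mix_seed(seed, sub_seed, 1L, s <- s + 1L),
                        stats::rnorm(length(p$values), 0, ep$main_sd))
      z <- z + eff[match(cond[[p$name]], p$values)]
    }
    if (length(cat_params) >= 2L) {
      pairs <- utils::combn(length(cat_params), 2L)
      for (col in seq_len(ncol(pairs))) {
        pa <- cat_params[[pairs[1L, col]]]; pb <- cat_params[[pairs[2L, col]]]
        n_ab <- length(pa$values) * length(pb$values)
        eff <- .with_seed(.mix_seed(seed, sub_seed, 2L, col), {
          e <- stats::rnorm(n_ab, 0, ep$interaction_sd)
          e[stats::runif(n_ab) > ep$interaction_density] <- 0
          e
        })
        idx <- (match(cond[[pa$name]], pa$values) - 1L) *
          length(pb$values) + match(cond[[pb$name]], pb$values)
        z <- z + eff[idx]
      }
    }
    if (!is.null(tp)) {
      temps <- as.numeric(cond[[tp]])
      t_rng <- range(space$parameters[[tp]]$values)
      t_opt <- .with_seed(.mix_seed(seed, sub_seed, 3L),
                          stats::runif(1, t_rng[1], t_rng[2]))
      z <- z - ep$temp_curvature * ((temps - t_opt) / diff(t_rng))^2
    }
    if (ep$n_cliffs > 0L && length(cat_params) >= 2L) {
      for (cl in seq_len(ep$n_cliffs)) {
        combo <- .with_seed(.mix_seed(seed, sub_seed, 4L, cl), {
          ij <- sample(length(cat_params), 2L)
          list(ij = ij,
               va = sample(cat_params[[ij[1L]]]$values, 1L),
               vb = sample(cat_params[[ij[2L]]]$values, 1L))
        })
        hit <- cond[[cat_params[[combo$ij[1L]]]$name]] == combo$va &
               cond[[cat_params[[combo$ij[2L]]]$name]] == combo$vb
        z[hit] <- z[hit] + ep$cliff_scale
      }
    }
    as.numeric(scale(z))
  }
  z1 <- latent_field(101L)
  z2_raw <- latent_field(202L)
  rho <- ep$tradeoff_cor
  z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * z2_raw
  truth <- cbind(AP_yield = 100 * stats::plogis(ep$gain * z1),
                 AP_selectivity = 100 * stats::plogis(ep$gain * z2))
  front <- pareto_front(truth)
  if (length(front) < ep$min_front_size)
    stop("landscape has a Pareto front of ", length(front), " points; ",
         "requested at least ", ep$min_front_size,
         " — adjust tradeoff_cor or effect scales")
  structure(list(pool = pool, truth = truth,
                 front_ids = as.integer(front - 1L),
                 ref_point = reference_point(truth),
                 bounds = rbind(c(0, 100), c(0, 100)),
                 noise_sd = noise_sd,
                 provenance = list(kind = "synthetic", seed = seed,
                                   effect_params = ep)),
            class = "rxnbo_oracle")
}

#' @export
print.rxnbo_oracle <- function(x, ...) {
  cat("rxnbo benchmark oracle (", x$provenance$kind, "): ",
      nrow(x$truth), " conditions, front of ", length(x$front_ids),
      " points\n", sep = "")
  invisible(x)
}

#' Train an emulator oracle from a seed dataset
#'
#' Fits one deterministic feed-forward (single hidden layer) regressor per
#' objective on the encoded seed observations and tabulates its predictions
#' over the full expanded feasible enumeration, clamped to the objective
#' bounds — a virtual dataset standing in for the laboratory, in the style
#' of emulated benchmark suites.
#'
#' @param seed_dataset data.frame holding one column per space parameter
#'   plus numeric objective columns.
#' @param expanded_space a `rxnbo_space` whose parameters are a superset of
#'   the seed dataset's condition columns (e.g. more temperature levels).
#' @param objectives names of the objective columns in `seed_dataset`.
#' @param seed integer; fixes the network initialization.
#' @param bounds per-objective clamp bounds, rows = objectives (default
#'   `[0, 100]` for both).
#' @param hidden hidden-layer size.
#' @export
train_emulator <- function(seed_dataset, expanded_space, objectives,
                           seed = 1L, bounds = NULL, hidden = 12L) {
  pool <- build_pool(expanded_space)
  pnames <- names(expanded_space$parameters)
  missing <- setdiff(pnames, names(seed_dataset))
  if (length(missing))
    stop("expanded space parameter(s) missing from seed dataset: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(seed_dataset),
                   c(pnames, objectives, "rxn_id", "iteration", "plate",
                     "well"))
  if (length(extra))
    stop("expanded space is missing seed parameter(s): ",
         paste(extra, collapse = ", "))
  if (nrow(seed_dataset) < 50L)
    stop("need >= 50 seed observations, got ", nrow(seed_dataset))
  key <- function(df) do.call(paste, c(lapply(pnames, function(p)
    as.character(df[[p]])), sep = "\r"))
  rows <- match(key(seed_dataset), key(pool$conditions))
  if (anyNA(rows))
    stop("seed dataset rows not in the expanded feasible space: rows ",
         paste(which(is.na(rows)), collapse = ", "))
  X <- pool$X[rows, , drop = FALSE]
  if (is.null(bounds)) bounds <- matrix(c(0, 100), length(objectives), 2,
                                        byrow = TRUE)
  truth <- matrix(0, nrow(pool$X), length(objectives),
                  dimnames = list(NULL, objectives))
  fits <- list()
  for (k in seq_along(objectives)) {
    y <- seed_dataset[[objectives[k]]]
    if (is.null(y)) stop("objective column not found: ", objectives[k])
    fit <- .with_seed(.mix_seed(seed, k),
                      nnet::nnet(X, y / 100, size = hidden, decay = 1e-4,
                                 maxit = 800L, linout = TRUE, trace = FALSE,
                                 MaxNWts = 10000L))
    fits[[k]] <- fit
    pred <- 100 * as.numeric(stats::predict(fit, pool$X))
    truth[, k] <- pmin(pmax(pred, bounds[k, 1L]), bounds[k, 2L])
  }
  structure(list(pool = pool, truth = truth,
                 front_ids = as.integer(pareto_front(truth) - 1L),
                 ref_point = reference_point(truth),
                 bounds = bounds, noise_sd = 0,
                 provenance = list(kind = "emulated", seed = seed,
                                   n_seed = nrow(seed_dataset),
                                   fits = fits,
                                   train_rows = rows)),
            class = "rxnbo_oracle")
}

#' Observe conditions through the oracle's noise model
#'
#' Returns the ground truth of the requested conditions plus independent
#' Gaussian noise per objective, clamped to the objective bounds (AP values
#' cannot leave `[0, 100]`). `sigma = 0` returns the truth exactly.
#'
#' @param oracle a `rxnbo_oracle`.
#' @param ids 0-based condition ids.
#' @param sigma noise standard deviation (scalar or per objective);
#'   defaults to the oracle's `noise_sd`.
#' @param seed RNG seed.
#' @export
observe <- function(oracle, ids, sigma = NULL, seed = 1L) {
  sigma <- sigma %||% oracle$noise_sd
  rows <- .pool_rows(oracle$pool, ids)
  Y <- oracle$truth[rows, , drop = FALSE]
  m <- ncol(Y)
  sigma <- rep(sigma, length.out = m)
  if (any(sigma > 0)) {
    noise <- .with_seed(seed, matrix(stats::rnorm(length(Y)), nrow(Y), m))
    Y <- Y + sweep(noise, 2L, sigma, `*`)
    for (k in seq_len(m))
      Y[, k] <- pmin(pmax(Y[, k], oracle$bounds[k, 1L]),
                     oracle$bounds[k, 2L])
  }
  Y
}

#' Run the repeated-seed benchmark harness
#'
#' For every seed and algorithm: a Sobol plate initializes the campaign,
#' then the algorithm proposes `q` conditions per iteration; the optimizer
#' only ever sees noisy observations, while the hypervolume-% score after
#' each iteration is computed from the noise-free truth of everything
#' selected so far against the oracle's true front.
#'
#' @param oracle a `rxnbo_oracle`.
#' @param algorithms character vector from `sobol`, `qnehvi`, `qnparego`,
#'   `tshvi` (labels must be unique).
#' @param q batch size per iteration.
#' @param n_iterations total iterations (iteration 1 is the Sobol plate).
#' @param seeds integer vector of replicate seeds (the study default is
#'   `1:20`).
#' @param sigma observation-noise standard deviation (AP units).
#' @param constraint optional [batch_constraint()]; when present, the
#'   initial plate restricts to `k` randomly chosen temperature levels and
#'   later iterations go through [constrained_batch()].
#' @param mc_samples Monte-Carlo samples for the noisy strategies.
#' @param n_restarts GP fit restarts per objective.
#' @return a `rxnbo_benchmark`: `results` (algorithm, seed, iteration,
#'   hv_percent) and `summary` (mean and sd per algorithm x iteration).
#' @export
run_benchmark <- function(oracle, algorithms, q = 24L, n_iterations = 5L,
                          seeds = 1:20, sigma = 0, constraint = NULL,
                          mc_samples = 128L, n_restarts = 2L) {
  if (anyDuplicated(algorithms)) stop("duplicate algorithm labels")
  if (q * n_iterations > nrow(oracle$pool$X))
    stop("q x n_iterations exceeds the feasible pool size")
  truth_front <- oracle$truth[oracle$front_ids + 1L, , drop = FALSE]
  rows <- list()
  for (algo in algorithms) {
    for (s in seeds) {
      traj <- .benchmark_one(oracle, algo, q, n_iterations, s, sigma,
                             constraint, mc_samples, n_restarts, truth_front)
      rows[[length(rows) + 1L]] <-
        data.frame(algorithm = algo, seed = s,
                   iteration = seq_len(n_iterations), hv_percent = traj)
    }
  }
  results <- do.call(rbind, rows)
  agg <- stats::aggregate(hv_percent ~ algorithm + iteration, results,
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  summary <- data.frame(algorithm = agg$algorithm, iteration = agg$iteration,
                        mean = agg$hv_percent[, "mean"],
                        sd = agg$hv_percent[, "sd"])
  structure(list(results = results, summary = summary,
                 q = q, n_iterations = n_iterations, sigma = sigma),
            class = "rxnbo_benchmark")
}

.benchmark_one <- function(oracle, algo, q, n_iterations, seed, sigma,
                           constraint, mc_samples, n_restarts, truth_front) {
  pool <- oracle$pool
  obs_ids <- integer(0)
  Yobs <- NULL
  traj <- numeric(n_iterations)
  init_temps <- NULL
  if (!is.null(constraint)) {
    temps <- pool_temperatures(pool)
    init_temps <- .with_seed(.mix_seed(seed, 7L),
                             sample(unique(temps), constraint$max_unique))
  }
  for (it in seq_len(n_iterations)) {
    if (it == 1L || algo == "sobol") {
      batch <- sobol_batch(pool, q, seed = .mix_seed(seed, it),
                           allowed_temperatures = init_temps)
    } else {
      model <- fit_surrogate(pool, observation_set(obs_ids, Yobs),
                             seed = .mix_seed(seed, it, 2L),
                             n_restarts = n_restarts)
      acq_seed <- .mix_seed(seed, it, 3L)
      if (is.null(constraint)) {
        batch <- switch(algo,
          qnehvi = qnehvi_batch(model, pool, q, mc_samples, acq_seed),
          qnparego = qnparego_batch(model, pool, q, 0.05, mc_samples,
                                    acq_seed),
          tshvi = tshvi_batch(model, pool, q, acq_seed),
          stop("unknown algorithm: ", algo))
      } else {
        batch <- constrained_batch(algo, constraint, model, pool, q,
                                   mc_samples = mc_samples, seed = acq_seed)
      }
    }
    ids <- batch$condition_ids
    Ynew <- observe(oracle, ids, sigma, seed = .mix_seed(seed, it, 4L))
    obs_ids <- c(obs_ids, ids)
    Yobs <- rbind(Yobs, Ynew)
    pool <- mark_run(pool, ids)
    traj[it] <- hypervolume_percent(
      oracle$truth[unique(obs_ids) + 1L, , drop = FALSE],
      truth_front, oracle$ref_point)
  }
  traj
}

#' Write benchmark trajectories to CSV
#' @param bench a `rxnbo_benchmark`.
#' @param path output file.
#' @export
write_benchmark_csv <- function(bench, path) {
  utils::write.csv(bench$results, path, row.names = FALSE)
  invisible(path)
}

#' Plot mean hypervolume-% trajectories with +-1 sd bands
#' @param x a `rxnbo_benchmark`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.rxnbo_benchmark <- function(x, ...) {
  s <- x$summary
  algos <- unique(s$algorithm)
  cols <- seq_along(algos)
  graphics::plot(NULL, xlim = range(s$iteration),
                 ylim = c(max(0, min(s$mean - s$sd)),
                          min(100, max(s$mean + s$sd) + 2)),
                 xlab = "iteration", ylab = "hypervolume (%)", ...)
  for (i in seq_along(algos)) {
    si <- s[s$algorithm == algos[i], ]
    si <- si[order(si$iteration), ]
    graphics::polygon(c(si$iteration, rev(si$iteration)),
                      c(si$mean - si$sd, rev(si$mean + si$sd)),
                      col = grDevices::adjustcolor(cols[i], 0.15),
                      border = NA)
    graphics::lines(si$iteration, si$mean, col = cols[i], lwd = 2)
  }
  graphics::legend("bottomright", legend = algos, col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}
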