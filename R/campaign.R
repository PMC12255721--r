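#' Start an optimization campaign
#'
#' A campaign is a small state machine over a candidate pool: iteration 1
#' proposes a Sobol plate (optionally restricted to configured starting
#' temperatures), later iterations run the configured acquisition strategy;
#' each suggested plate must be ingested (with measured objectives) before
#' the next one can be suggested. The state is an environment so helper
#' functions mutate it in place.
#'
#' @param pool a `rxnbo_pool`.
#' @param objectives objective column names (e.g.
#'   `c("AP_yield", "AP_selectivity")`).
#' @param q batch size per iteration.
#' @param strategy acquisition strategy for iterations >= 2 (see
#'   [acq_config()]).
#' @param constraint optional [batch_constraint()].
#' @param init_temperatures optional numeric temperatures the first Sobol
#'   plate is restricted to (the deployed campaigns used `c(70, 100)`).
#' @param mc_samples,rho,utopia,seed forwarded to the strategies.
#' @return a `rxnbo_campaign` environment.
#' @export
new_campaign <- function(pool, objectives, q = 96L, strategy = "qnehvi",
                         constraint = NULL, init_temperatures = NULL,
                         mc_samples = 128L, rho = 0.05,
                         utopia = c(110, 110), seed = 1L) {
  camp <- new.env(parent = emptyenv())
  camp$pool <- pool
  camp$config <- list(objectives = objectives, q = as.integer(q),
                      strategy = strategy, constraint = constraint,
                      init_temperatures = init_temperatures,
                      mc_samples = as.integer(mc_samples), rho = rho,
                      utopia = utopia, seed = as.integer(seed))
  camp$obs_ids <- integer(0)
  camp$Y <- NULL
  camp$obs_iteration <- integer(0)
  camp$history <- list()
  camp$iteration <- 0L
  camp$status <- "ready_to_suggest"
  class(camp) <- "rxnbo_campaign"
  camp
}

#' @export
print.rxnbo_campaign <- function(x, ...) {
  cat("rxnbo campaign: iteration ", x$iteration, ", status ", x$status,
      ", ", length(x$obs_ids), " observations\n", sep = "")
  invisible(x)
}

#' Suggest the next plate of experiments
#'
#' Iteration 1 is a Sobol plate (restricted to the configured starting
#' temperatures, if any); later iterations use the configured strategy,
#' wrapped by the temperature constraint when one is set. The batch is
#' appended to the history, its conditions are marked as pending/run, and
#' the campaign moves to `awaiting_results`.
#'
#' @param camp a `rxnbo_campaign`.
#' @return the `rxnbo_batch` suggested.
#' @export
suggest_next <- function(camp) {
  if (camp$status != "ready_to_suggest")
    stop("campaign is ", camp$status, "; ingest results first")
  cfg <- camp$config
  it <- camp$iteration + 1L
  seed_it <- .mix_seed(cfg$seed, it)
  if (it == 1L) {
    if (!is.null(cfg$constraint) && is.null(cfg$init_temperatures)) {
      temps <- pool_temperatures(camp$pool)
      init <- .with_seed(.mix_seed(cfg$seed, 7L),
                         sample(unique(temps), cfg$constraint$max_unique))
    } else init <- cfg$init_temperatures
    batch <- sobol_batch(camp$pool, cfg$q, seed = seed_it,
                         allowed_temperatures = init)
  } else {
    model <- fit_surrogate(camp$pool,
                           observation_set(camp$obs_ids, camp$Y),
                           seed = .mix_seed(cfg$seed, it, 2L))
    acq_seed <- .mix_seed(cfg$seed, it, 3L)
    if (!is.null(cfg$constraint)) {
      batch <- constrained_batch(cfg$strategy, cfg$constraint, model,
                                 camp$pool, cfg$q,
                                 mc_samples = cfg$mc_samples, rho = cfg$rho,
                                 utopia = cfg$utopia, seed = acq_seed)
    } else {
      batch <- switch(cfg$strategy,
        sobol = sobol_batch(camp$pool, cfg$q, seed = acq_seed),
        qnehvi = qnehvi_batch(model, camp$pool, cfg$q, cfg$mc_samples,
                              acq_seed),
        qnparego = qnparego_batch(model, camp$pool, cfg$q, cfg$rho,
                                  cfg$mc_samples, acq_seed),
        tshvi = tshvi_batch(model, camp$pool, cfg$q, acq_seed),
        utopia_exploit = utopia_exploit_batch(model, camp$pool, cfg$q,
                                              cfg$utopia),
        stop("unknown strategy: ", cfg$strategy))
    }
  }
  camp$pool <- mark_run(camp$pool, batch$condition_ids)
  camp$history[[it]] <- batch
  camp$iteration <- it
  camp$status <- "awaiting_results"
  batch
}

#' Ingest measured results for the pending plate
#'
#' @param camp a `rxnbo_campaign`.
#' @param results an [observation_set()], a data.frame with `rxn_id` plus
#'   objective columns, or a SURF file path.
#' @export
ingest_results <- function(camp, results) {
  if (camp$status != "awaiting_results")
    stop("campaign is ", camp$status, "; suggest a batch first")
  if (is.character(results))
    results <- read_surf(results, camp$pool, camp$config$objectives)
  if (is.data.frame(results)) {
    if (!"rxn_id" %in% names(results)) stop("results need an rxn_id column")
    results <- observation_set(results$rxn_id,
                               as.matrix(results[camp$config$objectives]))
  }
  ids <- results$condition_ids
  Y <- results$Y
  pending <- camp$history[[camp$iteration]]$condition_ids
  if (!all(ids %in% pending))
    stop("results contain conditions not in the pending batch: ",
         paste(setdiff(ids, pending), collapse = ", "))
  camp$obs_ids <- c(camp$obs_ids, ids)
  camp$Y <- rbind(camp$Y, Y)
  colnames(camp$Y) <- camp$config$objectives
  camp$obs_iteration <- c(camp$obs_iteration, rep(camp$iteration,
                                                  length(ids)))
  camp$status <- "ready_to_suggest"
  invisible(camp)
}

#' Run a campaign against a benchmark oracle
#'
#' Alternates [suggest_next()] and [observe()] for `n_iterations`,
#' ingesting the oracle's (optionally noisy) measurements, and reports the
#' hypervolume-% trajectory against the oracle's true front.
#'
#' @param camp a fresh `rxnbo_campaign` built on the oracle's pool.
#' @param oracle a `rxnbo_oracle`.
#' @param n_iterations number of plates.
#' @param sigma observation-noise standard deviation.
#' @return list with the campaign and a data.frame
#'   `(iteration, hv_percent)`.
#' @export
run_simulated_campaign <- function(camp, oracle, n_iterations, sigma = 0) {
  truth_front <- oracle$truth[oracle$front_ids + 1L, , drop = FALSE]
  hv <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    batch <- suggest_next(camp)
    Y <- observe(oracle, batch$condition_ids, sigma,
                 seed = .mix_seed(camp$config$seed, it, 4L))
    colnames(Y) <- camp$config$objectives
    ingest_results(camp, observation_set(batch$condition_ids, Y))
    hv[it] <- hypervolume_percent(
      oracle$truth[unique(camp$obs_ids) + 1L, , drop = FALSE],
      truth_front, oracle$ref_point)
  }
  list(campaign = camp,
       trajectory = data.frame(iteration = seq_len(n_iterations),
                               hv_percent = hv))
}

#' Read observations from a SURF-style table
#'
#' SURF (simple user-friendly reaction format) files are flat tab-separated
#' tables: one row per reaction, one column per reaction parameter, plus
#' numeric objective columns. Rows with every objective filled become
#' observations; rows with empty objective cells are counted as pending.
#' Column order is irrelevant. Conditions are resolved to pool ids by their
#' parameter labels (an `rxn_id` column, when present, is checked against
#' the resolution).
#'
#' @param path TSV file path.
#' @param pool the `rxnbo_pool` conditions are resolved against.
#' @param objectives objective column names expected in the file.
#' @return an [observation_set()]; attribute `pending` counts unmeasured
#'   rows.
#' @export
read_surf <- function(path, pool, objectives) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  pnames <- names(pool$space$parameters)
  missing <- setdiff(pnames, names(df))
  if (length(missing)) stop("SURF file lacks parameter column(s): ",
                            paste(missing, collapse = ", "))
  missing_obj <- setdiff(objectives, names(df))
  if (length(missing_obj)) stop("SURF file lacks objective column(s): ",
                                paste(missing_obj, collapse = ", "))
  key <- function(d) do.call(paste, c(lapply(pnames, function(p)
    as.character(d[[p]])), sep = "\r"))
  rows <- match(key(df), key(pool$conditions))
  if (anyNA(rows))
    stop("unresolvable condition(s) at row(s): ",
         paste(which(is.na(rows)), collapse = ", "))
  Y <- as.matrix(df[objectives])
  storage.mode(Y) <- "double"
  complete <- stats::complete.cases(Y)
  obs <- observation_set((rows - 1L)[complete],
                         Y[complete, , drop = FALSE],
                         iteration = if ("iteration" %in% names(df))
                           df$iteration[complete] else NULL)
  attr(obs, "pending") <- sum(!complete)
  obs
}

#' Write conditions (and optionally results) as a SURF-style table
#'
#' With `Y = NULL` this produces the skeleton handed to the lab: suggested
#' conditions with empty objective cells to fill in.
#'
#' @param pool the pool.
#' @param ids 0-based condition ids.
#' @param objectives objective column names.
#' @param path output TSV path.
#' @param Y optional matrix of measured values (rows follow `ids`).
#' @param iteration optional iteration tag (scalar or per row).
#' @export
write_surf <- function(pool, ids, objectives, path, Y = NULL,
                       iteration = NULL) {
  rows <- .pool_rows(pool, ids)
  df <- data.frame(rxn_id = as.integer(ids),
                   pool$conditions[rows, names(pool$space$parameters),
                                   drop = FALSE],
                   check.names = FALSE)
  if (is.null(Y)) Y <- matrix(NA_real_, length(ids), length(objectives))
  Y <- as.matrix(Y); colnames(Y) <- objectives
  df <- cbind(df, Y)
  if (!is.null(iteration)) df$iteration <- iteration
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Persist a campaign to a directory
#'
#' Writes a human-inspectable state bundle: `space.yaml` (+ descriptor
#' CSVs), `pool.csv`, `observations.surf`, `history.json`, `config.yaml`.
#'
#' @param camp a `rxnbo_campaign`.
#' @param dir target directory (created if needed).
#' @export
save_campaign <- function(camp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_space_yaml(camp$pool$space, file.path(dir, "space.yaml"))
  write_pool_csv(camp$pool, file.path(dir, "pool.csv"))
  if (length(camp$obs_ids))
    write_surf(camp$pool, camp$obs_ids, camp$config$objectives,
               file.path(dir, "observations.surf"), Y = camp$Y,
               iteration = camp$obs_iteration)
  history <- lapply(camp$history, function(b)
    list(strategy = b$strategy, condition_ids = b$condition_ids,
         acq_values = b$acq_values))
  jsonlite::write_json(list(iteration = camp$iteration,
                            status = camp$status, history = history),
                       file.path(dir, "history.json"), auto_unbox = TRUE,
                       digits = NA)
  cfg <- camp$config
  cfg$constraint <- if (!is.null(cfg$constraint))
    list(parameter = cfg$constraint$parameter,
         max_unique = cfg$constraint$max_unique,
         mode = cfg$constraint$mode)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Restore a campaign from [save_campaign()] output
#' @param dir state directory.
#' @export
load_campaign <- function(dir) {
  space <- read_space_yaml(file.path(dir, "space.yaml"))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  constraint <- if (!is.null(cfg$constraint))
    batch_constraint(cfg$constraint$max_unique, cfg$constraint$mode,
                     cfg$constraint$parameter)
  pool <- build_pool(space)
  camp <- new_campaign(pool, objectives = unlist(cfg$objectives),
                       q = cfg$q, strategy = cfg$strategy,
                       constraint = constraint,
                       init_temperatures = unlist(cfg$init_temperatures),
                       mc_samples = cfg$mc_samples, rho = cfg$rho,
                       utopia = unlist(cfg$utopia), seed = cfg$seed)
  hist <- jsonlite::read_json(file.path(dir, "history.json"),
                              simplifyVector = TRUE)
  if (length(hist$history)) {
    camp$history <- lapply(seq_len(nrow_or_len(hist$history)), function(i) {
      h <- if (is.data.frame(hist$history)) hist$history[i, ]
           else hist$history[[i]]
      .batch_selection(unlist(h$condition_ids), unlist(h$acq_values),
                       h$strategy)
    })
    for (b in camp$history)
      camp$pool <- mark_run(camp$pool, b$condition_ids)
  }
  camp$iteration <- hist$iteration
  camp$status <- hist$status
  surf <- file.path(dir, "observations.surf")
  if (file.exists(surf)) {
    obs <- read_surf(surf, camp$pool, unlist(cfg$objectives))
    camp$obs_ids <- obs$condition_ids
    camp$Y <- obs$Y
    colnames(camp$Y) <- unlist(cfg$objectives)
    camp$obs_iteration <- obs$iteration
  }
  camp
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
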