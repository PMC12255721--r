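#' Define one reaction parameter
#'
#' A parameter is either `categorical` (a named set of value labels such as
#' ligands, bases or solvents, optionally carrying a numeric descriptor
#' vector per value and, for solvent-like parameters, a boiling point per
#' value) or `temperature` (an ordered set of numeric levels in degrees
#' Celsius).
#'
#' @param name parameter name.
#' @param role `"categorical"` or `"temperature"`.
#' @param values ordered vector of value labels (numeric for temperature).
#' @param descriptors optional data.frame / matrix of numeric descriptors,
#'   one row per value; row names (or a first `value` column) must cover all
#'   values.
#' @param boiling_points optional named numeric vector, degrees Celsius, one
#'   entry per value (solvent-like parameters only).
#' @return a `rxnbo_param` object.
#' @export
param_def <- function(name, role = c("categorical", "temperature"), values,
                      descriptors = NULL, boiling_points = NULL) {
  role <- match.arg(role)
  if (length(values) < 1L) stop("parameter '", name, "' has no values")
  if (anyDuplicated(values)) stop("duplicate value labels in '", name, "'")
  if (role == "temperature") {
    values <- as.numeric(values)
    if (any(!is.finite(values))) stop("non-finite temperature in '", name, "'")
  } else {
    values <- as.character(values)
  }
  if (!is.null(descriptors)) {
    descriptors <- as.data.frame(descriptors)
    if ("value" %in% names(descriptors)) {
      rownames(descriptors) <- as.character(descriptors$value)
      descriptors$value <- NULL
    }
    missing <- setdiff(as.character(values), rownames(descriptors))
    if (length(missing))
      stop("descriptor table of '", name, "' is missing: ",
           paste(missing, collapse = ", "))
    descriptors <- as.matrix(descriptors[as.character(values), , drop = FALSE])
    storage.mode(descriptors) <- "double"
    if (any(!is.finite(descriptors)))
      stop("non-finite descriptors in '", name, "'")
  }
  if (!is.null(boiling_points)) {
    boiling_points <- unlist(boiling_points)
    if (is.null(names(boiling_points)))
      stop("boiling_points must be named by value label")
    boiling_points <- vapply(boiling_points, as.numeric, numeric(1))
  }
  structure(list(name = name, role = role, values = values,
                 descriptors = descriptors, boiling_points = boiling_points),
            class = "rxnbo_param")
}

#' Feasibility rule: reaction temperature must not exceed solvent boiling point
#'
#' A condition passes when its temperature is less than or equal to the
#' boiling point of every in-scope solvent-like value ("exceeded" is strict,
#' so running at reflux temperature is allowed).
#'
#' @param solvent_params names of the solvent-like parameters whose boiling
#'   points constrain the temperature.
#' @export
rule_temperature_le_bp <- function(solvent_params) {
  structure(list(kind = "max_temperature_le_boiling_point",
                 scope = as.character(solvent_params)),
            class = "rxnbo_rule")
}

#' Feasibility rule: forbid a specific combination of parameter values
#'
#' @param combination named list/vector, parameter name -> value label; a
#'   condition matching every entry is removed (e.g. a base/solvent pair that
#'   is unsafe to dispense together).
#' @export
rule_forbidden <- function(combination) {
  structure(list(kind = "forbidden_combination",
                 scope = names(combination),
                 combination = combination),
            class = "rxnbo_rule")
}

#' Assemble a discrete reaction-condition search space
#'
#' @param parameters list of [param_def()] objects (at most one with role
#'   `temperature`).
#' @param feasibility list of rules ([rule_temperature_le_bp()],
#'   [rule_forbidden()]).
#' @param featurization optional named list, parameter name -> one of
#'   `"one_hot"`, `"descriptor"`, `"numeric"`, or
#'   `list(method = "descriptor_pca", variance_threshold = 0.99)`. Defaults:
#'   `descriptor` when the parameter has a descriptor table, `numeric` for
#'   temperature, `one_hot` otherwise.
#' @return a `rxnbo_space` object.
#' @export
search_space <- function(parameters, feasibility = list(),
                         featurization = NULL) {
  if (length(parameters) == 0L) stop("empty space")
  stopifnot(all(vapply(parameters, inherits, logical(1), "rxnbo_param")))
  names(parameters) <- vapply(parameters, `[[`, character(1), "name")
  if (anyDuplicated(names(parameters))) stop("duplicate parameter names")
  n_temp <- sum(vapply(parameters, function(p) p$role == "temperature",
                       logical(1)))
  if (n_temp > 1L) stop("at most one temperature parameter is allowed")
  plan <- list()
  for (p in parameters) {
    default <- if (p$role == "temperature") "numeric"
      else if (!is.null(p$descriptors)) "descriptor" else "one_hot"
    plan[[p$name]] <- default
  }
  if (!is.null(featurization)) {
    unknown <- setdiff(names(featurization), names(parameters))
    if (length(unknown)) stop("featurization for unknown parameter(s): ",
                              paste(unknown, collapse = ", "))
    plan[names(featurization)] <- featurization
  }
  for (p in parameters) {
    f <- plan[[p$name]]
    method <- if (is.list(f)) f$method else f
    if (method %in% c("descriptor", "descriptor_pca") && is.null(p$descriptors))
      stop("parameter '", p$name, "' has no descriptor table for ", method)
    if (method == "numeric" && p$role != "temperature")
      stop("'numeric' featurization is reserved for the temperature parameter")
  }
  for (r in feasibility) {
    unknown <- setdiff(r$scope, names(parameters))
    if (length(unknown)) stop("feasibility rule references unknown parameter(s): ",
                              paste(unknown, collapse = ", "))
  }
  structure(list(parameters = parameters, feasibility = feasibility,
                 featurization = plan),
            class = "rxnbo_space")
}

#' @export
print.rxnbo_space <- function(x, ...) {
  cat("rxnbo search space:", length(x$parameters), "parameters,",
      prod(vapply(x$parameters, function(p) length(p$values), numeric(1))),
      "raw combinations\n")
  for (p in x$parameters)
    cat("  ", p$name, " (", p$role, "): ", length(p$values), " values\n",
        sep = "")
  invisible(x)
}

.temperature_param <- function(space) {
  for (p in space$parameters) if (p$role == "temperature") return(p$name)
  NULL
}

#' Enumerate the full combinatorial condition set
#'
#' Returns the Cartesian product of all parameter value lists in
#' lexicographic order of parameter definition (the first parameter varies
#' slowest), with stable 0-based ids.
#'
#' @param space a `rxnbo_space`.
#' @return data.frame with an `id` column and one column per parameter.
#' @export
enumerate_conditions <- function(space) {
  if (!inherits(space, "rxnbo_space") || length(space$parameters) == 0L)
    stop("empty space")
  vals <- lapply(space$parameters, `[[`, "values")
  grid <- rev(expand.grid(rev(vals), KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE))
  names(grid) <- names(space$parameters)
  data.frame(id = seq_len(nrow(grid)) - 1L, grid,
             stringsAsFactors = FALSE, check.names = FALSE)
}

.rule_passes <- function(rule, conditions, space) {
  if (rule$kind == "max_temperature_le_boiling_point") {
    tp <- .temperature_param(space)
    if (is.null(tp)) return(rep(TRUE, nrow(conditions)))
    temp <- conditions[[tp]]
    ok <- rep(TRUE, nrow(conditions))
    for (pn in setdiff(rule$scope, tp)) {
      p <- space$parameters[[pn]]
      labels <- conditions[[pn]]
      bp <- p$boiling_points[labels]
      if (anyNA(bp)) {
        bad <- unique(labels[is.na(bp)])
        stop("missing boiling point for '", pn, "' value(s): ",
             paste(bad, collapse = ", "))
      }
      ok <- ok & (temp <= bp)
    }
    ok
  } else if (rule$kind == "forbidden_combination") {
    hit <- rep(TRUE, nrow(conditions))
    for (pn in rule$scope)
      hit <- hit & (conditions[[pn]] == rule$combination[[pn]])
    !hit
  } else stop("unknown rule kind: ", rule$kind)
}

#' Filter conditions by the space's feasibility rules
#'
#' Keeps a condition iff every rule passes; preserves order and re-assigns
#' contiguous 0-based ids. Idempotent.
#'
#' @param conditions data.frame from [enumerate_conditions()].
#' @param space the `rxnbo_space` whose rules to apply.
#' @export
apply_feasibility <- function(conditions, space) {
  keep <- rep(TRUE, nrow(conditions))
  for (rule in space$feasibility)
    keep <- keep & .rule_passes(rule, conditions, space)
  out <- conditions[keep, , drop = FALSE]
  out$id <- seq_len(nrow(out)) - 1L
  rownames(out) <- NULL
  out
}

#' Fit a PCA reduction of a descriptor table
#'
#' Chooses the smallest number of principal components whose cumulative
#' explained-variance ratio reaches `variance_threshold`, and returns a
#' reusable projection (centering vector + loadings).
#'
#' @param descriptor_matrix numeric matrix, rows = values, columns =
#'   descriptors.
#' @param variance_threshold fraction in (0, 1].
#' @return a `rxnbo_pca` object with elements `mean`, `rotation`,
#'   `n_components`, `explained`.
#' @export
fit_pca_reduction <- function(descriptor_matrix, variance_threshold = 0.99) {
  X <- as.matrix(descriptor_matrix)
  stopifnot(nrow(X) >= 2, variance_threshold > 0, variance_threshold <= 1)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  vars <- pc$sdev^2
  total <- sum(vars)
  if (total <= .Machine$double.eps * ncol(X)) stop("no variance")
  ratio <- cumsum(vars) / total
  k <- which(ratio >= variance_threshold - 1e-12)[1L]
  structure(list(mean = pc$center,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 n_components = k,
                 explained = ratio[k]),
            class = "rxnbo_pca")
}

#' @export
predict.rxnbo_pca <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  sweep(X, 2L, object$mean) %*% object$rotation
}

#' Encode feasible conditions into a candidate pool
#'
#' Builds the numeric feature matrix the surrogates operate on: one-hot
#' columns for categorical parameters, (optionally PCA-projected) descriptor
#' columns, and a single numeric column for temperature. Every column is
#' min-max scaled to `[0, 1]` over the pool; constant columns are dropped
#' and recorded.
#'
#' @param space a `rxnbo_space`.
#' @param conditions feasible conditions (from [apply_feasibility()], or
#'   [enumerate_conditions()] when no rules apply).
#' @return a `rxnbo_pool` with elements `space`, `conditions`, `X`,
#'   `feature_names`, `run_mask`, `dropped`, `scaling`, `pca`.
#' @export
encode_pool <- function(space, conditions) {
  if (nrow(conditions) == 0L) stop("no conditions to encode")
  blocks <- list(); bnames <- character(0); pca_fits <- list()
  for (p in space$parameters) {
    f <- space$featurization[[p$name]]
    method <- if (is.list(f)) f$method else f
    labels <- conditions[[p$name]]
    if (method == "one_hot") {
      B <- outer(as.character(labels), as.character(p$values), `==`) * 1
      colnames(B) <- paste0(p$name, "=", p$values)
    } else if (method %in% c("descriptor", "descriptor_pca")) {
      miss <- setdiff(unique(as.character(labels)), rownames(p$descriptors))
      if (length(miss)) stop("value(s) absent from descriptor table of '",
                             p$name, "': ", paste(miss, collapse = ", "))
      D <- p$descriptors
      if (method == "descriptor_pca") {
        thr <- if (is.list(f) && !is.null(f$variance_threshold))
          f$variance_threshold else 0.99
        fit <- fit_pca_reduction(D, thr)      # fitted on the full value table
        pca_fits[[p$name]] <- fit
        D <- predict(fit, D)
        colnames(D) <- paste0(p$name, "_PC", seq_len(ncol(D)))
      } else {
        colnames(D) <- paste0(p$name, "_", colnames(D))
      }
      B <- D[as.character(labels), , drop = FALSE]
    } else if (method == "numeric") {
      B <- matrix(as.numeric(labels), ncol = 1,
                  dimnames = list(NULL, p$name))
    } else stop("unknown featurization method: ", method)
    blocks[[p$name]] <- B
  }
  X <- do.call(cbind, blocks)
  rownames(X) <- NULL
  mins <- apply(X, 2L, min); maxs <- apply(X, 2L, max)
  constant <- maxs - mins <= 0
  dropped <- colnames(X)[constant]
  X <- X[, !constant, drop = FALSE]
  rng <- (maxs - mins)[!constant]
  mins <- mins[!constant]
  X <- sweep(sweep(X, 2L, mins), 2L, rng, `/`)
  structure(list(space = space, conditions = conditions, X = X,
                 feature_names = colnames(X),
                 run_mask = rep(FALSE, nrow(conditions)),
                 dropped = dropped,
                 scaling = list(min = mins, range = rng),
                 pca = pca_fits),
            class = "rxnbo_pool")
}

#' @export
print.rxnbo_pool <- function(x, ...) {
  cat("rxnbo candidate pool:", nrow(x$X), "conditions x", ncol(x$X),
      "features (", sum(x$run_mask), "run )\n")
  invisible(x)
}

#' Convenience: enumerate, filter and encode a space in one call
#' @param space a `rxnbo_space`.
#' @export
build_pool <- function(space) {
  encode_pool(space, apply_feasibility(enumerate_conditions(space), space))
}

# row index (1-based) for 0-based pool ids, with validation
.pool_rows <- function(pool, ids) {
  ids <- as.integer(ids)
  if (length(ids) && (min(ids) < 0L || max(ids) >= nrow(pool$X)))
    stop("unknown pool id(s): ",
         paste(ids[ids < 0L | ids >= nrow(pool$X)], collapse = ", "))
  ids + 1L
}

#' Mark conditions as run
#' @param pool a `rxnbo_pool`.
#' @param ids 0-based condition ids.
#' @export
mark_run <- function(pool, ids) {
  pool$run_mask[.pool_rows(pool, ids)] <- TRUE
  pool
}

#' Temperatures of each pool condition (or NULL when the space has none)
#' @param pool a `rxnbo_pool`.
#' @export
pool_temperatures <- function(pool) {
  tp <- .temperature_param(pool$space)
  if (is.null(tp)) return(NULL)
  as.numeric(pool$conditions[[tp]])
}

#' Read a search space from a YAML definition
#'
#' Expected structure: a `parameters:` list (each with `name`, `role`,
#' `values`, optional `descriptors:` CSV path — first column = value label —
#' and optional `boiling_point:` map), an optional `feasibility:` list
#' (`kind` plus `scope`/`combination`), and an optional `featurization:`
#' map.
#'
#' @param path YAML file path.
#' @param base_dir directory against which relative descriptor CSV paths are
#'   resolved (defaults to the YAML's directory).
#' @export
read_space_yaml <- function(path, base_dir = dirname(path)) {
  doc <- yaml::read_yaml(path)
  params <- lapply(doc$parameters, function(p) {
    desc <- NULL
    if (!is.null(p$descriptors)) {
      f <- p$descriptors
      if (!file.exists(f)) f <- file.path(base_dir, p$descriptors)
      desc <- utils::read.csv(f, check.names = FALSE)
      rownames(desc) <- as.character(desc[[1L]])
      desc <- desc[, -1L, drop = FALSE]
    }
    param_def(p$name, p$role %||% "categorical", unlist(p$values),
              descriptors = desc,
              boiling_points = p$boiling_point)
  })
  rules <- lapply(doc$feasibility, function(r) {
    switch(r$kind,
      max_temperature_le_boiling_point = rule_temperature_le_bp(unlist(r$scope)),
      forbidden_combination = rule_forbidden(r$combination),
      stop("unknown feasibility kind: ", r$kind))
  })
  feat <- doc$featurization
  search_space(params, feasibility = rules %||% list(),
               featurization = feat)
}

#' Write a search space to YAML (descriptor tables as sibling CSV files)
#' @param space a `rxnbo_space`.
#' @param path output YAML path.
#' @export
write_space_yaml <- function(space, path) {
  dir <- dirname(path)
  params <- lapply(space$parameters, function(p) {
    out <- list(name = p$name, role = p$role, values = as.list(p$values))
    if (!is.null(p$descriptors)) {
      f <- paste0("descriptors_", p$name, ".csv")
      df <- data.frame(value = rownames(p$descriptors), p$descriptors,
                       check.names = FALSE)
      utils::write.csv(df, file.path(dir, f), row.names = FALSE)
      out$descriptors <- f
    }
    if (!is.null(p$boiling_points))
      out$boiling_point <- as.list(p$boiling_points)
    out
  })
  rules <- lapply(space$feasibility, function(r) {
    if (r$kind == "forbidden_combination")
      list(kind = r$kind, combination = as.list(r$combination))
    else list(kind = r$kind, scope = as.list(r$scope))
  })
  doc <- list(parameters = unname(params))
  if (length(rules)) doc$feasibility <- unname(rules)
  doc$featurization <- space$featurization
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Export a pool as CSV (id, parameter columns, feature columns)
#' @param pool a `rxnbo_pool`.
#' @param path output CSV path.
#' @export
write_pool_csv <- function(pool, path) {
  utils::write.csv(cbind(pool$conditions, as.data.frame(pool$X)),
                   path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
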