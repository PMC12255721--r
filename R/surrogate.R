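#' Fit independent Gaussian-process surrogates, one per objective
#'
#' Each objective (e.g. AP yield, AP selectivity) gets its own GP with a
#' Matern-5/2 ARD kernel over the pool's `[0,1]` features. Targets are
#' standardized per objective before fitting and every prediction is mapped
#' back to original AP units. Replicate observations of the same condition
#' are kept as separate rows; the fitted noise term absorbs them.
#'
#' @param pool a `rxnbo_pool`.
#' @param observations an observation set: list with `condition_ids`
#'   (0-based pool ids) and `Y` (matrix, rows = observations, columns =
#'   objectives); see [observation_set()].
#' @param seed integer; fixes the multi-start hyperparameter optimization.
#' @param n_restarts optimizer restarts (first start is a fixed default).
#' @return a `rxnbo_surrogate`.
#' @export
fit_surrogate <- function(pool, observations, seed = 1L, n_restarts = 2L) {
  obs <- observations
  if (length(obs$condition_ids) < 2L) stop("insufficient data: need >= 2 observations")
  Y <- as.matrix(obs$Y)
  if (ncol(Y) < 1L) stop("need at least one objective")
  if (any(!is.finite(Y))) stop("non-finite objective values")
  rows <- .pool_rows(pool, obs$condition_ids)
  X <- pool$X[rows, , drop = FALSE]
  models <- vector("list", ncol(Y))
  std <- vector("list", ncol(Y))
  for (k in seq_len(ncol(Y))) {
    m <- mean(Y[, k]); s <- stats::sd(Y[, k])
    if (!is.finite(s) || s <= 0) s <- 1   # constant targets: centre only
    std[[k]] <- list(mean = m, sd = s)
    models[[k]] <- .gp_fit_core(X, (Y[, k] - m) / s,
                                seed = seed + 7919L * k,
                                n_restarts = n_restarts)
  }
  structure(list(models = models, std = std,
                 objective_names = colnames(Y) %||%
                   paste0("objective_", seq_len(ncol(Y))),
                 condition_ids = as.integer(obs$condition_ids),
                 Y = Y, seed = seed),
            class = "rxnbo_surrogate")
}

#' Bundle observations for surrogate fitting
#'
#' @param condition_ids 0-based pool ids (duplicates allowed: replicates).
#' @param Y matrix or data.frame of objective values in AP units, one row
#'   per observation.
#' @param iteration optional iteration tag per row.
#' @export
observation_set <- function(condition_ids, Y, iteration = NULL) {
  Y <- as.matrix(Y)
  if (length(condition_ids) != nrow(Y))
    stop("condition_ids and Y disagree on the number of observations")
  structure(list(condition_ids = as.integer(condition_ids), Y = Y,
                 objective_names = colnames(Y),
                 iteration = iteration %||% rep(1L, nrow(Y))),
            class = "rxnbo_observations")
}

#' Posterior mean and variance over pool candidates
#'
#' @param model a `rxnbo_surrogate`.
#' @param pool the pool the model was fitted against.
#' @param ids 0-based pool ids (default: all).
#' @return list with `mean` and `var` matrices (rows = ids, columns =
#'   objectives), de-standardized to AP units.
#' @export
predict_surrogate <- function(model, pool, ids = NULL) {
  if (is.null(ids)) ids <- seq_len(nrow(pool$X)) - 1L
  rows <- .pool_rows(pool, ids)
  Xn <- pool$X[rows, , drop = FALSE]
  m <- length(model$models)
  mu <- matrix(0, length(rows), m); va <- matrix(0, length(rows), m)
  for (k in seq_len(m)) {
    p <- .gp_predict_core(model$models[[k]], Xn)
    mu[, k] <- p$mean * model$std[[k]]$sd + model$std[[k]]$mean
    va[, k] <- p$var * model$std[[k]]$sd^2
  }
  colnames(mu) <- colnames(va) <- model$objective_names
  list(mean = mu, var = va, ids = as.integer(ids))
}

#' Joint posterior samples over a set of candidates
#'
#' Draws from the joint latent posterior restricted to the requested ids,
#' independently per objective (the surrogates are independent GPs), using
#' a jittered Cholesky factor of the posterior covariance. For id sets
#' larger than `max_joint` a seeded random subset of that size is sampled
#' jointly and the remaining ids fall back to their marginal posterior
#' (documented sketch for very large pools).
#'
#' @param model a `rxnbo_surrogate`.
#' @param pool the pool.
#' @param ids 0-based pool ids.
#' @param n_samples number of joint draws.
#' @param seed RNG seed; identical seeds give identical arrays.
#' @param max_joint largest id set factorized exactly (default 4096).
#' @return array `[n_samples, length(ids), n_objectives]` in AP units.
#' @export
sample_posterior <- function(model, pool, ids, n_samples, seed = 1L,
                             max_joint = 4096L) {
  if (n_samples < 1L) stop("n_samples must be >= 1")
  rows <- .pool_rows(pool, ids)
  n <- length(rows); m <- length(model$models)
  Xn <- pool$X[rows, , drop = FALSE]
  out <- array(0, c(n_samples, n, m))
  joint_idx <- if (n > max_joint)
    .with_seed(seed + 13L, sort(sample.int(n, max_joint))) else seq_len(n)
  for (k in seq_len(m)) {
    gp <- model$models[[k]]
    p <- .gp_predict_core(gp, Xn)
    Z <- .with_seed(seed + 101L * k,
                    matrix(stats::rnorm(n_samples * n), n_samples, n))
    S <- matrix(p$mean, n_samples, n, byrow = TRUE)
    # joint block
    C <- .gp_post_cov(gp, Xn[joint_idx, , drop = FALSE])
    L <- .gp_chol(C)$L
    S[, joint_idx] <- S[, joint_idx, drop = FALSE] +
      Z[, joint_idx, drop = FALSE] %*% L
    if (length(joint_idx) < n) {
      rest <- setdiff(seq_len(n), joint_idx)
      S[, rest] <- S[, rest, drop = FALSE] +
        sweep(Z[, rest, drop = FALSE], 2L, sqrt(p$var[rest]), `*`)
    }
    out[, , k] <- S * model$std[[k]]$sd + model$std[[k]]$mean
  }
  dimnames(out) <- list(NULL, NULL, model$objective_names)
  out
}

# Monte-Carlo scaffolding shared by the noisy acquisition strategies.
# Draws S joint posterior samples at the *observed* conditions (the noisy
# baseline), then candidate values from the conditional posterior given each
# baseline draw; candidate-candidate correlation is not materialised (it is
# irrelevant for one-at-a-time greedy scoring). All in AP units.
#
# Returns per objective: obs_samples (S x n_obs), cand_samples (S x n_cand).
.acq_base_samples <- function(model, pool, cand_ids, n_samples, seed) {
  m <- length(model$models)
  obs_rows <- unique(.pool_rows(pool, model$condition_ids))
  Xo <- pool$X[obs_rows, , drop = FALSE]
  cand_rows <- .pool_rows(pool, cand_ids)
  Xc <- pool$X[cand_rows, , drop = FALSE]
  res <- vector("list", m)
  for (k in seq_len(m)) {
    gp <- model$models[[k]]
    sd_k <- model$std[[k]]$sd; mean_k <- model$std[[k]]$mean
    po <- .gp_predict_core(gp, Xo)
    So <- .gp_post_cov(gp, Xo)
    Lo <- .gp_chol(So)$L
    Zo <- .with_seed(seed + 577L * k,
                     matrix(stats::rnorm(n_samples * nrow(Xo)), n_samples))
    Fo <- matrix(po$mean, n_samples, nrow(Xo), byrow = TRUE) + Zo %*% Lo
    # conditional posterior of candidates given sampled f at observed points
    pc <- .gp_predict_core(gp, Xc)
    Ks <- .gp_kstar(gp, Xc)                    # cand x train
    Vtr <- forwardsolve(t(gp$L), t(Ks))        # train x cand
    # posterior cross-covariance cand x obs-locations
    Ks_o <- .gp_kstar(gp, Xo)                  # obs x train
    Vo <- forwardsolve(t(gp$L), t(Ks_o))       # train x obs
    Sco <- gp$s2 * .matern52(.scaled_sqdist(Xc, Xo, gp$ell)) -
      crossprod(Vtr, Vo)                       # cand x obs
    W <- t(backsolve(Lo, forwardsolve(t(Lo), t(Sco))))  # cand x obs, = Sco So^-1
    cond_var <- pmax(pc$var - rowSums(W * Sco), 0)
    cond_mean_shift <- tcrossprod(Fo - matrix(po$mean, n_samples, nrow(Xo),
                                              byrow = TRUE), W)  # S x cand
    Zc <- .with_seed(seed + 977L * k,
                     matrix(stats::rnorm(n_samples * nrow(Xc)), n_samples))
    Fc <- matrix(pc$mean, n_samples, nrow(Xc), byrow = TRUE) +
      cond_mean_shift +
      sweep(Zc, 2L, sqrt(cond_var), `*`)
    res[[k]] <- list(obs = Fo * sd_k + mean_k, cand = Fc * sd_k + mean_k)
  }
  res
}
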