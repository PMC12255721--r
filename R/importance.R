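#' Permutation feature importance of the encoded reaction parameters
#'
#' Fits a random-forest regressor on the pool's encoded features and scores
#' every feature by mean permutation importance: the average increase in
#' mean-squared prediction error when that feature's column is shuffled,
#' over `n_repeats` seeded shuffles. Features are labelled by parameter and
#' value (e.g. `precatalyst=P3`), so the ranking reads directly as "which
#' reaction parameters drive the objective".
#'
#' @param pool a `rxnbo_pool`.
#' @param observations an [observation_set()] (>= 50 rows).
#' @param target_objective column of `observations$Y` to explain.
#' @param seed RNG seed.
#' @param n_repeats permutation repeats per feature.
#' @param num_trees forest size.
#' @return data.frame `(feature, importance)`, sorted descending.
#' @export
feature_importance <- function(pool, observations, target_objective = 1L,
                               seed = 1L, n_repeats = 10L,
                               num_trees = 500L) {
  obs <- observations
  if (length(obs$condition_ids) < 50L)
    stop("need >= 50 observations for importance analysis")
  y <- obs$Y[, target_objective]
  X <- pool$X[.pool_rows(pool, obs$condition_ids), , drop = FALSE]
  out <- data.frame(feature = colnames(X),
                    importance = 0, stringsAsFactors = FALSE)
  if (stats::sd(y) == 0) {
    warning("constant target: all importances are 0")
    return(out)
  }
  df <- data.frame(X, check.names = FALSE)
  fit <- ranger::ranger(x = df, y = y, num.trees = num_trees,
                        seed = seed, num.threads = 1L)
  base_mse <- mean((stats::predict(fit, df,
                                   num.threads = 1L)$predictions - y)^2)
  imp <- .with_seed(seed, {
    vapply(seq_len(ncol(df)), function(j) {
      deltas <- vapply(seq_len(n_repeats), function(r) {
        dp <- df
        dp[[j]] <- dp[[j]][sample.int(nrow(dp))]
        mean((stats::predict(fit, dp,
                             num.threads = 1L)$predictions - y)^2) - base_mse
      }, numeric(1))
      mean(deltas)
    }, numeric(1))
  })
  out$importance <- imp
  out[order(-out$importance), ]
}
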