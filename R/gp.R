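# Gaussian-process regression core: Matern-5/2 kernel with automatic
# relevance determination (one length scale per feature), fitted by
# maximizing the log marginal likelihood with analytic gradients.
# Inputs live in the pool's [0,1] feature cube; targets are standardized
# by the caller. All internal math is in standardized units.

.gp_jitter <- 1e-8
.gp_jitter_max <- 1e-2

# Matern-5/2 correlation from scaled squared distance r2 (r = sqrt(r2)).
.matern52 <- function(r2) {
  r <- sqrt(pmax(r2, 0))
  (1 + sqrt(5) * r + 5 * r2 / 3) * exp(-sqrt(5) * r)
}

# Pairwise squared distances per dimension are precomputed once per fit so
# likelihood/gradient evaluations are cheap matrix algebra.
.gp_dims_sq <- function(X) {
  n <- nrow(X)
  lapply(seq_len(ncol(X)), function(j) {
    dj <- outer(X[, j], X[, j], `-`)
    dj * dj
  })
}

.gp_scaled_r2 <- function(dims_sq, ell) {
  r2 <- 0
  for (j in seq_along(dims_sq)) r2 <- r2 + dims_sq[[j]] / ell[j]^2
  r2
}

# Cholesky with escalating jitter; errors past the documented cap.
.gp_chol <- function(K) {
  jit <- .gp_jitter
  n <- nrow(K)
  repeat {
    L <- tryCatch(chol(K + diag(jit, n)), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = jit))
    jit <- jit * 10
    if (jit > .gp_jitter_max)
      stop("kernel matrix not positive definite even with jitter ",
           .gp_jitter_max)
  }
}

# Negative log marginal likelihood and gradient w.r.t.
# theta = (log ell_1..d, log s2, log sn2).
.gp_nll <- function(theta, dims_sq, y, grad = TRUE) {
  d <- length(dims_sq)
  ell <- exp(theta[seq_len(d)])
  s2 <- exp(theta[d + 1L]); sn2 <- exp(theta[d + 2L])
  n <- length(y)
  r2 <- .gp_scaled_r2(dims_sq, ell)
  M <- .matern52(r2)
  K <- s2 * M + diag(sn2, n)
  ch <- .gp_chol(K)
  L <- ch$L
  alpha <- backsolve(L, forwardsolve(t(L), y))
  nll <- 0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  if (!grad) return(list(value = nll))
  Kinv <- chol2inv(L)
  A <- tcrossprod(alpha) - Kinv            # dNLL/dtheta_i = -0.5 tr(A dK)
  r <- sqrt(pmax(r2, 0))
  E <- exp(-sqrt(5) * r)
  g <- numeric(d + 2L)
  # dK/dlog ell_j = (5/3) s2 (1 + sqrt5 r) e^{-sqrt5 r} * d_j^2 / ell_j^2
  base <- (5 / 3) * s2 * (1 + sqrt(5) * r) * E
  for (j in seq_len(d)) {
    dK <- base * dims_sq[[j]] / ell[j]^2
    g[j] <- -0.5 * sum(A * dK)
  }
  g[d + 1L] <- -0.5 * sum(A * (s2 * M))
  g[d + 2L] <- -0.5 * sum(diag(A)) * sn2
  list(value = nll, grad = g)
}

# Fit one GP on standardized targets. Multi-start L-BFGS-B, deterministic
# given seed. Bounds keep length scales away from zero (one-hot features sit
# sqrt(2) apart) and the noise above a floor of 1e-4 standardized variance.
.gp_fit_core <- function(X, y, seed, n_restarts = 2L, maxit = 60L) {
  d <- ncol(X)
  dims_sq <- .gp_dims_sq(X)
  lower <- c(rep(log(0.05), d), log(1e-3), log(1e-4))
  upper <- c(rep(log(30), d), log(50), log(2))
  starts <- list(c(rep(log(0.7), d), log(1), log(0.01)))
  if (n_restarts > 1L) {
    rs <- .with_seed(seed, lapply(seq_len(n_restarts - 1L), function(i)
      stats::runif(d + 2L, lower, upper)))
    starts <- c(starts, rs)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, fn = function(th) .gp_nll(th, dims_sq, y, grad = FALSE)$value,
                   gr = function(th) .gp_nll(th, dims_sq, y, grad = TRUE)$grad,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("GP hyperparameter optimization failed")
  theta <- best$par
  ell <- exp(theta[seq_len(d)])
  s2 <- exp(theta[d + 1L]); sn2 <- exp(theta[d + 2L])
  K <- s2 * .matern52(.gp_scaled_r2(dims_sq, ell)) + diag(sn2, nrow(X))
  ch <- .gp_chol(K)
  alpha <- backsolve(ch$L, forwardsolve(t(ch$L), y))
  list(X = X, y = y, ell = ell, s2 = s2, sn2 = sn2, L = ch$L,
       alpha = alpha, jitter = ch$jitter, nll = best$value)
}

# Length-scaled squared distances between row sets, via BLAS.
.scaled_sqdist <- function(A, B, ell) {
  As <- sweep(A, 2L, ell, `/`)
  Bs <- sweep(B, 2L, ell, `/`)
  d2 <- matrix(rowSums(As * As), nrow(A), nrow(B)) +
    matrix(rowSums(Bs * Bs), nrow(A), nrow(B), byrow = TRUE) -
    2 * tcrossprod(As, Bs)
  pmax(d2, 0)
}

# Cross-kernel between new inputs and training inputs (standardized units).
.gp_kstar <- function(gp, Xnew) {
  gp$s2 * .matern52(.scaled_sqdist(Xnew, gp$X, gp$ell))
}

# Posterior mean and (latent-function) variance at new inputs.
.gp_predict_core <- function(gp, Xnew) {
  Ks <- .gp_kstar(gp, Xnew)
  mu <- drop(Ks %*% gp$alpha)
  V <- forwardsolve(t(gp$L), t(Ks))
  var <- pmax(gp$s2 - colSums(V * V), 0)
  list(mean = mu, var = var)
}

# Posterior covariance (latent) over a set of new inputs.
.gp_post_cov <- function(gp, Xnew) {
  Ks <- .gp_kstar(gp, Xnew)
  Kss <- gp$s2 * .matern52(.scaled_sqdist(Xnew, Xnew, gp$ell))
  V <- forwardsolve(t(gp$L), t(Ks))
  Kss - crossprod(V)
}

# Run expr with a temporary RNG seed, restoring the caller's state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
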