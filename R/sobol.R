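#' Generate a (scrambled) Sobol low-discrepancy sequence
#'
#' Produces quasi-random points that cover the unit hypercube far more evenly
#' than i.i.d. uniform draws, which is what makes them attractive for seeding
#' an optimization campaign: the first plate should probe the whole condition
#' space, not cluster by chance.
#'
#' Direction numbers are the Joe--Kuo table (the de facto standard for
#' Sobol sequences), supporting up to 100 dimensions. Randomization uses a
#' seeded digital shift (bitwise XOR of every point with one random binary
#' fraction per dimension), which preserves the sequence's equidistribution
#' while decorrelating repeated runs.
#'
#' @param n number of points.
#' @param d dimension (1--100).
#' @param seed integer seed for the digital shift; `NULL` disables
#'   scrambling and returns the raw sequence (whose first point is the
#'   origin).
#' @return an `n x d` matrix with entries in `[0, 1)`.
#' @export
sobol_points <- function(n, d, seed = NULL) {
  stopifnot(n >= 0, d >= 1)
  if (d > nrow(.sobol_joe_kuo) + 1L)
    stop("sobol_points supports at most ", nrow(.sobol_joe_kuo) + 1L,
         " dimensions")
  if (n == 0) return(matrix(numeric(0), 0, d))
  nbits <- 30L                      # fits in R's 32-bit signed integers
  V <- .sobol_direction_integers(d, nbits)
  X <- matrix(0L, n, d)
  x <- integer(d)
  # Gray-code order: point i flips the direction number indexed by the
  # lowest zero bit of (i-1).
  for (i in seq_len(n)) {
    if (i > 1L) {
      c_ <- .lowest_zero_bit(i - 2L)  # 0-based index of point i-1
      x <- bitwXor(x, V[c_, ])
      X[i, ] <- x
    }
  }
  if (!is.null(seed)) {
    shift <- .sobol_digital_shift(seed, d, nbits)
    X <- matrix(bitwXor(X, rep(shift, each = n)), n, d)
  }
  X / 2^nbits
}

# 1-based index of the lowest zero bit of nonnegative integer m.
.lowest_zero_bit <- function(m) {
  c_ <- 1L
  while (bitwAnd(m, 1L) == 1L) {
    m <- bitwShiftR(m, 1L)
    c_ <- c_ + 1L
  }
  c_
}

# One uniformly random nbits-bit integer per dimension, derived from seed
# without disturbing the caller's RNG state.
.sobol_digital_shift <- function(seed, d, nbits) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  hi <- sample.int(2^15, d, replace = TRUE) - 1L
  lo <- sample.int(2^15, d, replace = TRUE) - 1L
  bitwOr(bitwShiftL(hi, nbits - 15L), lo)
}

# Direction integers: nbits x d matrix; column j holds V_1..V_nbits for
# dimension j, scaled to nbits bits.
.sobol_direction_integers <- function(d, nbits) {
  V <- matrix(0L, nbits, d)
  # dimension 1: van der Corput, m_j = 1 for all j
  V[, 1L] <- bitwShiftL(1L, nbits - seq_len(nbits))
  if (d == 1L) return(V)
  for (dim in 2:d) {
    row <- .sobol_joe_kuo[dim - 1L, ]
    p <- row[1L]
    s <- floor(log2(p))                       # polynomial degree
    a <- bitwAnd(bitwShiftR(p, 1L), bitwShiftL(1L, s - 1L) - 1L)
    m <- row[1L + seq_len(s)]
    v <- integer(nbits)
    for (j in seq_len(min(s, nbits)))
      v[j] <- bitwShiftL(as.integer(m[j]), nbits - j)
    if (nbits > s) {
      for (j in (s + 1L):nbits) {
        new <- bitwXor(v[j - s], bitwShiftR(v[j - s], s))
        if (s > 1L) for (k in seq_len(s - 1L))
          if (bitwAnd(bitwShiftR(a, s - 1L - k), 1L) == 1L)
            new <- bitwXor(new, v[j - k])
        v[j] <- new
      }
    }
    V[, dim] <- v
  }
  V
}
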