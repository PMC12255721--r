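#' Pareto front of a point set (maximization)
#'
#' A point is on the front when no other point is at least as good in every
#' objective and strictly better in one. Duplicates of a front point are all
#' returned.
#'
#' @param points numeric matrix, rows = points, columns = objectives.
#' @return integer vector of row indices (1-based) of the non-dominated set.
#' @export
pareto_front <- function(points) {
  points <- .as_points(points)
  if (nrow(points) == 0L) return(integer(0))
  which(cpp_pareto_mask(points))
}

.as_points <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  storage.mode(points) <- "double"
  if (anyNA(points)) stop("points contain NA")
  points
}

#' Hypervolume dominated by a point set
#'
#' Exact volume (maximization convention) of the region dominated by the set
#' and bounded below by `ref`. Two objectives use an O(n log n) sweep;
#' higher dimensions use exact recursive slicing on the last objective.
#' Dominated and duplicate points do not change the result.
#'
#' @param points numeric matrix (rows = points).
#' @param ref reference point, dominated by every point considered.
#' @export
hypervolume <- function(points, ref) {
  points <- .as_points(points)
  if (nrow(points) == 0L) return(0)
  d <- ncol(points)
  stopifnot(length(ref) == d)
  if (any(sweep(points, 2L, as.numeric(ref)) < 0))
    stop("point below reference point; filter points or lower ref")
  if (d == 1L) return(max(points[, 1L]) - ref[1L])
  if (d == 2L) return(cpp_hv2d(points, as.numeric(ref)))
  .hv_recursive(points, as.numeric(ref))
}

# Exact d>2 hypervolume: slice along the last objective. Sorting points by
# that coordinate (descending), the slab between consecutive levels is the
# (d-1)-volume of the points already seen, projected.
.hv_recursive <- function(points, ref) {
  d <- ncol(points)
  ord <- order(points[, d], decreasing = TRUE)
  z <- points[ord, d]
  proj <- points[ord, -d, drop = FALSE]
  vol <- 0
  for (i in seq_along(z)) {
    z_next <- if (i < length(z)) z[i + 1L] else ref[d]
    h <- z[i] - z_next
    if (h > 0) {
      sub <- proj[seq_len(i), , drop = FALSE]
      v <- if (ncol(sub) == 2L) cpp_hv2d(sub, ref[-d])
           else .hv_recursive(sub, ref[-d])
      vol <- vol + h * v
    }
  }
  vol
}

#' Hypervolume improvement of a candidate over a front
#'
#' `HV(front + candidate) - HV(front)`: nonnegative, and zero exactly when
#' the candidate is dominated by (or equal to) a front point.
#'
#' @param candidate numeric objective vector (or 1-row matrix).
#' @param front matrix of current front points (dominated rows are fine).
#' @param ref reference point.
#' @export
hvi <- function(candidate, front, ref) {
  candidate <- .as_points(candidate)
  front <- .as_points(front)
  if (any(candidate < matrix(ref, nrow(candidate), length(ref), byrow = TRUE)))
    stop("candidate below reference point")
  if (nrow(front) > 0 && any(sweep(front, 2L, as.numeric(ref)) < 0))
    stop("front point below reference point")
  if (ncol(candidate) == 2L)
    return(cpp_hvi2d_many(candidate, front, as.numeric(ref))[1L])
  hypervolume(rbind(front, candidate), ref) - hypervolume(front, ref)
}

#' Hypervolume percentage of a found set relative to a ground truth
#'
#' The benchmark metric: `100 * HV(front(found)) / HV(front(truth))`, both
#' against the same reference point. Reaches 100 exactly when the found
#' front dominates the same region as the true front.
#'
#' @param found matrix of objective vectors identified by an algorithm.
#' @param truth matrix of ground-truth objective vectors.
#' @param ref shared reference point.
#' @export
hypervolume_percent <- function(found, truth, ref) {
  found <- .as_points(found); truth <- .as_points(truth)
  if (nrow(found) == 0L || nrow(truth) == 0L) stop("empty point set")
  hv_truth <- hypervolume(truth[pareto_front(truth), , drop = FALSE], ref)
  if (hv_truth <= 0) stop("ground-truth hypervolume is zero")
  hv_found <- hypervolume(found[pareto_front(found), , drop = FALSE], ref)
  100 * hv_found / hv_truth
}

#' Default reference point for hypervolume bookkeeping
#'
#' Componentwise minimum of the supplied points minus `margin` times each
#' objective's range (a degenerate zero range falls back to a unit margin),
#' guaranteeing every point strictly dominates the reference.
#'
#' @param points matrix of objective vectors.
#' @param margin fraction of the per-objective range, default 0.01.
#' @export
reference_point <- function(points, margin = 0.01) {
  points <- .as_points(points)
  rng <- apply(points, 2L, function(v) max(v) - min(v))
  rng[rng <= 0] <- 1
  apply(points, 2L, min) - margin * rng
}
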