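#' Minkowski distance between screen points
#'
#' Distance in the (possibly warped) stimulus space,
#' \eqn{d(a,b) = (|a_1-b_1|^g + |a_2-b_2|^g)^{1/g}}. The default \eqn{g = 2}
#' is the ordinary Euclidean screen distance; \eqn{g = 1.5} is the
#' conventional choice when allowing for non-linear warping of perceived
#' space. For \eqn{1 < g \le 2} this is a proper metric, so the triangle
#' inequality (and with it the \eqn{[-1, 1]} bound on the bias statistic)
#' holds.
#'
#' @param a,b Points as length-2 numeric `(x, y)` vectors or n x 2 matrices
#'   (rows are recycled against each other when one argument has one row).
#' @param g Minkowski exponent, `1 < g <= 2`.
#' @return Numeric vector of distances in pixels.
#' @examples
#' mink_dist(c(0, 0), c(3, 4))        # 5
#' mink_dist(c(0, 0), c(1, 1), g = 1.5)  # 2^(2/3)
#' @export
mink_dist <- function(a, b, g = 2) {
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g <= 1 || g > 2) {
    stop("`g` must be a single number with 1 < g <= 2", call. = FALSE)
  }
  A <- check_finite(as_point_matrix(a, "a"), "a")
  B <- check_finite(as_point_matrix(b, "b"), "b")
  if (nrow(A) != nrow(B)) {
    if (nrow(A) == 1L) A <- A[rep(1L, nrow(B)), , drop = FALSE]
    else if (nrow(B) == 1L) B <- B[rep(1L, nrow(A)), , drop = FALSE]
    else stop("`a` and `b` have incompatible numbers of points", call. = FALSE)
  }
  unname(rowSums(abs(A - B)^g)^(1 / g))
}

#' Centroid (coordinate-wise mean) of a set of points
#'
#' @param points An n x 2 matrix or data frame of `(x, y)` coordinates.
#' @return Length-2 numeric `(x, y)`.
#' @export
centroid <- function(points) {
  m <- as_point_matrix(points, "points")
  if (nrow(m) == 0L) stop("cannot take the centroid of zero points", call. = FALSE)
  check_finite(m, "points")
  unname(colMeans(m))
}

#' Centroid of all points except one (the "local" centre)
#'
#' The local centre of an outlier layout: the centroid of the encoded
#' locations disregarding the designated spatial outlier.
#'
#' @param points An n x 2 matrix of coordinates, n >= 2.
#' @param outlier_index Integer index of the point to exclude.
#' @return Length-2 numeric `(x, y)`.
#' @export
local_centroid <- function(points, outlier_index) {
  m <- as_point_matrix(points, "points")
  if (nrow(m) < 2L) stop("need at least two points", call. = FALSE)
  if (!is.numeric(outlier_index) || length(outlier_index) != 1L ||
      outlier_index < 1 || outlier_index > nrow(m) || outlier_index != round(outlier_index)) {
    stop("`outlier_index` out of range", call. = FALSE)
  }
  centroid(m[-outlier_index, , drop = FALSE])
}

#' Accuracy-weighted centroid of encoded locations
#'
#' Weighted centre in which more accurately retrieved items count more:
#' item i gets weight \eqn{w_i = (1 - e_i / \sum_j e_j) / (n - 1)}, which
#' is non-negative and sums to exactly 1. With all errors equal every
#' weight is \eqn{1/n} and the plain centroid is recovered; the same
#' fallback is used when every error is zero (the formula's equal-error
#' limit).
#'
#' @param encoded An n x 2 matrix of encoded coordinates, n >= 2.
#' @param errors Numeric vector of n non-negative retrieval errors (pixels).
#' @return Length-2 numeric `(x, y)`.
#' @export
accuracy_weighted_centroid <- function(encoded, errors) {
  m <- as_point_matrix(encoded, "encoded")
  n <- nrow(m)
  if (n < 2L) stop("need at least two encoded points", call. = FALSE)
  if (!is.numeric(errors) || length(errors) != n || any(!is.finite(errors)) || any(errors < 0)) {
    stop("`errors` must be ", n, " finite non-negative values", call. = FALSE)
  }
  total <- sum(errors)
  if (total == 0) return(centroid(m))
  w <- (1 - errors / total) / (n - 1)
  c(sum(w * m[, 1]), sum(w * m[, 2]))
}
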