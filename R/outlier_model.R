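#' The 81-point outlier-weight grid
#'
#' Candidate outlier weights from 0 to 1 in steps of 0.0125.
#'
#' @return Numeric vector of length 81.
#' @export
outlier_weight_grid <- function() seq(0, 1, by = 0.0125)

#' Simulated centre under a given outlier weight
#'
#' The weighted centre assigning weight `w` to the encoded outlier and
#' `(1 - w) / (n - 1)` to each of the other items:
#' `w = 0` gives the local centre ignoring the outlier, `w = 1/n` the
#' global centroid of all items, `w = 1` the outlier itself. The candidate
#' centres trace the straight segment from the local centre to the outlier
#' as `w` runs over `[0, 1]`.
#'
#' @param layout A `spatial_layout` with a designated outlier.
#' @param outlier_weight Weight in `[0, 1]`.
#' @return Length-2 numeric centre.
#' @export
weighted_center_for <- function(layout, outlier_weight) {
  if (!is.numeric(outlier_weight) || length(outlier_weight) != 1L ||
      outlier_weight < 0 || outlier_weight > 1) {
    stop("`outlier_weight` must be a single value in [0, 1]", call. = FALSE)
  }
  o <- outlier_point(layout) # errors if no outlier designated
  l <- local_center(layout)
  outlier_weight * o + (1 - outlier_weight) * l
}

#' Estimate the outlier's weight in a reported centre
#'
#' Grid search over the 81 candidate weights: the Euclidean distance from
#' the reported centre to each simulated centre is evaluated and the weight
#' with the smallest distance is the estimate. Ties are broken toward the
#' smaller weight (conservative toward discounting the outlier; exact ties
#' have measure zero on continuous data). The equal-weight benchmark
#' `1 / n_items` (0.125 for eight items) is carried alongside for the
#' over-weighting comparison.
#'
#' @param reported_center Length-2 numeric reported centre.
#' @param layout A `spatial_layout` with a designated outlier.
#' @return An `outlier_weight_fit` list: `weight_grid`, `distances`,
#'   `estimated_weight`, `min_distance`, `equal_weight_benchmark`.
#' @export
estimate_outlier_weight <- function(reported_center, layout) {
  reported_center <- check_finite(as.numeric(reported_center), "reported_center")
  grid <- outlier_weight_grid()
  o <- outlier_point(layout)
  l <- local_center(layout)
  centers <- cbind(l[1] + grid * (o[1] - l[1]), l[2] + grid * (o[2] - l[2]))
  d <- mink_dist(centers, reported_center, g = 2)
  best <- which.min(d) # first minimum = smallest weight on ties
  structure(
    list(weight_grid = grid,
         distances = d,
         estimated_weight = grid[best],
         min_distance = d[best],
         equal_weight_benchmark = 1 / n_items(layout)),
    class = "outlier_weight_fit"
  )
}

#' @export
print.outlier_weight_fit <- function(x, ...) {
  cat(sprintf(
    "<outlier_weight_fit> estimated weight %.4f (min distance %.1f px; equal-weight benchmark %.4f)\n",
    x$estimated_weight, x$min_distance, x$equal_weight_benchmark))
  invisible(x)
}

#' Continuous (off-grid) outlier-weight diagnostic
#'
#' The orthogonal projection of the reported centre onto the local-centre to
#' outlier segment, clamped to `[0, 1]` — the continuous counterpart of the
#' grid estimate, provided as a diagnostic only (the headline estimator is
#' grid-based).
#'
#' @inheritParams estimate_outlier_weight
#' @return A single weight in `[0, 1]`.
#' @export
outlier_weight_continuous <- function(reported_center, layout) {
  reported_center <- check_finite(as.numeric(reported_center), "reported_center")
  o <- outlier_point(layout)
  l <- local_center(layout)
  v <- o - l
  denom <- sum(v^2)
  if (denom == 0) return(0)
  min(1, max(0, sum((reported_center - l) * v) / denom))
}

#' Outlier-weight fits across a cohort
#'
#' @param cohort A `memory_cohort` whose layout has a designated outlier.
#' @return Tibble with one row per (participant, session): the estimated
#'   weight and its minimum distance.
#' @export
cohort_outlier_weights <- function(cohort) {
  rows <- lapply(cohort$records, function(r) {
    fit <- estimate_outlier_weight(r$reported_center, cohort$layout)
    tibble::tibble(
      participant_id = r$participant_id,
      session = r$session,
      delay_group = r$delay_group,
      estimated_weight = fit$estimated_weight,
      min_distance = fit$min_distance,
      equal_weight_benchmark = fit$equal_weight_benchmark
    )
  })
  dplyr::bind_rows(rows)
}
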