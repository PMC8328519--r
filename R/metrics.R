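#' Error summary for one participant-session
#'
#' The three accuracy measures of the paradigm:
#' \describe{
#'   \item{item error}{mean distance between each retrieved item and its
#'     encoded location;}
#'   \item{gist error}{distance between the reported centre and the true
#'     centre of the encoded items;}
#'   \item{estimated-centre error}{distance between the centroid of the
#'     retrieved items and the true centre — what gist accuracy would be if
#'     the gist were assembled purely from item memories.}
#' }
#'
#' @param record A `retrieval_record`.
#' @param layout The `spatial_layout`.
#' @param g Minkowski exponent for distances (2 = Euclidean).
#' @return An `error_summary` list: `per_item_error` (named), `item_error`,
#'   `gist_error`, `estimated_center_error`.
#' @export
error_summary <- function(record, layout, g = 2) {
  enc <- layout_points(layout)
  per_item <- mink_dist(record$retrieved, enc, g = g)
  names(per_item) <- rownames(enc)
  true_center <- encoded_centroid(layout)
  structure(
    list(
      per_item_error = per_item,
      item_error = mean(per_item),
      gist_error = mink_dist(record$reported_center, true_center, g = g),
      estimated_center_error = mink_dist(centroid(record$retrieved), true_center, g = g)
    ),
    class = "error_summary"
  )
}

#' Chance baselines implied by the layout geometry
#'
#' The error a strategy-free responder would achieve, computed from the
#' layout alone: clicking the screen centre on every item trial
#' (`item_vs_screen_center`), clicking the true centre on every item trial
#' (`item_vs_encoded_center`), and clicking the screen centre on the gist
#' trial (`gist_vs_screen_center`).
#'
#' @param layout A `spatial_layout`.
#' @param g Minkowski exponent.
#' @return A `chance_baselines` list of the three pixel values (unrounded;
#'   published values are conventionally reported to the nearest pixel).
#' @export
chance_baselines <- function(layout, g = 2) {
  enc <- layout_points(layout)
  sc <- screen_center(layout$screen)
  true_center <- encoded_centroid(layout)
  structure(
    list(
      item_vs_screen_center = mean(mink_dist(enc, sc, g = g)),
      item_vs_encoded_center = mean(mink_dist(enc, true_center, g = g)),
      gist_vs_screen_center = mink_dist(true_center, sc, g = g)
    ),
    class = "chance_baselines"
  )
}

#' @export
print.chance_baselines <- function(x, ...) {
  cat(sprintf(paste0(
    "<chance_baselines> item vs screen centre %.1f px, ",
    "item vs encoded centre %.1f px, gist vs screen centre %.1f px\n"),
    x$item_vs_screen_center, x$item_vs_encoded_center, x$gist_vs_screen_center))
  invisible(x)
}

#' Gist-based bias of a single retrieved item
#'
#' The signed, error-normalised displacement of a retrieval toward a
#' reference centre:
#' \deqn{bias = \frac{d(encoded, centre) - d(retrieved, centre)}{d(encoded, retrieved)}}
#' Positive values indicate attraction toward the centre, negative values
#' repulsion; the triangle inequality bounds the value to \eqn{[-1, 1]} for
#' every Minkowski exponent in (1, 2]. A perfect retrieval (0/0) is defined
#' as bias 0, the numerator being 0 as well.
#'
#' @param encoded Encoded location (length-2).
#' @param retrieved Retrieved location(s): length-2 or n x 2 matrix.
#' @param center Reference centre (length-2).
#' @param g Minkowski exponent.
#' @return Numeric vector of bias values in `[-1, 1]`.
#' @export
item_bias <- function(encoded, retrieved, center, g = 2) {
  e <- mink_dist(encoded, retrieved, g = g)
  b <- (mink_dist(encoded, center, g = g) - mink_dist(retrieved, center, g = g)) / e
  b[e == 0] <- 0
  b
}

#' Specification of the bias reference centre
#'
#' @param mode Which centre to measure bias against: the participant's
#'   `"reported"` centre, the `"encoded_center"` (true centroid), the
#'   `"accuracy_weighted"` centroid (items with smaller retrieval error
#'   weighted more), or the `"local"` centre (encoded centroid excluding
#'   the outlier; requires an outlier layout).
#' @param g Minkowski exponent used for every distance in the bias analysis.
#' @return A `bias_center_spec` object.
#' @export
bias_center_spec <- function(mode = c("reported", "encoded_center",
                                      "accuracy_weighted", "local"),
                             g = 2) {
  mode <- match.arg(mode)
  if (!is.numeric(g) || length(g) != 1L || g <= 1 || g > 2) {
    stop("`g` must satisfy 1 < g <= 2", call. = FALSE)
  }
  structure(list(mode = mode, g = g), class = "bias_center_spec")
}

#' Resolve the reference centre for a record under a bias-centre spec
#'
#' @param record A `retrieval_record`.
#' @param layout The `spatial_layout`.
#' @param spec A [bias_center_spec()].
#' @return Length-2 numeric centre.
#' @export
resolve_bias_center <- function(record, layout, spec) {
  switch(spec$mode,
    reported = record$reported_center,
    encoded_center = encoded_centroid(layout),
    accuracy_weighted = {
      enc <- layout_points(layout)
      accuracy_weighted_centroid(enc, mink_dist(record$retrieved, enc, g = spec$g))
    },
    local = {
      if (is.null(layout$outlier_label)) {
        stop("local bias centre requires a layout with an outlier", call. = FALSE)
      }
      local_center(layout)
    }
  )
}

#' Participant-level gist-based bias
#'
#' Per-item bias for every item against the centre resolved from `spec`,
#' and the participant value as their unweighted mean. In `local` mode the
#' outlier item is included in the average (its own bias is also reported
#' separately so outlier-only analyses remain possible).
#'
#' @param record A `retrieval_record`.
#' @param layout The `spatial_layout`.
#' @param spec A [bias_center_spec()].
#' @param zero_error How to treat perfectly retrieved items: `"zero"`
#'   (default; they contribute bias 0) or `"drop"` (excluded from the mean).
#' @return A `bias_result` list: `per_item_bias` (named), `participant_bias`,
#'   `center_used`, `mode`, `g`, and `outlier_bias` when the layout has one.
#' @export
participant_bias <- function(record, layout, spec = bias_center_spec("reported"),
                             zero_error = c("zero", "drop")) {
  zero_error <- match.arg(zero_error)
  center <- resolve_bias_center(record, layout, spec)
  enc <- layout_points(layout)
  per_item <- vapply(seq_len(nrow(enc)), function(i) {
    item_bias(enc[i, ], record$retrieved[i, ], center, g = spec$g)
  }, numeric(1))
  names(per_item) <- rownames(enc)
  include <- if (zero_error == "drop") {
    mink_dist(record$retrieved, enc, g = spec$g) > 0
  } else rep(TRUE, length(per_item))
  participant <- if (any(include)) mean(per_item[include]) else 0
  res <- list(per_item_bias = per_item, participant_bias = participant,
              center_used = center, mode = spec$mode, g = spec$g)
  if (!is.null(layout$outlier_label)) {
    res$outlier_bias <- unname(per_item[layout$outlier_label])
  }
  structure(res, class = "bias_result")
}

#' Tidy error table for a cohort
#'
#' @param cohort A `memory_cohort`.
#' @param g Minkowski exponent.
#' @return Tibble with one row per (participant, session): the three error
#'   measures, plus the outlier item's own error for outlier layouts.
#' @export
cohort_errors <- function(cohort, g = 2) {
  has_outlier <- !is.null(cohort$layout$outlier_label)
  rows <- lapply(cohort$records, function(r) {
    es <- error_summary(r, cohort$layout, g = g)
    out <- tibble::tibble(
      participant_id = r$participant_id,
      session = r$session,
      delay_group = r$delay_group,
      item_error = es$item_error,
      gist_error = es$gist_error,
      estimated_center_error = es$estimated_center_error
    )
    if (has_outlier) out$outlier_error <- unname(es$per_item_error[cohort$layout$outlier_label])
    out
  })
  dplyr::bind_rows(rows)
}

#' Tidy bias table for a cohort
#'
#' @param cohort A `memory_cohort`.
#' @param specs List of [bias_center_spec()]s to evaluate.
#' @param zero_error Passed to [participant_bias()].
#' @return Tibble with one row per (participant, session, mode).
#' @export
cohort_bias <- function(cohort, specs = list(bias_center_spec("reported")),
                        zero_error = "zero") {
  rows <- list()
  for (spec in specs) {
    for (r in cohort$records) {
      b <- participant_bias(r, cohort$layout, spec, zero_error = zero_error)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant_id = r$participant_id,
        session = r$session,
        delay_group = r$delay_group,
        mode = spec$mode,
        g = spec$g,
        participant_bias = b$participant_bias,
        outlier_bias = if (!is.null(b$outlier_bias)) b$outlier_bias else NA_real_
      )
    }
  }
  dplyr::bind_rows(rows)
}
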