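#' Participant exclusion rules
#'
#' Applies the cohort preprocessing rules:
#' \describe{
#'   \item{gist_out_of_scope (exp1 only)}{the Session-1 reported-centre
#'     error exceeds the gist chance baseline (the distance from the screen
#'     centre to the true centre) — the reported gist fell outside the scope
#'     of the learned landmarks;}
#'   \item{outlier_misplaced (exp2 only)}{the outlier item's retrieval error
#'     exceeds the distance from the screen centre to the encoded outlier at
#'     any session — the participant put the outlier among the main cluster,
#'     which would spuriously inflate global bias;}
#'   \item{three_sd}{item or gist error at any session more than 3 SD worse
#'     than the (remaining) cohort mean for that session and measure.}
#' }
#' Participant-local rules run first; the 3-SD screen is then evaluated in
#' one pass on the remainder (no iterative re-exclusion). With fewer than
#' two remaining participants the SD rule is skipped with a warning.
#'
#' @param cohort A `memory_cohort`.
#' @param experiment `"exp1"` (no-outlier design, between-subject delays) or
#'   `"exp2"` (outlier design, within-subject sessions).
#' @param g Minkowski exponent for the error computations.
#' @return A list with `cohort` (retained records) and `report`, an
#'   `exclusion_report` holding `excluded` (named character vector of
#'   reasons, names = participant ids), `retained_n`, and the per-session
#'   3-SD thresholds used.
#' @export
apply_exclusions <- function(cohort, experiment = c("exp1", "exp2"), g = 2) {
  experiment <- match.arg(experiment)
  errs <- cohort_errors(cohort, g = g)
  sessions <- sort(unique(errs$session))
  first_session <- sessions[1]
  excluded <- character(0)

  if (experiment == "exp1") {
    baseline <- chance_baselines(cohort$layout, g = g)$gist_vs_screen_center
    s1 <- errs[errs$session == first_session, ]
    bad <- unique(s1$participant_id[s1$gist_error > baseline])
    excluded[bad] <- "gist_out_of_scope"
  } else {
    if (is.null(cohort$layout$outlier_label)) {
      stop("exp2 exclusions require a layout with an outlier", call. = FALSE)
    }
    threshold <- mink_dist(screen_center(cohort$layout$screen),
                           outlier_point(cohort$layout), g = g)
    bad <- unique(errs$participant_id[errs$outlier_error > threshold])
    excluded[bad] <- "outlier_misplaced"
  }

  remaining <- errs[!errs$participant_id %in% names(excluded), ]
  thresholds <- NULL
  n_remaining <- length(unique(remaining$participant_id))
  if (n_remaining < 2L) {
    warning("fewer than two participants remain; 3-SD rule skipped", call. = FALSE)
  } else {
    thresholds <- dplyr::summarise(
      tidyr::pivot_longer(remaining[, c("participant_id", "session",
                                        "item_error", "gist_error")],
                          c("item_error", "gist_error"),
                          names_to = "measure", values_to = "error"),
      threshold = mean(.data$error) + 3 * stats::sd(.data$error),
      .by = c("session", "measure")
    )
    long <- tidyr::pivot_longer(remaining[, c("participant_id", "session",
                                              "item_error", "gist_error")],
                                c("item_error", "gist_error"),
                                names_to = "measure", values_to = "error")
    long <- dplyr::left_join(long, thresholds, by = c("session", "measure"))
    bad <- unique(long$participant_id[long$error > long$threshold])
    excluded[bad] <- "three_sd"
  }

  keep <- vapply(cohort$records,
                 function(r) !r$participant_id %in% names(excluded), logical(1))
  report <- structure(
    list(excluded = excluded,
         retained_n = length(unique(errs$participant_id)) - length(excluded),
         sd_thresholds = thresholds),
    class = "exclusion_report"
  )
  list(cohort = memory_cohort(cohort$layout, cohort$records[keep]),
       report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("<exclusion_report> %d retained, %d excluded\n",
              x$retained_n, length(x$excluded)))
  if (length(x$excluded)) {
    for (reason in unique(x$excluded)) {
      ids <- names(x$excluded)[x$excluded == reason]
      cat(sprintf("  %s: %s\n", reason, paste(ids, collapse = ", ")))
    }
  }
  invisible(x)
}

#' Write an exclusion report as JSON
#'
#' @param report An `exclusion_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(report, path) {
  obj <- list(
    excluded = as.list(report$excluded),
    retained_n = report$retained_n
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
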