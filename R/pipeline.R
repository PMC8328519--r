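#' Configuration for a full cohort analysis run
#'
#' @param experiment `"exp1"` or `"exp2"`; selects the exclusion rule set.
#' @param bias_modes Character vector of bias-centre modes to evaluate
#'   (see [bias_center_spec()]); at least one.
#' @param g Minkowski exponent applied throughout.
#' @param null A [null_config()] for the Monte Carlo null models (its seed
#'   is overridden by `seed`).
#' @param run_null Run the null models and gap analysis? With all toggles
#'   off the pipeline reduces to metrics-only output at no simulation cost.
#' @param exclusions Apply the participant exclusion rules?
#' @param swap_correction Detect and correct misbound item pairs first?
#' @param seed Integer seed recorded in (and governing) all stochastic
#'   outputs.
#' @return A `run_config` object.
#' @export
run_config <- function(experiment = c("exp1", "exp2"),
                       bias_modes = "reported", g = 2,
                       null = null_config(), run_null = TRUE,
                       exclusions = TRUE, swap_correction = TRUE,
                       seed = 1L) {
  experiment <- match.arg(experiment)
  if (length(bias_modes) < 1) stop("need at least one bias mode", call. = FALSE)
  null$seed <- as.integer(seed)
  null$g <- g
  structure(
    list(experiment = experiment, bias_modes = bias_modes, g = g,
         null = null, run_null = run_null, exclusions = exclusions,
         swap_correction = swap_correction, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full analysis pipeline on a cohort
#'
#' Orchestrates the stages in order: swap correction, participant
#' exclusions, error summaries and session change scores, participant bias
#' under each requested centre mode, the item-only and item-plus-gist null
#' models with their bias gaps (first bias mode), and — for outlier
#' layouts — the outlier-weight grid fits. Fully reproducible from
#' (cohort, config, seed).
#'
#' @param cohort A `memory_cohort`, or a path to a trials CSV (then
#'   `layout` must be given).
#' @param config A [run_config()].
#' @param layout Optional `spatial_layout` (or path to a layout JSON) when
#'   `cohort` is a CSV path.
#' @return A `gist_analysis` list of tidy tables: `errors`,
#'   `error_changes`, `bias`, `gaps` (when `run_null`), `outlier_weights`
#'   (outlier layouts), `swaps`, `exclusions`, and the `config`.
#' @export
run_analysis <- function(cohort, config = run_config(), layout = NULL) {
  if (is.character(cohort)) {
    if (is.character(layout)) layout <- read_layout_json(layout)
    if (is.null(layout)) stop("reading a trials CSV requires `layout`", call. = FALSE)
    cohort <- read_cohort(cohort, layout)
  }
  stopifnot(inherits(cohort, "memory_cohort"))

  swaps <- NULL
  if (config$swap_correction) {
    corrected <- correct_cohort_swaps(cohort, g = config$g)
    cohort <- corrected$cohort
    swaps <- corrected$swaps
  }

  report <- NULL
  if (config$exclusions) {
    excl <- apply_exclusions(cohort, config$experiment, g = config$g)
    cohort <- excl$cohort
    report <- excl$report
  }

  errors <- cohort_errors(cohort, g = config$g)
  n_sessions <- length(unique(errors$session))
  changes <- if (n_sessions >= 2) compare_sessions(errors) else {
    warning("single session: no change scores computed", call. = FALSE)
    NULL
  }

  specs <- lapply(config$bias_modes, bias_center_spec, g = config$g)
  bias <- cohort_bias(cohort, specs)

  gaps <- NULL
  if (config$run_null) {
    gaps <- bias_gap_analysis(cohort, specs[[1]], config$null)
  }

  weights <- if (!is.null(cohort$layout$outlier_label)) {
    cohort_outlier_weights(cohort)
  }

  structure(
    list(errors = errors, error_changes = changes, bias = bias, gaps = gaps,
         outlier_weights = weights, swaps = swaps, exclusions = report,
         config = config, cohort = cohort),
    class = "gist_analysis"
  )
}

#' @export
print.gist_analysis <- function(x, ...) {
  cat(sprintf("<gist_analysis> %s: %d participants, %d records\n",
              x$config$experiment,
              length(unique(x$errors$participant_id)), nrow(x$errors)))
  cat("  tables:", paste(names(Filter(Negate(is.null), x))[1:5], collapse = ", "), "\n")
  invisible(x)
}

#' Session change scores for the error measures
#'
#' Change relative to the first session (later session minus Session 1),
#' per participant and measure — the construction entering the
#' delay-by-memory-type comparisons. Pairwise rank tests between measures
#' are available through [session_change_tests()].
#'
#' @param errors The tidy error table from [cohort_errors()] (or the
#'   `errors` element of a [run_analysis()] result).
#' @param measures Error columns to difference.
#' @return Tibble with one row per (participant, later session, measure)
#'   holding the change score.
#' @export
compare_sessions <- function(errors,
                             measures = c("item_error", "gist_error",
                                          "estimated_center_error")) {
  sessions <- sort(unique(errors$session))
  if (length(sessions) < 2) {
    stop("change scores need at least two sessions", call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    errors[, c("participant_id", "session", "delay_group", measures)],
    dplyr::all_of(measures), names_to = "measure", values_to = "error"
  )
  base <- long[long$session == sessions[1],
               c("participant_id", "measure", "error")]
  names(base)[3] <- "baseline"
  rest <- long[long$session != sessions[1], ]
  out <- dplyr::left_join(rest, base, by = c("participant_id", "measure"))
  out$change <- out$error - out$baseline
  out[, c("participant_id", "delay_group", "session", "measure", "change")]
}

#' Rank tests on session change scores
#'
#' Paired Wilcoxon signed-rank test of item-error change against gist-error
#' change within each delay group and later session (the directional
#' "item memory decays faster" comparison), delegated to
#' [stats::wilcox.test()].
#'
#' @param changes Output of [compare_sessions()].
#' @param alternative Alternative hypothesis for item change minus gist
#'   change (default `"greater"`).
#' @return Tibble with one row per (delay group, session): the median
#'   changes, V statistic and p value.
#' @export
session_change_tests <- function(changes, alternative = "greater") {
  wide <- tidyr::pivot_wider(
    changes[changes$measure %in% c("item_error", "gist_error"), ],
    names_from = "measure", values_from = "change"
  )
  dplyr::summarise(
    wide,
    n = dplyr::n(),
    median_item_change = stats::median(.data$item_error),
    median_gist_change = stats::median(.data$gist_error),
    statistic = stats::wilcox.test(.data$item_error, .data$gist_error,
                                   paired = TRUE, exact = FALSE,
                                   alternative = alternative)$statistic,
    p_value = stats::wilcox.test(.data$item_error, .data$gist_error,
                                 paired = TRUE, exact = FALSE,
                                 alternative = alternative)$p.value,
    .by = c("delay_group", "session")
  )
}

#' Write all analysis tables to a directory
#'
#' CSV per table plus a JSON sidecar echoing the configuration (seed
#' included) for provenance.
#'
#' @param analysis A `gist_analysis` from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("errors", "error_changes", "bias", "gaps", "outlier_weights", "swaps")
  for (nm in tables) {
    if (!is.null(analysis[[nm]])) {
      readr::write_csv(analysis[[nm]], file.path(dir, paste0(nm, ".csv")), na = "")
    }
  }
  if (!is.null(analysis$exclusions)) {
    write_exclusion_report(analysis$exclusions, file.path(dir, "exclusions.json"))
  }
  cfg <- analysis$config
  jsonlite::write_json(
    list(experiment = cfg$experiment, bias_modes = cfg$bias_modes, g = cfg$g,
         n_simulations = cfg$null$n_simulations, n_angles = cfg$null$n_angles,
         run_null = cfg$run_null, exclusions = cfg$exclusions,
         swap_correction = cfg$swap_correction, seed = cfg$seed),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
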