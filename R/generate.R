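#' Generative parameters for synthetic cohorts
#'
#' Describes a synthetic cohort with the statistical structure the analysis
#' assumes: per-item retrieval errors whose magnitude grows with delay, a
#' gist pull mixing a uniform retrieval direction with the centre-weighted
#' direction law of the item-plus-gist model, a reported centre placed at a
#' weighted centre (outlier layouts) or the true centroid plus isotropic
#' noise, and occasional misbinding swaps.
#'
#' @param n_participants Number of participants.
#' @param sessions Character vector of session labels in temporal order.
#' @param schedule Data frame with columns `session`, optionally
#'   `delay_group`, and `item_error_scale` (pixels; folded-normal location
#'   of per-item error magnitudes), `gist_error_scale` (pixels; isotropic SD
#'   of the reported-centre noise) and `gist_pull` (mixture weight in
#'   `[0, 1]` of the centre-weighted direction law).
#' @param delay_groups Named integer vector of group sizes (e.g.
#'   `c("24h" = 44, "1week" = 43, "1month" = 43)`), or `NULL` for a single
#'   `within_subject` group.
#' @param outlier_weight Weight of the outlier in the generated reported
#'   centre (outlier layouts only; `1/n` reproduces the plain centroid).
#' @param error_cv Coefficient of variation of the per-item error
#'   magnitudes (folded normal, default 0.3).
#' @param swap_rate Probability that one random item pair is exchanged in a
#'   generated record.
#' @param pull_center Which centre the gist pull points to: `"auto"`
#'   (local centre for outlier layouts, global centroid otherwise),
#'   `"global"`, or `"local"`.
#' @param seed Integer base seed; per-(participant, session) substreams are
#'   derived from it.
#' @return A `generative_params` object.
#' @export
generative_params <- function(n_participants, sessions, schedule,
                              delay_groups = NULL, outlier_weight = NULL,
                              error_cv = 0.3, swap_rate = 0,
                              pull_center = c("auto", "global", "local"),
                              seed = 1L) {
  pull_center <- match.arg(pull_center)
  schedule <- as.data.frame(schedule)
  needed <- c("session", "item_error_scale", "gist_error_scale", "gist_pull")
  if (!all(needed %in% names(schedule))) {
    stop("`schedule` needs columns ", paste(needed, collapse = ", "), call. = FALSE)
  }
  if (any(schedule$item_error_scale < 0) || any(schedule$gist_error_scale < 0) ||
      any(schedule$gist_pull < 0) || any(schedule$gist_pull > 1)) {
    stop("schedule scales must be >= 0 and gist_pull in [0, 1]", call. = FALSE)
  }
  if (!is.null(delay_groups)) {
    if (is.null(names(delay_groups)) || sum(delay_groups) != n_participants) {
      stop("`delay_groups` must be a named vector summing to `n_participants`",
           call. = FALSE)
    }
  }
  if (!is.null(outlier_weight) &&
      (outlier_weight < 0 || outlier_weight > 1)) {
    stop("`outlier_weight` must be in [0, 1]", call. = FALSE)
  }
  if (swap_rate < 0 || swap_rate > 1) stop("`swap_rate` must be in [0, 1]", call. = FALSE)
  structure(
    list(n_participants = as.integer(n_participants),
         sessions = as.character(sessions),
         schedule = schedule,
         delay_groups = delay_groups,
         outlier_weight = outlier_weight,
         error_cv = error_cv,
         swap_rate = swap_rate,
         pull_center = pull_center,
         seed = as.integer(seed)),
    class = "generative_params"
  )
}

schedule_row <- function(params, session, delay_group) {
  sch <- params$schedule
  hit <- sch$session == session
  if ("delay_group" %in% names(sch)) {
    hit <- hit & (is.na(sch$delay_group) | sch$delay_group == delay_group)
  }
  if (!any(hit)) {
    stop("no schedule row for session '", session, "' / group '", delay_group, "'",
         call. = FALSE)
  }
  sch[which(hit)[1], ]
}

generative_pull_center <- function(layout, params) {
  use_local <- switch(params$pull_center,
    auto = !is.null(layout$outlier_label),
    global = FALSE,
    local = TRUE
  )
  if (use_local) local_center(layout) else encoded_centroid(layout)
}

#' Generate one synthetic participant-session record
#'
#' Each item's error magnitude is drawn as
#' `|Normal(item_error_scale, error_cv * item_error_scale)|`; its direction
#' is uniform with probability `1 - gist_pull` and otherwise follows the
#' centre-weighted law of [angle_probabilities()] toward the generative pull
#' centre. The reported centre is the weighted centre (or the plain
#' centroid for layouts without an outlier) plus isotropic
#' `Normal(0, gist_error_scale)` noise; off-screen draws are redrawn. With
#' probability `swap_rate` one random item pair's retrievals are exchanged.
#'
#' @param layout A `spatial_layout`.
#' @param params A [generative_params()] object.
#' @param participant_id,session Identifiers; together with `params$seed`
#'   they determine the record's RNG substream.
#' @param delay_group Group label used for the schedule lookup.
#' @return A `retrieval_record`.
#' @export
generate_participant <- function(layout, params, participant_id, session,
                                 delay_group = "within_subject") {
  row <- schedule_row(params, session, delay_group)
  pull <- generative_pull_center(layout, params)
  enc <- layout_points(layout)
  screen <- layout$screen
  with_seed(derive_seed(params$seed, participant_id, session), {
    n <- nrow(enc)
    ret <- matrix(0, n, 2, dimnames = list(rownames(enc), NULL))
    for (i in seq_len(n)) {
      e <- abs(stats::rnorm(1, row$item_error_scale,
                            params$error_cv * row$item_error_scale))
      if (e == 0) {
        ret[i, ] <- enc[i, ]
        next
      }
      if (stats::runif(1) < row$gist_pull) {
        ap <- angle_probabilities(enc[i, ], e, pull, screen)
        idx <- sample.int(length(ap$prob), 1L, prob = ap$prob)
        ret[i, ] <- ap$points[idx, ]
      } else {
        ret[i, ] <- sample_uniform_circle(enc[i, ], e, screen, 1L, 1e4)
      }
    }
    base <- if (!is.null(layout$outlier_label)) {
      weighted_center_for(layout, params$outlier_weight %||% (1 / n))
    } else {
      encoded_centroid(layout)
    }
    repeat {
      center <- base + stats::rnorm(2, 0, row$gist_error_scale)
      if (in_bounds(center, screen)) break
    }
    if (n >= 2 && stats::runif(1) < params$swap_rate) {
      pair <- sample.int(n, 2L)
      tmp <- ret[pair[1], ]
      ret[pair[1], ] <- ret[pair[2], ]
      ret[pair[2], ] <- tmp
    }
    retrieval_record(participant_id, session, delay_group, ret, center, layout)
  })
}

#' Generate a full synthetic cohort
#'
#' Participants are labelled `P001`, `P002`, ... and assigned to delay
#' groups in the order of `params$delay_groups`; every participant
#' contributes one record per session. Records are reproducible per
#' (participant, session) substream, so the result is identical whatever
#' the generation order.
#'
#' @param layout A `spatial_layout`.
#' @param params A [generative_params()] object.
#' @return A `memory_cohort`.
#' @export
generate_cohort <- function(layout, params) {
  groups <- if (is.null(params$delay_groups)) {
    rep("within_subject", params$n_participants)
  } else {
    rep(names(params$delay_groups), params$delay_groups)
  }
  ids <- sprintf("P%03d", seq_len(params$n_participants))
  records <- list()
  for (p in seq_along(ids)) {
    for (s in params$sessions) {
      records[[length(records) + 1L]] <-
        generate_participant(layout, params, ids[p], s, groups[p])
    }
  }
  memory_cohort(layout, records)
}

#' Shipped study presets
#'
#' Loads one of the two shipped JSON presets: `"exp1"` (six items, no
#' outlier, between-subject delay groups of 44/43/43 participants over two
#' sessions, chance baselines 348/267/270 px, pairwise separation above
#' 160 px) or `"exp2"` (eight items with one outlier 573 px from the screen
#' centre, 43 participants over three within-subject sessions, chance
#' baselines 386/262/223 px, separation above 100 px).
#'
#' @param name `"exp1"` or `"exp2"`.
#' @return A list with `name`, `screen`, `n_items`, `targets`
#'   (a [calibration_targets()]) and `params` (a [generative_params()]).
#' @export
load_preset <- function(name = c("exp1", "exp2")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, "_params.json"),
                      package = "gistbias", mustWork = TRUE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cal <- obj$calibration
  targets <- calibration_targets(
    item_vs_screen_center = cal$item_vs_screen_center,
    item_vs_encoded_center = cal$item_vs_encoded_center,
    gist_vs_screen_center = cal$gist_vs_screen_center,
    min_pair_separation = cal$min_pair_separation,
    outlier_offset = cal$outlier_offset
  )
  gen <- obj$generative
  params <- generative_params(
    n_participants = gen$n_participants,
    sessions = gen$sessions,
    schedule = gen$schedule,
    delay_groups = if (!is.null(gen$delay_groups)) unlist(gen$delay_groups),
    outlier_weight = gen$outlier_weight,
    error_cv = gen$error_cv,
    swap_rate = gen$swap_rate,
    pull_center = gen$pull_center %||% "auto",
    seed = gen$seed
  )
  list(name = name,
       screen = screen_def(obj$screen$width, obj$screen$height),
       n_items = obj$n_items,
       targets = targets,
       params = params)
}

#' Calibrated layout for a shipped preset
#'
#' @param preset A preset from [load_preset()] (or its name).
#' @param seed Seed for the calibration optimiser.
#' @return A calibrated `spatial_layout`.
#' @export
preset_layout <- function(preset, seed = 1L) {
  if (is.character(preset)) preset <- load_preset(preset)
  calibrate_layout(preset$targets, preset$n_items, preset$screen, seed = seed)
}
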