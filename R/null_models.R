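#' Configuration for the Monte Carlo null models
#'
#' @param n_simulations Number of simulated cohorts per participant
#'   (default 1000).
#' @param n_angles Number of candidate angles on the error circle for the
#'   item-plus-gist model (default 200).
#' @param seed Integer base seed; per-(participant, session, model)
#'   substreams are derived deterministically from it, so results do not
#'   depend on the order in which participants are simulated.
#' @param model `"item_only"` (uniform retrieval direction) or
#'   `"item_plus_gist"` (direction probabilities decreasing with distance to
#'   the reference centre).
#' @param g Minkowski exponent for all distances.
#' @param max_resample Cap on boundary-rejection redraw rounds before a
#'   geometry error is raised.
#' @return A `null_config` object.
#' @export
null_config <- function(n_simulations = 1000, n_angles = 200, seed = 1L,
                        model = c("item_only", "item_plus_gist"), g = 2,
                        max_resample = 1e4) {
  model <- match.arg(model)
  if (n_simulations < 1) stop("`n_simulations` must be >= 1", call. = FALSE)
  if (n_angles < 3) stop("`n_angles` must be >= 3", call. = FALSE)
  structure(
    list(n_simulations = as.integer(n_simulations),
         n_angles = as.integer(n_angles),
         seed = as.integer(seed), model = model, g = g,
         max_resample = max_resample),
    class = "null_config"
  )
}

#' Direction probabilities on the error circle
#'
#' For an item retrieved with error `e`, the candidate retrievals are the
#' `n_angles` equally spaced points on the circle of radius `e` about the
#' encoded location (angle 0 on the +x axis, candidates at the centres of
#' equal arcs), restricted to points inside the screen. Each in-bounds
#' candidate i at distance \eqn{d_i} from the reference centre gets
#' probability
#' \deqn{P_i = \frac{d_i - \max_j d_j}{\sum_j (d_j - \max_j d_j)},}
#' so the candidate farthest from the centre gets probability 0 and
#' probability decreases with distance to the centre. When every candidate
#' is equidistant from the centre (e.g. the centre coincides with the
#' encoded location) the distribution degenerates to uniform.
#'
#' @param encoded Encoded location (length-2).
#' @param error Error radius in pixels (> 0).
#' @param center Reference centre (length-2).
#' @param screen A `screen` object.
#' @param n_angles Number of candidate angles.
#' @param g Minkowski exponent for the distance to the centre.
#' @return A list with `angles`, `points` (in-bounds candidates, m x 2) and
#'   `prob` (length m, sums to 1).
#' @export
angle_probabilities <- function(encoded, error, center, screen,
                                n_angles = 200, g = 2) {
  if (!is.numeric(error) || length(error) != 1L || !is.finite(error) || error <= 0) {
    stop("`error` must be a single positive radius", call. = FALSE)
  }
  encoded <- check_finite(as.numeric(encoded), "encoded")
  theta <- 2 * pi * (seq_len(n_angles) - 0.5) / n_angles
  pts <- cbind(encoded[1] + error * cos(theta), encoded[2] + error * sin(theta))
  ok <- in_bounds(pts, screen)
  if (!any(ok)) {
    stop("no candidate location on the error circle lies within the screen",
         call. = FALSE)
  }
  theta <- theta[ok]
  pts <- pts[ok, , drop = FALSE]
  d <- mink_dist(pts, center, g = g)
  w <- max(d) - d
  total <- sum(w)
  # all candidates (numerically) equidistant from the centre -> uniform
  degenerate <- total == 0 || (max(d) - min(d)) <= 1e-9 * max(1, max(d))
  prob <- if (degenerate) rep(1 / length(d), length(d)) else w / total
  list(angles = theta, points = pts, prob = prob)
}

# Simulate n uniform in-bounds points on the circle of radius `error` about
# `encoded`, by rejection of out-of-bounds draws (the law of "redraw until
# inside"). Returns an n x 2 matrix.
sample_uniform_circle <- function(encoded, error, screen, n, max_resample) {
  theta <- stats::runif(n, 0, 2 * pi)
  pts <- cbind(encoded[1] + error * cos(theta), encoded[2] + error * sin(theta))
  bad <- which(!in_bounds(pts, screen))
  tries <- 0L
  while (length(bad)) {
    tries <- tries + 1L
    if (tries > max_resample) {
      stop("boundary resampling failed: error circle nearly entirely off-screen",
           call. = FALSE)
    }
    th <- stats::runif(length(bad), 0, 2 * pi)
    pts[bad, ] <- cbind(encoded[1] + error * cos(th), encoded[2] + error * sin(th))
    bad <- bad[!in_bounds(pts[bad, , drop = FALSE], screen)]
  }
  pts
}

#' Simulate a participant's null bias distribution
#'
#' Generates `n_simulations` simulated retrieval sets matched to the
#' participant's observed per-item error magnitudes: every simulated
#' retrieval lies at exactly the observed error radius from its encoded
#' location, with direction drawn uniformly (`item_only`) or from
#' [angle_probabilities()] toward `center` (`item_plus_gist`). Draws falling
#' off-screen are redrawn. A zero-error item is simulated at its encoded
#' point and contributes bias 0. Each run's bias is the mean [item_bias()]
#' of its items against the same `center`; the run's simulated
#' estimated-centre error (distance from the simulated retrievals' centroid
#' to the true centre) is recorded alongside.
#'
#' @param record A `retrieval_record`.
#' @param layout The `spatial_layout`.
#' @param center Reference centre for both the direction weighting and the
#'   bias evaluation (length-2).
#' @param config A [null_config()].
#' @return A `null_sim_result` list: `model`, `simulated_bias_mean`,
#'   `bias_per_run`, `estimated_center_error_per_run`, `n_simulations`.
#' @export
simulate_participant <- function(record, layout, center, config = null_config()) {
  enc <- layout_points(layout)
  errors <- mink_dist(record$retrieved, enc, g = config$g)
  n_it <- nrow(enc)
  R <- config$n_simulations
  seed <- derive_seed(config$seed, record$participant_id, record$session, config$model)
  with_seed(seed, {
    bias_mat <- matrix(0, n_it, R)
    sum_x <- numeric(R)
    sum_y <- numeric(R)
    for (i in seq_len(n_it)) {
      e <- errors[i]
      if (e == 0) {
        sum_x <- sum_x + enc[i, 1]
        sum_y <- sum_y + enc[i, 2]
        next # bias contribution 0
      }
      pts <- if (config$model == "item_only") {
        sample_uniform_circle(enc[i, ], e, layout$screen, R, config$max_resample)
      } else {
        ap <- angle_probabilities(enc[i, ], e, center, layout$screen,
                                  n_angles = config$n_angles, g = config$g)
        idx <- sample.int(length(ap$prob), R, replace = TRUE, prob = ap$prob)
        ap$points[idx, , drop = FALSE]
      }
      bias_mat[i, ] <- item_bias(enc[i, ], pts, center, g = config$g)
      sum_x <- sum_x + pts[, 1]
      sum_y <- sum_y + pts[, 2]
    }
    true_center <- encoded_centroid(layout)
    est_err <- mink_dist(cbind(sum_x / n_it, sum_y / n_it), true_center, g = config$g)
    bias_per_run <- colMeans(bias_mat)
    structure(
      list(model = config$model,
           simulated_bias_mean = mean(bias_per_run),
           bias_per_run = bias_per_run,
           estimated_center_error_per_run = est_err,
           n_simulations = R),
      class = "null_sim_result"
    )
  })
}

#' Observed-versus-simulated bias gaps across a cohort
#'
#' For each participant-session, computes the observed bias and the mean
#' bias under both null models against the same reference centre, plus the
#' two gap quantities entering the session-by-delay analyses: observed
#' minus item-only simulated bias (evidence of gist influence beyond item
#' memory alone) and gist-simulated minus observed bias (closeness to the
#' item-plus-gist account).
#'
#' @param cohort A `memory_cohort`.
#' @param spec A [bias_center_spec()] resolving the reference centre.
#' @param config A [null_config()]; its `model` field is ignored — both
#'   models are run.
#' @param zero_error Passed to [participant_bias()].
#' @return Tibble with one row per (participant, session): `observed_bias`,
#'   `sim_item_only`, `sim_item_plus_gist`, `gap_item_only`
#'   (observed - Sim-I), `gap_gist` (Sim-G - observed), and the mean
#'   simulated estimated-centre errors under each model. Bit-for-bit
#'   reproducible given `config$seed`.
#' @export
bias_gap_analysis <- function(cohort, spec = bias_center_spec("reported"),
                              config = null_config(), zero_error = "zero") {
  cfg_i <- config
  cfg_i$model <- "item_only"
  cfg_g <- config
  cfg_g$model <- "item_plus_gist"
  cfg_i$g <- cfg_g$g <- spec$g
  rows <- lapply(cohort$records, function(r) {
    center <- resolve_bias_center(r, cohort$layout, spec)
    obs <- participant_bias(r, cohort$layout, spec, zero_error = zero_error)
    sim_i <- simulate_participant(r, cohort$layout, center, cfg_i)
    sim_g <- simulate_participant(r, cohort$layout, center, cfg_g)
    tibble::tibble(
      participant_id = r$participant_id,
      session = r$session,
      delay_group = r$delay_group,
      mode = spec$mode,
      observed_bias = obs$participant_bias,
      sim_item_only = sim_i$simulated_bias_mean,
      sim_item_plus_gist = sim_g$simulated_bias_mean,
      gap_item_only = obs$participant_bias - sim_i$simulated_bias_mean,
      gap_gist = sim_g$simulated_bias_mean - obs$participant_bias,
      sim_item_only_est_center_error = mean(sim_i$estimated_center_error_per_run),
      sim_gist_est_center_error = mean(sim_g$estimated_center_error_per_run)
    )
  })
  dplyr::bind_rows(rows)
}
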