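# Shared fixtures, built once per test run.

toy_screen <- screen_def(200, 100)

# Three-item toy layout for hand-checked arithmetic.
toy_layout <- spatial_layout(
  data.frame(label = c("A", "B", "C"), x = c(0, 100, 50), y = c(0, 0, 80)),
  screen = toy_screen
)

# Calibrated study layouts (seeded, deterministic).
exp1_layout <- calibrate_layout(
  calibration_targets(348, 267, 270, 160), n_items = 6, seed = 11L
)
exp2_layout <- calibrate_layout(
  calibration_targets(386, 262, 223, 100, outlier_offset = 573),
  n_items = 8, seed = 11L
)

make_record <- function(layout, retrieved, center,
                        pid = "P1", session = "S1", group = "24h") {
  retrieval_record(pid, session, group, retrieved, center, layout)
}

perfect_record <- function(layout, pid = "P1", session = "S1", group = "24h") {
  retrieval_record(pid, session, group, layout_points(layout),
                   encoded_centroid(layout), layout)
}

# A record with every retrieval translated by a fixed offset.
translated_record <- function(layout, dx, dy, ...) {
  pts <- layout_points(layout)
  pts[, 1] <- pts[, 1] + dx
  pts[, 2] <- pts[, 2] + dy
  make_record(layout, pts, encoded_centroid(layout), ...)
}

random_points_in <- function(n, screen, margin = 0) {
  cbind(stats::runif(n, margin, screen$width - margin),
        stats::runif(n, margin, screen$height - margin))
}
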