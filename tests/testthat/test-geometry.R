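test_that("Minkowski distance matches closed forms and rejects bad input", {
  expect_equal(mink_dist(c(0, 0), c(3, 4)), 5)
  expect_equal(mink_dist(c(7, -2), c(7, -2), g = 1.5), 0)
  expect_equal(mink_dist(c(0, 0), c(1, 1), g = 1.5), 2^(2 / 3))
  # vectorised over rows
  expect_equal(mink_dist(rbind(c(0, 0), c(0, 0)), rbind(c(3, 4), c(6, 8))), c(5, 10))
  expect_error(mink_dist(c(0, NA), c(1, 1)), "non-finite")
  expect_error(mink_dist(c(0, 0), c(1, 1), g = 1), "g")
  expect_error(mink_dist(c(0, 0), c(1, 1), g = 2.5), "g")
})

test_that("Minkowski distance is a metric for g in (1, 2]", {
  set.seed(401)
  for (g in c(1.2, 1.5, 2)) {
    for (k in 1:200) {
      a <- stats::runif(2, -50, 50)
      b <- stats::runif(2, -50, 50)
      c_ <- stats::runif(2, -50, 50)
      dab <- mink_dist(a, b, g = g)
      expect_gte(dab, 0)
      expect_equal(dab, mink_dist(b, a, g = g))
      expect_lte(mink_dist(a, c_, g = g), dab + mink_dist(b, c_, g = g) + 1e-9)
    }
    expect_equal(mink_dist(c(1, 2), c(1, 2), g = g), 0)
  }
})

test_that("centroid is the coordinate mean and minimises summed squared distance", {
  expect_equal(centroid(rbind(c(0, 0), c(2, 0), c(1, 3))), c(1, 1))
  expect_equal(centroid(rbind(c(4.5, -2))), c(4.5, -2))
  # translation linearity
  pts <- rbind(c(1, 2), c(5, 1), c(2, 9))
  shift <- c(13, -4)
  expect_equal(centroid(sweep(pts, 2, shift, "+")), centroid(pts) + shift)
  # brute-force grid oracle: no grid point beats the centroid on summed
  # squared Euclidean distance
  ssd <- function(p) sum((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)
  grid <- expand.grid(x = seq(0, 10, by = 0.1), y = seq(0, 10, by = 0.1))
  best_grid <- min(apply(grid, 1, ssd))
  expect_lte(ssd(centroid(pts)), best_grid + 1e-9)
  expect_error(centroid(matrix(numeric(0), ncol = 2)), "zero points")
})

test_that("local centroid excludes exactly the outlier", {
  pts <- rbind(c(0, 0), c(2, 0), c(100, 100))
  expect_equal(local_centroid(pts, 3), c(1, 0))
  # outlier sitting at the centroid of the rest leaves the centre unchanged
  pts2 <- rbind(c(0, 0), c(4, 0), c(2, 6), c(2, 2))
  expect_equal(local_centroid(pts2, 4), centroid(pts2[1:3, ]))
  expect_error(local_centroid(pts, 4), "out of range")
  expect_error(local_centroid(pts[1, , drop = FALSE], 1), "two points")
  # calibrated outlier layout: direct mean over the seven non-outlier items
  m <- layout_points(exp2_layout)
  i <- match("outlier", rownames(m))
  expect_equal(local_center(exp2_layout), unname(colMeans(m[-i, ])))
})

test_that("accuracy-weighted centroid follows the published weight formula", {
  # equal errors collapse to the plain centroid
  pts <- layout_points(exp1_layout)
  expect_equal(accuracy_weighted_centroid(pts, rep(37, 6)), centroid(pts))
  # hand-evaluated two-item case: weights (0.75, 0.25)
  expect_equal(accuracy_weighted_centroid(rbind(c(0, 0), c(10, 0)), c(1, 3)),
               c(2.5, 0))
  # weights sum to one for random error vectors: result is an affine
  # combination, so translating the points translates the result exactly
  set.seed(402)
  for (k in 1:25) {
    n <- sample(3:8, 1)
    p <- random_points_in(n, toy_screen)
    e <- stats::runif(n, 0, 100)
    w <- (1 - e / sum(e)) / (n - 1)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
    expect_equal(accuracy_weighted_centroid(p, e),
                 c(sum(w * p[, 1]), sum(w * p[, 2])))
    shift <- c(-3, 11)
    expect_equal(accuracy_weighted_centroid(sweep(p, 2, shift, "+"), e),
                 accuracy_weighted_centroid(p, e) + shift)
  }
  # all-zero errors fall back to the unweighted centroid
  expect_equal(accuracy_weighted_centroid(pts, rep(0, 6)), centroid(pts))
  expect_error(accuracy_weighted_centroid(rbind(c(1, 1)), 0), "two encoded")
})

test_that("layouts validate input and round-trip through JSON", {
  expect_equal(screen_center(toy_screen), c(100, 50))
  expect_true(all(in_bounds(rbind(c(0, 0), c(200, 100)), toy_screen)))
  expect_false(in_bounds(c(-1, 50), toy_screen))
  expect_error(spatial_layout(data.frame(label = c("A", "A"), x = 1:2, y = 1:2),
                              toy_screen), "unique")
  expect_error(spatial_layout(data.frame(label = "A", x = 500, y = 5), toy_screen),
               "within the screen")
  expect_error(spatial_layout(toy_layout$items, toy_screen, outlier_label = "Z"),
               "not one of the item labels")
  path <- withr::local_tempfile(fileext = ".json")
  write_layout_json(exp2_layout, path)
  back <- read_layout_json(path)
  expect_equal(layout_points(back), layout_points(exp2_layout))
  expect_equal(back$outlier_label, "outlier")
  expect_equal(back$screen$width, exp2_layout$screen$width)
})
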