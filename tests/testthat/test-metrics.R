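test_that("error summary matches the hand-computed toy oracle", {
  # oracle computed by direct arithmetic:
  # per-item errors 10, 10, 0; encoded centroid (50, 80/3);
  # retrieved centroid (160/3, 30)
  rec <- make_record(toy_layout,
                     rbind(A = c(10, 0), B = c(100, 10), C = c(50, 80)),
                     c(60, 30))
  es <- error_summary(rec, toy_layout)
  expect_equal(unname(es$per_item_error), c(10, 10, 0))
  expect_equal(es$item_error, 20 / 3)
  expect_equal(es$gist_error, sqrt(10^2 + (10 / 3)^2))
  expect_equal(es$estimated_center_error, sqrt(2 * (10 / 3)^2))
  expect_identical(error_summary(rec, toy_layout, g = 2), es)
})

test_that("perfect retrieval gives zero errors; rigid translation gives the shift", {
  es0 <- error_summary(perfect_record(exp1_layout), exp1_layout)
  expect_equal(es0$item_error, 0)
  expect_equal(es0$gist_error, 0)
  expect_equal(es0$estimated_center_error, 0)
  es <- error_summary(translated_record(exp1_layout, 30, 40), exp1_layout)
  expect_equal(es$item_error, 50)
  expect_equal(es$estimated_center_error, 50)
  expect_equal(unname(es$per_item_error), rep(50, 6))
})

test_that("chance baselines depend on layout geometry alone", {
  sym <- spatial_layout(
    data.frame(label = c("A", "B"), x = c(60, 140), y = c(30, 70)),
    screen = toy_screen
  )
  cb <- chance_baselines(sym)
  expect_equal(cb$gist_vs_screen_center, 0) # centroid sits on the screen centre
  expect_equal(cb$item_vs_encoded_center, sqrt(40^2 + 20^2))
  expect_equal(cb$item_vs_screen_center, sqrt(40^2 + 20^2))
})

test_that("item bias matches closed forms and the sign convention", {
  ctr <- c(0, 0)
  enc <- c(100, 0)
  expect_equal(item_bias(enc, c(60, 0), ctr), 1)   # straight toward the centre
  expect_equal(item_bias(enc, c(140, 0), ctr), -1) # straight away
  # orthogonal displacement: small negative bias without being "biased away"
  expect_equal(item_bias(enc, c(100, 40), ctr), (100 - sqrt(100^2 + 40^2)) / 40)
  expect_equal(item_bias(enc, enc, ctr), 0) # 0/0 convention
})

test_that("item bias is invariant under translation, scaling, and (g=2) rotation", {
  set.seed(701)
  for (k in 1:50) {
    enc <- stats::runif(2, -100, 100)
    ret <- stats::runif(2, -100, 100)
    ctr <- stats::runif(2, -100, 100)
    t <- stats::runif(2, -500, 500)
    s <- stats::runif(1, 0.1, 10)
    for (g in c(1.5, 2)) {
      b <- item_bias(enc, ret, ctr, g = g)
      expect_equal(item_bias(enc + t, ret + t, ctr + t, g = g), b)
      expect_equal(item_bias(s * enc, s * ret, s * ctr, g = g), b)
    }
    th <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    expect_equal(item_bias(as.vector(R %*% enc), as.vector(R %*% ret),
                           as.vector(R %*% ctr)),
                 item_bias(enc, ret, ctr))
  }
})

test_that("participant bias averages per-item bias under the chosen centre", {
  # every item retrieved halfway along the segment toward the centre
  enc <- layout_points(exp1_layout)
  ctr <- encoded_centroid(exp1_layout)
  halfway <- sweep(sweep(enc, 2, ctr, "-") * 0.5, 2, ctr, "+")
  rec <- make_record(exp1_layout, halfway, ctr)
  b <- participant_bias(rec, exp1_layout, bias_center_spec("encoded_center"))
  expect_equal(b$participant_bias, 1)
  # perfect retrieval: bias 0 under the 0/0 convention, dropped items give 0 mean
  p <- perfect_record(exp1_layout)
  expect_equal(participant_bias(p, exp1_layout)$participant_bias, 0)
  expect_equal(participant_bias(p, exp1_layout, zero_error = "drop")$participant_bias, 0)
})

test_that("all four centre modes agree on a coincidence fixture", {
  # four corners plus an outlier exactly at their centre: the reported centre,
  # encoded centroid, accuracy-weighted centroid, and local centre all coincide
  lay <- spatial_layout(
    data.frame(label = c("A", "B", "C", "D", "out"),
               x = c(40, 160, 160, 40, 100), y = c(20, 20, 80, 80, 50)),
    screen = toy_screen, outlier_label = "out"
  )
  th <- 0.2 # rotate the corners about the centre; the outlier stays put
  ctr <- c(100, 50)
  pts <- layout_points(lay)
  rot <- t(apply(pts, 1, function(p) {
    v <- p - ctr
    ctr + c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2])
  }))
  rec <- make_record(lay, rot, ctr)
  vals <- vapply(c("reported", "encoded_center", "accuracy_weighted", "local"),
                 function(m) participant_bias(rec, lay, bias_center_spec(m))$participant_bias,
                 numeric(1))
  expect_equal(unname(vals), rep(vals[[1]], 4))
})

test_that("local mode requires an outlier layout and reports the outlier's own bias", {
  rec <- perfect_record(exp1_layout)
  expect_error(participant_bias(rec, exp1_layout, bias_center_spec("local")),
               "outlier")
  params <- generative_params(
    n_participants = 1, sessions = "S1",
    schedule = data.frame(session = "S1", item_error_scale = 50,
                          gist_error_scale = 20, gist_pull = 0.5),
    outlier_weight = 0.25, swap_rate = 0, seed = 702
  )
  r2 <- generate_participant(exp2_layout, params, "P1", "S1")
  b <- participant_bias(r2, exp2_layout, bias_center_spec("local"))
  expect_equal(b$outlier_bias, unname(b$per_item_bias["outlier"]))
  expect_equal(b$participant_bias, mean(b$per_item_bias))
})

test_that("bias across centre modes is strongly correlated when centres nearly coincide", {
  # reported centre generated near the global centroid (w = 1/8, small noise),
  # with between-participant variation in gist reliance — the individual
  # differences that drive mode-to-mode agreement in real cohorts
  mk <- function(pull, n, seed) {
    params <- generative_params(
      n_participants = n, sessions = "S1",
      schedule = data.frame(session = "S1", item_error_scale = 60,
                            gist_error_scale = 8, gist_pull = pull),
      outlier_weight = 0.125, swap_rate = 0, seed = seed
    )
    generate_cohort(exp2_layout, params)$records
  }
  recs <- c(mk(0, 20, 703), mk(0.5, 20, 704), mk(1, 20, 705))
  for (i in seq_along(recs)) recs[[i]]$participant_id <- sprintf("Q%03d", i)
  coh <- memory_cohort(exp2_layout, recs)
  specs <- lapply(c("reported", "encoded_center", "accuracy_weighted", "local"),
                  bias_center_spec)
  tab <- cohort_bias(coh, specs)
  wide <- tidyr::pivot_wider(tab[, c("participant_id", "mode", "participant_bias")],
                             names_from = "mode", values_from = "participant_bias")
  cm <- stats::cor(as.matrix(wide[, -1]))
  expect_true(all(cm[upper.tri(cm)] > 0.9))
})
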