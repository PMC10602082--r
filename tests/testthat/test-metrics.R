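test_that("prediction vectors and error measures match hand computations", {
  expect_equal(unname(predict_costim(c(1, 2, 3), c(-1, -2, -3))), c(0, 0, 0))
  p <- predict_costim(c(0.5, 0, 0), c(0, 0.5, 0))
  expect_equal(unname(p), c(0.5, 0.5, 0))
  expect_equal(vec_magnitude(p), sqrt(0.5), tolerance = 1e-12)
  expect_equal(unname(predict_costim(c(1, 2, 3), c(0, 0, 0))), c(1, 2, 3))

  expect_equal(prediction_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(prediction_error(c(1, 0, 0), c(0, 1, 0)), sqrt(2))
  # homogeneity and symmetry
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(3); c <- runif(1, 0.1, 5)
    expect_equal(prediction_error(c * a, c * b), c * prediction_error(a, b),
                 tolerance = 1e-12)
    expect_equal(prediction_error(a, b), prediction_error(b, a))
  }

  expect_equal(magnitude_error(c(1, 0, 0), c(2, 0, 0)), 1)
  expect_equal(direction_error(c(1, 0, 0), c(2, 0, 0)), 0)
  expect_equal(direction_error(c(1, 0, 0), c(-1, 0, 0)), 180)
  expect_equal(direction_error(c(1, 0, 0), c(1, 1, 0)), 45, tolerance = 1e-12)
  expect_warning(de <- direction_error(c(0, 0, 0), c(1, 0, 0)), "zero-magnitude")
  expect_true(is.na(de))
})

test_that("error measures satisfy their geometric inequalities", {
  set.seed(2)
  A <- random_vectors(300); B <- random_vectors(300)
  pe <- prediction_error(A, B)
  me <- magnitude_error(A, B)
  # reverse triangle inequality
  expect_true(all(abs(me) <= pe + 1e-12))
  # triangle inequality against a third vector
  C <- random_vectors(300)
  expect_true(all(prediction_error(A, B) <=
                  prediction_error(A, C) + prediction_error(C, B) + 1e-12))
  # direction error invariant to positive rescaling
  s <- runif(300, 0.1, 10)
  expect_equal(direction_error(A * s, B), direction_error(A, B), tolerance = 1e-9)
})

test_that("combined R-squared matches its trivial and hand-computed values", {
  set.seed(3)
  obs <- random_vectors(10)
  expect_equal(combined_r_squared(obs, obs), 1)
  null_pred <- matrix(colMeans(obs), 10, 3, byrow = TRUE)
  expect_equal(combined_r_squared(obs, null_pred), 0, tolerance = 1e-12)
  # 4-point fixture against the naive spreadsheet-style oracle
  obs4 <- rbind(c(1, 0, 2), c(2, 1, 0), c(0, -1, 1), c(1, 2, -1))
  pred4 <- rbind(c(0.9, 0.2, 1.8), c(2.2, 0.8, 0.1), c(0.1, -0.9, 1.2), c(1, 1.9, -0.8))
  expect_equal(combined_r_squared(obs4, pred4), naive_combined_r2(obs4, pred4),
               tolerance = 1e-14)
  expect_true(combined_r_squared(obs, random_vectors(10)) <= 1)
  expect_warning(r <- combined_r_squared(matrix(1, 3, 3), matrix(1, 3, 3)),
                 "zero total sum of squares")
  expect_true(is.na(r))
})

test_that("angular deviation matches closed forms and is rotation invariant", {
  expect_equal(angular_deviation(c(30, 30, 30)), 0)
  expect_equal(angular_deviation(c(0, 90)), sqrt(2 - sqrt(2)) * 180 / pi,
               tolerance = 1e-12)
  # uniform angles: R -> 0, deviation -> sqrt(2) rad
  expect_equal(angular_deviation(seq(0, 359, by = 1)), sqrt(2) * 180 / pi,
               tolerance = 0.01)
  set.seed(4)
  ang <- runif(50, -180, 180)
  expect_true(angular_deviation(ang) <= sqrt(2) * 180 / pi + 1e-9)
  for (shift in c(-170, 45, 300))
    expect_equal(angular_deviation(ang + shift), angular_deviation(ang),
                 tolerance = 1e-9)
  expect_error(angular_deviation(5), "at least 2")
})

test_that("recruitment dispersion reflects the configured rotation", {
  m <- default_recruitment_model("muscle")
  v <- magnitude_at(m, m$amplitude_grid) * direction_at(m, m$amplitude_grid)
  expect_equal(recruitment_direction_dispersion(v), 2.7, tolerance = 1e-6)
  one_dir <- matrix(rep(c(1, 1, 0), 5), ncol = 3, byrow = TRUE)
  expect_equal(recruitment_direction_dispersion(one_dir), 0)
})

test_that("all metrics agree with naive oracles on random instances", {
  set.seed(5)
  n <- 1000
  A <- random_vectors(n); B <- random_vectors(n)
  pe <- prediction_error(A, B); de <- direction_error(A, B)
  me <- magnitude_error(A, B)
  for (i in seq_len(n)) {
    expect_equal(pe[i], naive_prediction_error(A[i, ], B[i, ]), tolerance = 1e-12)
    expect_equal(me[i], naive_magnitude_error(A[i, ], B[i, ]), tolerance = 1e-12)
    expect_equal(de[i], naive_direction_error(A[i, ], B[i, ]), tolerance = 1e-12)
  }
  expect_equal(combined_r_squared(A, B), naive_combined_r2(A, B), tolerance = 1e-12)
  ang <- runif(n, -180, 180)
  expect_equal(angular_deviation(ang), naive_angular_deviation(ang), tolerance = 1e-12)
})

test_that("error records pair co-stim trials with same-block individual means", {
  cfg <- quiet_config(n_subjects = 1, n_blocks = 2, recruitment_repeats = 0, seed = 2)
  tr <- simulate_experiment(cfg)$trials
  err <- build_error_records(tr)
  expect_true(all(c("spinal/muscle", "muscle/muscle") %in% err$type))
  # noiseless linear data: predictions are exact
  expect_true(all(err$prediction_error_N < 1e-12))
  expect_true(all(abs(err$magnitude_error_N) < 1e-12))
  expect_true(all(err$relative_error_pct < 1e-10))
})
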