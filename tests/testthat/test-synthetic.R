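test_that("noiseless responses equal the recruitment curve exactly", {
  m <- default_recruitment_model("spinal")
  nz <- noise_model(0, 0)
  for (a in c(200, 300, 420)) {
    v <- simulate_response(m, nz, a)
    expect_equal(unname(v),
                 unname(magnitude_at(m, a) * drop(direction_at(m, a))),
                 tolerance = 1e-12)
  }
  expect_error(simulate_response(m, nz, -10), "non-negative")
})

test_that("noiseless recruitment magnitudes are non-decreasing in amplitude", {
  for (kind in c("spinal", "muscle", "muscle2")) {
    m <- default_recruitment_model(kind)
    mags <- magnitude_at(m, m$amplitude_grid)
    expect_true(all(diff(mags) >= 0))
    expect_true(all(abs(vec_magnitude(direction_at(m, m$amplitude_grid)) - 1) < 1e-9))
  }
})

test_that("configured noise SDs are recovered from repeated trials", {
  set.seed(42)
  n <- 500
  for (kind in c("spinal", "muscle")) {
    m <- default_recruitment_model(kind)
    nz <- default_noise_model(kind)
    a <- max(m$amplitude_grid)
    v <- simulate_response(m, nz, a, n = n)
    sd_mag <- sd(vec_magnitude(v))
    se <- nz$magnitude_sd / sqrt(2 * (n - 1))
    expect_lt(abs(sd_mag - nz$magnitude_sd), 3 * se)
    circ <- angular_deviation(sagittal_angle(v))
    # brute-force oracle: resample the stated rotation model directly
    oracle <- naive_angular_deviation(rnorm(2e5, 0, nz$direction_sd_deg))
    expect_lt(abs(circ - oracle), 3 * nz$direction_sd_deg / sqrt(2 * n) + 0.2)
  }
})

test_that("co-stimulation combination rules match their definitions", {
  expect_equal(unname(simulate_costim(c(1, 0, 0), c(0, 1, 0))), c(1, 1, 0))
  # epsilon = 0 gain is the identity
  set.seed(1)
  for (i in 1:10) {
    va <- rnorm(3); vb <- rnorm(3)
    expect_equal(simulate_costim(va, vb, interaction_model("multiplicative-gain", 0)),
                 simulate_costim(va, vb))
  }
  # saturating: (3,4,0) capped at 2.5 N -> (1.5,2,0)
  expect_equal(unname(simulate_costim(c(3, 4, 0), c(0, 0, 0),
                                      interaction_model("saturating", f_sat = 2.5))),
               c(1.5, 2, 0))
  expect_error(simulate_costim(c(Inf, 0, 0), c(0, 0, 0)), "finite")
})

test_that("mean co-stim response converges to the sum of mean responses", {
  set.seed(7)
  sm <- default_recruitment_model("spinal"); mm <- default_recruitment_model("muscle")
  ns <- default_noise_model("spinal"); nm <- default_noise_model("muscle")
  n <- 4000
  S <- simulate_response(sm, ns, 400, n = n)
  M <- simulate_response(mm, nm, 1320, n = n)
  C <- t(sapply(seq_len(n), function(i) simulate_costim(S[i, ], M[i, ])))
  expect_equal(colMeans(C), colMeans(S) + colMeans(M), tolerance = 1e-12)
})

test_that("simulated traces settle onto the requested plateau", {
  v <- c(0.8, -0.4, 0.1)
  tr <- simulate_trace(v, duration_ms = 600)
  ex <- extract_force_vector(tr)
  expect_lt(max(abs(ex - v)), 0.01 * max(abs(v)))
  # baseline offsets cancel after demeaning
  tr2 <- simulate_trace(v, duration_ms = 600, baseline_offset = c(0.2, 0, 0))
  expect_equal(extract_force_vector(demean_trace(tr2)), ex, tolerance = 1e-9)
  expect_error(simulate_trace(v, duration_ms = 600, pre_ms = 100), "400 ms")
})

test_that("a fixed seed makes experiment and traces byte-identical", {
  cfg <- generator_config(n_subjects = 2, n_blocks = 2, seed = 99)
  a <- simulate_experiment(cfg, traces = TRUE)
  b <- simulate_experiment(cfg, traces = TRUE)
  expect_identical(a$trials, b$trials)
  expect_identical(a$traces, b$traces)
})

test_that("one block covers each amplitude alone and every pair", {
  cfg <- quiet_config(muscle2 = NULL, n_subjects = 1, n_blocks = 1,
                      recruitment_repeats = 0,
                      spinal_costim_amps = c(233, 272),
                      muscle_costim_amps = c(1000, 1333))
  tr <- simulate_experiment(cfg)$trials
  expect_equal(nrow(tr), 8L)
  conds <- paste(tr$spinal_amplitude_uA, tr$muscle1_amplitude_uA)
  expect_setequal(conds, c("233 0", "272 0", "0 1000", "0 1333",
                           "233 1000", "233 1333", "272 1000", "272 1333"))
  expect_equal(diff(tr$timestamp_min), rep(45 / 60, 7), tolerance = 1e-12)
})

test_that("zero repeats or empty amplitude grids are rejected", {
  expect_error(generator_config(repeats = 0), "repeats")
  expect_error(generator_config(spinal_costim_amps = numeric()), "non-empty")
})

test_that("fatigue drift is detected by the exclusion regression", {
  # low-noise spinal responses declining at -0.02 N/min over ~2 h
  cfg <- generator_config(
    spinal_noise = noise_model(0.05, 1, trace_noise_sd = 0),
    muscle_noise = noise_model(0.01, 0.5, trace_noise_sd = 0),
    n_subjects = 1, n_blocks = 8, recruitment_repeats = 0,
    fatigue_drift = -0.02, seed = 5)
  tr <- simulate_experiment(cfg)$trials
  expect_gt(max(tr$timestamp_min), 100)
  cases <- costim_cases(tr)
  drops <- vapply(Filter(function(c) c$eligible, cases),
                  function(c) fatigue_exclusion(c)$keep, logical(1))
  expect_true(all(!drops))
  # null drift: no exclusions expected
  cfg0 <- generator_config(
    spinal_noise = noise_model(0.05, 1, trace_noise_sd = 0),
    muscle_noise = noise_model(0.01, 0.5, trace_noise_sd = 0),
    n_subjects = 1, n_blocks = 8, recruitment_repeats = 0,
    fatigue_drift = 0, seed = 5)
  cases0 <- costim_cases(simulate_experiment(cfg0)$trials)
  keep0 <- vapply(Filter(function(c) c$eligible, cases0),
                  function(c) fatigue_exclusion(c)$keep, logical(1))
  expect_true(all(keep0))
})
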