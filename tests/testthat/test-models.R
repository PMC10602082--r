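# Simulated error table: by-subject random intercepts plus an additive
# type effect, mirroring the structure the mixed model assumes.
sim_errors <- function(n_subjects = 6, n_per_type = 15, effect = 0,
                       subj_sd = 0.05, noise_sd = 0.05, base = 0.15) {
  subj <- rep(seq_len(n_subjects), each = 2 * n_per_type)
  type <- rep(rep(c("muscle/muscle", "spinal/muscle"), each = n_per_type),
              n_subjects)
  b0 <- rnorm(n_subjects, 0, subj_sd)
  y <- base + b0[subj] + effect * (type == "spinal/muscle") +
    rnorm(length(subj), 0, noise_sd)
  data.frame(subject_id = subj, type = type, prediction_error_N = y,
             obs_magnitude_N = runif(length(subj), 0.5, 1.5))
}

test_that("an injected type effect is recovered within two standard errors", {
  set.seed(21)
  d <- sim_errors(effect = 0.05)
  fit <- fit_error_model(d, transform = "none")
  expect_true(fit$converged)
  co <- fit$coefficients[fit$coefficients$term == "typespinal/muscle", ]
  expect_lt(abs(co$estimate - 0.05), 2 * co$se)
  expect_lt(co$p, 0.05)
  # the effect survives a balanced magnitude nuisance covariate
  fit2 <- fit_error_model(d, transform = "none", covariates = "obs_magnitude_N")
  co2 <- fit2$coefficients[fit2$coefficients$term == "typespinal/muscle", ]
  expect_lt(abs(co2$estimate - 0.05), 2 * co2$se)
  expect_lt(co2$p, 0.05)
})

test_that("a null type effect yields a small, nonsignificant estimate", {
  set.seed(22)
  d <- sim_errors(effect = 0, n_per_type = 40)
  fit <- fit_error_model(d, transform = "none")
  co <- fit$coefficients[fit$coefficients$term == "typespinal/muscle", ]
  expect_lt(abs(co$estimate), 3 * co$se)
})

test_that("single-subject or single-type inputs are rejected", {
  set.seed(23)
  d <- sim_errors()
  expect_error(fit_error_model(d[d$subject_id == 1, ], transform = "none"),
               "single subject")
  expect_error(fit_error_model(d[d$type == "spinal/muscle", ], transform = "none"),
               "both levels")
})

test_that("under a log transform, rescaling errors moves only the intercept", {
  set.seed(24)
  d <- sim_errors(effect = 0.05, base = 0.5)
  d$prediction_error_N <- abs(d$prediction_error_N)
  f1 <- fit_error_model(d, transform = "log")
  d2 <- d; d2$prediction_error_N <- 7.3 * d2$prediction_error_N
  f2 <- fit_error_model(d2, transform = "log")
  c1 <- f1$coefficients; c2 <- f2$coefficients
  i <- c1$term == "typespinal/muscle"
  expect_equal(c1$estimate[i], c2$estimate[i], tolerance = 1e-6)
  expect_equal(c1$p[i], c2$p[i], tolerance = 1e-5)
  expect_equal(c2$estimate[c2$term == "(Intercept)"],
               c1$estimate[c1$term == "(Intercept)"] + log(7.3), tolerance = 1e-6)
})

test_that("the automatic transform gate reacts to skewed residuals", {
  set.seed(25)
  d <- sim_errors(effect = 0, noise_sd = 1e-4)
  d$prediction_error_N <- exp(rnorm(nrow(d), 0, 1)) +
    0.3 * (d$type == "spinal/muscle")
  fit <- fit_error_model(d, transform = "auto")
  expect_equal(fit$transform, "log")
  dn <- sim_errors(effect = 0)
  fitn <- fit_error_model(dn, transform = "auto")
  expect_equal(fitn$transform, "none")
})

test_that("Welch's dispersion test matches t.test and handles degeneracy", {
  x <- c(44.1, 51.3, 38.2, 60.5, 47.0, 49.9)
  y <- c(2.1, 3.4, 1.8, 2.9, 2.5, 3.1)
  got <- welch_dispersion_test(x, y)
  ref <- t.test(x, y)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  same <- welch_dispersion_test(c(5, 5, 5), c(5, 5))
  expect_equal(same$p_value, 1)
  diff_ <- welch_dispersion_test(c(5, 5, 5), c(4, 4))
  expect_equal(diff_$p_value, 0)
  expect_error(welch_dispersion_test(1, c(1, 2)))
})

test_that("windowed errors vanish on noiseless linear traces", {
  cfg <- quiet_config(muscle2 = NULL, n_subjects = 1, n_blocks = 1,
                      recruitment_repeats = 0, seed = 31)
  ex <- simulate_experiment(cfg, traces = TRUE)
  wa <- windowed_error_analysis(ex$trials, ex$traces)
  expect_equal(unique(wa$errors$window_start_ms), seq(0, 450, by = 50))
  expect_equal(length(unique(wa$errors$window_start_ms)), 10L)
  # rise transients are shared by observed and predicted windows, so even
  # the earliest windows predict exactly under linear summation
  expect_true(all(wa$errors$prediction_error_N < 1e-9))
})

test_that("constant plateaus give equal windowed and whole-train errors", {
  # hand-built traces: constant plateau from onset (no rise)
  mk <- function(v) {
    t <- seq(-400, 600)
    force_trace(t, ifelse(t >= 0, v[1], 0), ifelse(t >= 0, v[2], 0),
                ifelse(t >= 0, v[3], 0))
  }
  trials <- data.frame(subject_id = 1L, block_id = 1L, trial_index = 1:3,
                       timestamp_min = 0:2,
                       spinal_amplitude_uA = c(100, 0, 100),
                       muscle1_amplitude_uA = c(0, 900, 900),
                       muscle2_amplitude_uA = 0,
                       fx_N = c(1, 0.5, 1.8), fy_N = c(0.2, -0.1, 0.3),
                       fz_N = 0)
  traces <- list(s1_t1 = mk(c(1, 0.2, 0)), s1_t2 = mk(c(0.5, -0.1, 0)),
                 s1_t3 = mk(c(1.8, 0.3, 0)))
  wa <- windowed_error_analysis(trials, traces)
  whole <- prediction_error(c(1.5, 0.1, 0), c(1.8, 0.3, 0))
  expect_equal(wa$errors$prediction_error_N, rep(whole, 10), tolerance = 1e-9)
})

test_that("early and late train periods agree under stationary plateaus", {
  cfg <- generator_config(
    muscle2 = NULL, n_subjects = 3, n_blocks = 2, recruitment_repeats = 0,
    spinal_noise = noise_model(0.05, 2, trace_noise_sd = 0.002),
    muscle_noise = noise_model(0.01, 0.5, trace_noise_sd = 0.002),
    seed = 32)
  ex <- simulate_experiment(cfg, traces = TRUE)
  res <- early_late_contrast(ex$trials, ex$traces, transform = "none")
  expect_setequal(unique(res$errors$period), c("early", "late"))
  co <- res$fit$coefficients[res$fit$coefficients$term == "periodlate", ]
  # stationary plateaus: the period effect is negligible against the
  # trial-to-trial error scale (~0.1 N)
  expect_lt(abs(co$estimate), 0.02)
})

test_that("a late-train sag in co-stimulation only is detected", {
  cfg <- generator_config(
    muscle2 = NULL, n_subjects = 3, n_blocks = 2, recruitment_repeats = 0,
    spinal_noise = noise_model(0.02, 1, trace_noise_sd = 0.002),
    muscle_noise = noise_model(0.01, 0.5, trace_noise_sd = 0.002),
    seed = 33)
  ex <- simulate_experiment(cfg, traces = TRUE)
  # scale co-stimulation traces by 0.8 after 300 ms
  amp <- as.matrix(ex$trials[, c("spinal_amplitude_uA", "muscle1_amplitude_uA",
                                 "muscle2_amplitude_uA")])
  costim_idx <- which(rowSums(amp > 0) == 2L)
  for (i in costim_idx) {
    key <- sprintf("s%d_t%d", ex$trials$subject_id[i], ex$trials$trial_index[i])
    tr <- ex$traces[[key]]
    sag <- tr$time_ms >= 300
    tr$f[sag, ] <- 0.8 * tr$f[sag, ]
    ex$traces[[key]] <- tr
  }
  res <- early_late_contrast(ex$trials, ex$traces, transform = "none")
  co <- res$fit$coefficients[res$fit$coefficients$term == "periodlate", ]
  expect_gt(co$estimate, 0.05)
  expect_lt(co$p, 0.05)
})
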