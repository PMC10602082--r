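# Independent brute-force reimplementations of the linearity metrics, kept
# deliberately naive (scalar loops, textbook formulas) so they can serve as
# oracles for the vectorized package implementations.

naive_prediction_error <- function(pred, obs) {
  s <- 0
  for (i in 1:3) s <- s + (obs[i] - pred[i])^2
  sqrt(s)
}

naive_norm <- function(v) sqrt(v[1]^2 + v[2]^2 + v[3]^2)

naive_magnitude_error <- function(pred, obs) naive_norm(obs) - naive_norm(pred)

naive_direction_error <- function(pred, obs) {
  d <- (pred[1] * obs[1] + pred[2] * obs[2] + pred[3] * obs[3]) /
    (naive_norm(pred) * naive_norm(obs))
  d <- min(1, max(-1, d))
  acos(d) * 180 / pi
}

naive_combined_r2 <- function(obs, pred) {
  rss <- 0; tss <- 0
  for (ax in 1:3) {
    m <- mean(obs[, ax])
    for (i in seq_len(nrow(obs))) {
      rss <- rss + (obs[i, ax] - pred[i, ax])^2
      tss <- tss + (obs[i, ax] - m)^2
    }
  }
  1 - rss / tss
}

naive_angular_deviation <- function(angles_deg) {
  z <- exp(1i * angles_deg * pi / 180)
  R <- Mod(mean(z))
  sqrt(2 * (1 - R)) * 180 / pi
}

# Random non-zero force vectors for property tests.
random_vectors <- function(n, scale = 1) {
  matrix(stats::rnorm(3 * n, sd = scale), ncol = 3)
}

# A small noiseless generator config used by several tests.
quiet_config <- function(...) {
  generator_config(
    spinal_noise = noise_model(0, 0, trace_noise_sd = 0),
    muscle_noise = noise_model(0, 0, trace_noise_sd = 0),
    ...)
}
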