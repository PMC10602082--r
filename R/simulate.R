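#' Simulate evoked force vectors for one site
#'
#' Draws one or more trial responses at a given stimulation current: the
#' noiseless recruitment magnitude plus truncated-Gaussian magnitude noise,
#' pointed along the recruitment direction rotated in the sagittal plane by a
#' Gaussian angle.  Truncation keeps magnitudes non-negative without shifting
#' them when the mean force is well above zero.
#'
#' @param model a [recruitment_model()].
#' @param noise a [noise_model()].
#' @param amplitude stimulation current, microamps (scalar, >= 0).
#' @param n number of trials to draw.
#' @param mean_shift additive shift of the noiseless magnitude (N), used for
#'   fatigue drift; the shifted mean is floored at 0.
#' @return For `n = 1` a named numeric force vector; otherwise an `n` x 3
#'   matrix with one trial per row.
#' @examples
#' set.seed(1)
#' simulate_response(default_recruitment_model("muscle"),
#'                   default_noise_model("muscle"), amplitude = 1200)
#' @export
simulate_response <- function(model, noise, amplitude, n = 1L, mean_shift = 0) {
  stopifnot(inherits(model, "recruitment_model"), inherits(noise, "noise_model"),
            length(amplitude) == 1L, n >= 1L)
  if (amplitude < 0)
    stop("stimulation amplitude must be non-negative, got ", amplitude)
  mu <- max(0, magnitude_at(model, amplitude) + mean_shift)
  mag <- rnorm_trunc0(n, mu, noise$magnitude_sd)
  ang <- direction_angle_at(model, amplitude) +
    stats::rnorm(n, 0, noise$direction_sd_deg)
  v <- mag * sagittal_unit(ang)
  if (n == 1L) c(fx = v[1, 1], fy = v[1, 2], fz = v[1, 3]) else v
}

# Gaussian truncated below at 0, drawn by inverse-CDF so that sd = 0 and
# mu >> sd reduce to the untruncated draw.
rnorm_trunc0 <- function(n, mu, sd) {
  if (sd == 0) return(rep(mu, n))
  p0 <- stats::pnorm(0, mu, sd)
  stats::qnorm(stats::runif(n, p0, 1), mu, sd)
}

#' Combine two individual responses into a co-stimulation response
#'
#' Under `kind = "none"` the co-stimulation response is the exact
#' component-wise vector sum.  `"multiplicative-gain"` returns
#' `(1 + strength) * (v_a + v_b)`; `"saturating"` rescales the sum so its
#' magnitude does not exceed `f_sat`.
#'
#' @param v_a,v_b individual-site force vectors (length 3, finite).
#' @param interaction an [interaction_model()]; default linear.
#' @export
simulate_costim <- function(v_a, v_b, interaction = interaction_model("none")) {
  stopifnot(inherits(interaction, "interaction_model"))
  v_a <- drop(as_force_matrix(v_a)[1, ]); v_b <- drop(as_force_matrix(v_b)[1, ])
  if (!all(is.finite(v_a)) || !all(is.finite(v_b)))
    stop("individual force vectors must be finite")
  s <- v_a + v_b
  out <- switch(interaction$kind,
    "none" = s,
    "multiplicative-gain" = (1 + interaction$strength) * s,
    "saturating" = {
      m <- sqrt(sum(s^2))
      if (m > interaction$f_sat) s * interaction$f_sat / m else s
    },
    stop("unknown interaction kind: ", interaction$kind))
  names(out) <- c("fx", "fy", "fz")
  out
}

#' Simulate a recorded force trace around one stimulation train
#'
#' Emulates the transducer recording: zero force before stimulation onset, a
#' per-axis first-order exponential rise (time constant `tau_ms`) to the
#' plateau vector `v` during the train, plus a constant baseline offset and
#' white sample noise.  The plateau over the standard analysis window (300 to
#' 500 ms after onset) equals `v` to within the time-constant decay residual
#' (< 0.1 percent for the defaults).
#'
#' @param v plateau force vector (length 3, N).
#' @param duration_ms stimulation-train duration, ms.
#' @param sampling_rate_hz sampling rate, Hz (> 0).
#' @param tau_ms rise time constant, ms.
#' @param pre_ms pre-stimulus span recorded before onset; must be at least
#'   400 ms so baseline subtraction has its full window.
#' @param trace_noise_sd white-noise SD per sample, N.
#' @param baseline_offset constant per-axis offset, N (length 3).
#' @return A [force_trace()] with stimulation onset at time 0.
#' @export
simulate_trace <- function(v, duration_ms, sampling_rate_hz = 1000,
                           tau_ms = 50, pre_ms = 400,
                           trace_noise_sd = 0, baseline_offset = c(0, 0, 0)) {
  stopifnot(sampling_rate_hz > 0, tau_ms > 0, duration_ms > 0)
  if (pre_ms < 400)
    stop("trace must cover at least 400 ms before onset, got ", pre_ms, " ms")
  v <- drop(as_force_matrix(v)[1, ])
  dt <- 1000 / sampling_rate_hz
  t <- seq(-pre_ms, duration_ms, by = dt)
  rise <- ifelse(t >= 0, 1 - exp(-t / tau_ms), 0)
  f <- outer(rise, v)
  f <- sweep(f, 2, as.numeric(baseline_offset), "+")
  if (trace_noise_sd > 0)
    f <- f + matrix(stats::rnorm(length(f), 0, trace_noise_sd), nrow = nrow(f))
  force_trace(t, f[, 1], f[, 2], f[, 3], onset_ms = 0)
}

#' Configuration for a simulated co-stimulation experiment
#'
#' Bundles the per-site recruitment and noise models with the session design:
#' number of subjects, amplitudes selected for co-stimulation, number of
#' randomized blocks, repeats of each condition per block, inter-trial
#' interval, fatigue drift and stimulation-train parameters (spinal trains:
#' 15 ms period, 0.2 ms pulses, 600 ms; muscle trains: 13 ms period, 0.12 ms
#' pulses, 520 ms).
#'
#' @param spinal,muscle1,muscle2 [recruitment_model()]s; set `muscle2 = NULL`
#'   to omit the second muscle site (and with it muscle/muscle
#'   co-stimulation).
#' @param spinal_noise,muscle_noise [noise_model()]s shared by subjects.
#' @param interaction [interaction_model()] applied to spinal/muscle
#'   co-stimulation; muscle/muscle pairs always sum linearly.
#' @param n_subjects number of simulated animals.
#' @param spinal_costim_amps,muscle_costim_amps currents (uA) selected for
#'   co-stimulation blocks; defaults pick two mid-to-high grid values, as one
#'   to three amplitudes per site are typical.
#' @param n_blocks randomized blocks per subject.
#' @param repeats copies of each condition within a block.
#' @param recruitment_repeats trials per grid amplitude in the initial
#'   recruitment-curve phase (block 0).
#' @param fatigue_drift slow drift of evoked magnitude, N per minute (<= 0).
#' @param inter_trial_s rest between trials, seconds.
#' @param spinal_train,muscle_train stimulation-train parameter lists with
#'   elements `period_ms`, `pulse_ms`, `duration_ms`.
#' @param sampling_rate_hz trace sampling rate, Hz.
#' @param tau_ms trace rise time constant, ms.
#' @param seed integer seed; a fixed seed makes the generated tables
#'   byte-identical across runs.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(spinal = default_recruitment_model("spinal"),
                             muscle1 = default_recruitment_model("muscle"),
                             muscle2 = default_recruitment_model("muscle2"),
                             spinal_noise = default_noise_model("spinal"),
                             muscle_noise = default_noise_model("muscle"),
                             interaction = interaction_model("none"),
                             n_subjects = 6L,
                             spinal_costim_amps = NULL,
                             muscle_costim_amps = NULL,
                             n_blocks = 4L,
                             repeats = 1L,
                             recruitment_repeats = 1L,
                             fatigue_drift = 0,
                             inter_trial_s = 45,
                             spinal_train = list(period_ms = 15, pulse_ms = 0.2,
                                                 duration_ms = 600),
                             muscle_train = list(period_ms = 13, pulse_ms = 0.12,
                                                 duration_ms = 520),
                             sampling_rate_hz = 1000,
                             tau_ms = 50,
                             seed = 1L) {
  stopifnot(n_subjects >= 1L, n_blocks >= 0L, repeats >= 1L,
            recruitment_repeats >= 0L, fatigue_drift <= 0, inter_trial_s > 0)
  pick2 <- function(grid) grid[unique(pmax(1L, round(length(grid) * c(0.6, 0.9))))]
  if (is.null(spinal_costim_amps)) spinal_costim_amps <- pick2(spinal$amplitude_grid)
  if (is.null(muscle_costim_amps)) muscle_costim_amps <- pick2(muscle1$amplitude_grid)
  if (length(spinal_costim_amps) == 0L || length(muscle_costim_amps) == 0L)
    stop("co-stimulation amplitude sets must be non-empty")
  structure(list(spinal = spinal, muscle1 = muscle1, muscle2 = muscle2,
                 spinal_noise = spinal_noise, muscle_noise = muscle_noise,
                 interaction = interaction, n_subjects = as.integer(n_subjects),
                 spinal_costim_amps = spinal_costim_amps,
                 muscle_costim_amps = muscle_costim_amps,
                 n_blocks = as.integer(n_blocks), repeats = as.integer(repeats),
                 recruitment_repeats = as.integer(recruitment_repeats),
                 fatigue_drift = fatigue_drift, inter_trial_s = inter_trial_s,
                 spinal_train = spinal_train, muscle_train = muscle_train,
                 sampling_rate_hz = sampling_rate_hz, tau_ms = tau_ms,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Simulate a full blocked co-stimulation experiment
#'
#' Generates the trial table of a session per subject: an initial
#' recruitment-curve phase (each grid amplitude stimulated alone, block 0),
#' followed by `n_blocks` randomized blocks.  Each block contains every
#' selected amplitude of every site alone plus all site-pair combinations
#' (spinal with each muscle, and muscle1 with muscle2 when present), in a
#' seeded random order.  Timestamps advance by the inter-trial interval;
#' fatigue drift lowers evoked magnitudes in proportion to elapsed minutes.
#'
#' @param cfg a [generator_config()].
#' @param traces if `TRUE`, also simulate a recorded force trace per trial
#'   (named `s<subject>_t<trial_index>`); the trial table then reports the
#'   vectors re-extracted from those traces only if you run them through
#'   [extract_trials()] - the table itself always holds the noiseless-trace
#'   plateau vectors.
#' @return A list with `trials` (data frame: subject_id, block_id,
#'   trial_index, timestamp_min, spinal_amplitude_uA, muscle1_amplitude_uA,
#'   muscle2_amplitude_uA, fx_N, fy_N, fz_N) and `traces` (list or `NULL`).
#' @examples
#' ex <- simulate_experiment(generator_config(n_subjects = 1, n_blocks = 1,
#'                                            recruitment_repeats = 0))
#' head(ex$trials)
#' @export
simulate_experiment <- function(cfg, traces = FALSE) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  sites <- list(spinal = list(model = cfg$spinal, noise = cfg$spinal_noise),
                muscle1 = list(model = cfg$muscle1, noise = cfg$muscle_noise))
  if (!is.null(cfg$muscle2))
    sites$muscle2 <- list(model = cfg$muscle2, noise = cfg$muscle_noise)

  rows <- list()
  trace_list <- if (traces) list() else NULL
  for (subj in seq_len(cfg$n_subjects)) {
    sched <- experiment_schedule(cfg, names(sites))
    t_min <- (seq_len(nrow(sched)) - 1L) * cfg$inter_trial_s / 60
    for (i in seq_len(nrow(sched))) {
      amps <- c(spinal = sched$spinal[i], muscle1 = sched$muscle1[i],
                muscle2 = sched$muscle2[i])
      active <- names(amps)[amps > 0]
      shift <- cfg$fatigue_drift * t_min[i]
      resp <- lapply(active, function(s)
        simulate_response(sites[[s]]$model, sites[[s]]$noise, amps[[s]],
                          mean_shift = shift))
      v <- if (length(resp) == 1L) resp[[1]]
      else simulate_costim(resp[[1]], resp[[2]],
                           if ("spinal" %in% active) cfg$interaction
                           else interaction_model("none"))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subj, block_id = sched$block[i], trial_index = i,
        timestamp_min = t_min[i],
        spinal_amplitude_uA = amps[["spinal"]],
        muscle1_amplitude_uA = amps[["muscle1"]],
        muscle2_amplitude_uA = amps[["muscle2"]],
        fx_N = v[[1]], fy_N = v[[2]], fz_N = v[[3]])
      if (traces) {
        dur <- if ("spinal" %in% active) cfg$spinal_train$duration_ms
               else cfg$muscle_train$duration_ms
        nm <- sites[[active[1]]]$noise
        trace_list[[sprintf("s%d_t%d", subj, i)]] <-
          simulate_trace(v, duration_ms = dur,
                         sampling_rate_hz = cfg$sampling_rate_hz,
                         tau_ms = cfg$tau_ms,
                         trace_noise_sd = nm$trace_noise_sd,
                         baseline_offset = nm$baseline_offset)
      }
    }
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  list(trials = trials, traces = trace_list)
}

# Condition schedule for one subject: recruitment phase (block 0, fixed
# ascending order) then n_blocks randomized blocks of singles + pairs.
experiment_schedule <- function(cfg, site_names) {
  zero <- c(spinal = 0, muscle1 = 0, muscle2 = 0)
  rows <- list()
  add <- function(block, a) rows[[length(rows) + 1L]] <<-
    data.frame(block = block, spinal = a[["spinal"]], muscle1 = a[["muscle1"]],
               muscle2 = a[["muscle2"]])
  # recruitment phase
  if (cfg$recruitment_repeats > 0L) {
    for (s in site_names) {
      grid <- (if (s == "spinal") cfg$spinal else
               if (s == "muscle1") cfg$muscle1 else cfg$muscle2)$amplitude_grid
      for (a in grid) for (r in seq_len(cfg$recruitment_repeats)) {
        x <- zero; x[s] <- a
        add(0L, x)
      }
    }
  }
  # co-stimulation blocks
  block_conditions <- function() {
    conds <- list()
    for (a in cfg$spinal_costim_amps) { x <- zero; x["spinal"] <- a
      conds[[length(conds) + 1L]] <- x }
    for (a in cfg$muscle_costim_amps) { x <- zero; x["muscle1"] <- a
      conds[[length(conds) + 1L]] <- x }
    if ("muscle2" %in% site_names)
      for (a in cfg$muscle_costim_amps) { x <- zero; x["muscle2"] <- a
        conds[[length(conds) + 1L]] <- x }
    for (as_ in cfg$spinal_costim_amps) for (am in cfg$muscle_costim_amps) {
      x <- zero; x["spinal"] <- as_; x["muscle1"] <- am
      conds[[length(conds) + 1L]] <- x }
    if ("muscle2" %in% site_names) {
      for (as_ in cfg$spinal_costim_amps) for (am in cfg$muscle_costim_amps) {
        x <- zero; x["spinal"] <- as_; x["muscle2"] <- am
        conds[[length(conds) + 1L]] <- x }
      for (a1 in cfg$muscle_costim_amps) for (a2 in cfg$muscle_costim_amps) {
        x <- zero; x["muscle1"] <- a1; x["muscle2"] <- a2
        conds[[length(conds) + 1L]] <- x }
    }
    conds
  }
  for (b in seq_len(cfg$n_blocks)) {
    conds <- rep(block_conditions(), cfg$repeats)
    for (j in sample(length(conds)))
      add(b, conds[[j]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
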