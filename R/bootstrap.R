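#' Assemble co-stimulation cases for the resampling analysis
#'
#' A case is a unique (subject, site pair, amplitude pair) combination: all
#' co-stimulation trials at that pair, together with every individual-site
#' trial at the constituent amplitudes pooled across the session, and the
#' per-trial prediction errors from [build_error_records()].  Eligibility for
#' the bootstrap requires at least `min_repeats` individual trials of each
#' constituent condition.
#'
#' @param trials trial table (see [simulate_experiment()]).
#' @param errors error records from [build_error_records()]; computed from
#'   `trials` when `NULL`.
#' @param threshold magnitude filter, N.
#' @param min_repeats minimum individual repeats per constituent condition.
#' @return A list of `costim_case` objects (possibly empty).
#' @export
costim_cases <- function(trials, errors = NULL, threshold = 0.03,
                         min_repeats = 4L) {
  if (is.null(errors))
    errors <- build_error_records(trials, threshold)
  kept <- apply_magnitude_filter(trials, threshold)$kept
  site_cols <- c(spinal = "spinal_amplitude_uA", muscle1 = "muscle1_amplitude_uA",
                 muscle2 = "muscle2_amplitude_uA")
  amp <- as.matrix(kept[, site_cols])
  singles <- kept[rowSums(amp > 0) == 1L, , drop = FALSE]
  if (nrow(errors) == 0L) return(list())
  key <- interaction(errors$subject_id, errors$site_a, errors$site_b,
                     errors$amp_a_uA, errors$amp_b_uA, drop = TRUE)
  out <- list()
  for (k in levels(key)) {
    e <- errors[key == k, , drop = FALSE]
    subj <- e$subject_id[1]
    pull <- function(site, a) {
      m <- singles[singles$subject_id == subj &
                   singles[[site_cols[[site]]]] == a, , drop = FALSE]
      list(v = as.matrix(m[, c("fx_N", "fy_N", "fz_N")]),
           t = m$timestamp_min)
    }
    A <- pull(e$site_a[1], e$amp_a_uA[1])
    B <- pull(e$site_b[1], e$amp_b_uA[1])
    case <- structure(list(
      case_id = sprintf("s%d_%s%g_%s%g", subj, e$site_a[1], e$amp_a_uA[1],
                        e$site_b[1], e$amp_b_uA[1]),
      subject_id = subj, type = e$type[1],
      site_a = e$site_a[1], site_b = e$site_b[1],
      amp_a_uA = e$amp_a_uA[1], amp_b_uA = e$amp_b_uA[1],
      v_a = A$v, v_b = B$v, t_a = A$t,
      costim = as.matrix(e[, c("obs_fx_N", "obs_fy_N", "obs_fz_N")]),
      obs_errors = e$prediction_error_N,
      eligible = nrow(A$v) >= min_repeats && nrow(B$v) >= min_repeats),
      class = "costim_case")
    out[[length(out) + 1L]] <- case
  }
  out
}

#' Directly simulate one synthetic co-stimulation case
#'
#' Builds a `costim_case` without the full experiment machinery, for
#' coverage and power studies of the bootstrap: `n_repeats` individual
#' trials per site form the resampling pools, and each of `n_costim`
#' co-stimulation trials is the (optionally nonlinear) combination of fresh
#' individual draws, paired with a prediction formed from one further fresh
#' draw per site - mirroring a block where each individual condition is
#' stimulated once alongside the co-stimulation trial.
#'
#' @param spinal_amp,muscle_amp stimulation currents, uA.
#' @param n_repeats individual trials per site in the resampling pool.
#' @param n_costim number of co-stimulation trials.
#' @param spinal,muscle [recruitment_model()]s.
#' @param spinal_noise,muscle_noise [noise_model()]s.
#' @param interaction [interaction_model()] applied to the co-stimulation
#'   trials only.
#' @return A `costim_case` (uses the current RNG state; seed outside).
#' @export
simulate_costim_case <- function(spinal_amp = 400, muscle_amp = 1320,
                                 n_repeats = 16L, n_costim = 1L,
                                 spinal = default_recruitment_model("spinal"),
                                 muscle = default_recruitment_model("muscle"),
                                 spinal_noise = default_noise_model("spinal"),
                                 muscle_noise = default_noise_model("muscle"),
                                 interaction = interaction_model("none")) {
  stopifnot(n_repeats >= 1L, n_costim >= 1L)
  S <- simulate_response(spinal, spinal_noise, spinal_amp, n = n_repeats)
  M <- simulate_response(muscle, muscle_noise, muscle_amp, n = n_repeats)
  if (n_repeats == 1L) { S <- matrix(S, 1); M <- matrix(M, 1) }
  C <- matrix(NA_real_, n_costim, 3)
  errs <- numeric(n_costim)
  for (j in seq_len(n_costim)) {
    C[j, ] <- simulate_costim(
      simulate_response(spinal, spinal_noise, spinal_amp),
      simulate_response(muscle, muscle_noise, muscle_amp), interaction)
    pred <- predict_costim(simulate_response(spinal, spinal_noise, spinal_amp),
                           simulate_response(muscle, muscle_noise, muscle_amp))
    errs[j] <- prediction_error(pred, C[j, ])
  }
  structure(list(case_id = sprintf("sim_%g_%g", spinal_amp, muscle_amp),
                 subject_id = 1L, type = "spinal/muscle",
                 site_a = "spinal", site_b = "muscle1",
                 amp_a_uA = spinal_amp, amp_b_uA = muscle_amp,
                 v_a = S, v_b = M, t_a = seq_len(n_repeats),
                 costim = C, obs_errors = errs, eligible = n_repeats >= 4L),
            class = "costim_case")
}

#' Screen a case for fatigue
#'
#' Regresses the spinal-response force magnitude on elapsed session time
#' (minutes) by ordinary least squares and flags the case for exclusion when
#' the slope is negative with two-sided p below `alpha` - a significant
#' decline of evoked force over the experiment.  Cases without a spinal site
#' (muscle/muscle pairs) are kept.  When all timestamps coincide the
#' regression is undefined and the case is kept with a warning.
#'
#' @param case a `costim_case`.
#' @param alpha significance level for exclusion.
#' @return List with `keep` (logical), `slope` (N/min), `p_value` and `n`.
#' @export
fatigue_exclusion <- function(case, alpha = 0.01) {
  stopifnot(inherits(case, "costim_case"))
  if (case$site_a != "spinal")
    return(list(keep = TRUE, slope = NA_real_, p_value = NA_real_,
                n = 0L, reason = "no spinal site"))
  mag <- vec_magnitude(case$v_a)
  t <- case$t_a
  if (length(mag) < 3L)
    stop("need at least 3 spinal trials for the fatigue regression")
  if (length(unique(t)) < 2L) {
    warning("all spinal timestamps identical; fatigue regression undefined, case kept")
    return(list(keep = TRUE, slope = NA_real_, p_value = NA_real_,
                n = length(mag), reason = "identical timestamps"))
  }
  fit <- stats::lm(mag ~ t)
  co <- summary(fit)$coefficients
  slope <- co["t", "Estimate"]; p <- co["t", "Pr(>|t|)"]
  list(keep = !(slope < 0 && p < alpha), slope = slope, p_value = p,
       n = length(mag))
}

#' Bootstrap null distribution of prediction errors for one case
#'
#' Estimates the distribution of force prediction errors expected if the two
#' sites' responses combined exactly linearly while carrying their observed
#' trial-to-trial variability.  `n_draws` resamples (with replacement) of
#' each site's individual trials are summed pairwise to give simulated
#' "observed" co-stimulation vectors; a second, independent resampling gives
#' matched "predicted" vectors; the Euclidean distance between the matched
#' pairs yields `n_draws` error draws, whose 2.5th and 97.5th percentiles
#' form the 95% confidence interval.  The case's actual mean prediction
#' error (averaged over its real co-stimulation trials) is compared against
#' that interval.
#'
#' @param case an eligible `costim_case` (>= 4 repeats of each individual
#'   condition).
#' @param n_draws number of bootstrap draws (>= 100).
#' @return An object of class `bootstrap_result`: `case_id`, `type`,
#'   `errors` (the draws), `ci_lower`, `ci_upper`, `observed_mean_error`,
#'   `within_ci`, `n_draws`.  Uses the current RNG state; seed outside for
#'   reproducible intervals.
#' @export
bootstrap_error_distribution <- function(case, n_draws = 5000L) {
  stopifnot(inherits(case, "costim_case"))
  na <- nrow(case$v_a); nb <- nrow(case$v_b)
  if (na < 4L || nb < 4L)
    stop(sprintf("case %s has %d/%d individual repeats; need at least 4 of each",
                 case$case_id, na, nb))
  if (n_draws < 100L)
    stop("n_draws must be at least 100 for a stable percentile interval")
  obs <- case$v_a[sample.int(na, n_draws, TRUE), , drop = FALSE] +
         case$v_b[sample.int(nb, n_draws, TRUE), , drop = FALSE]
  pred <- case$v_a[sample.int(na, n_draws, TRUE), , drop = FALSE] +
          case$v_b[sample.int(nb, n_draws, TRUE), , drop = FALSE]
  errs <- sqrt(rowSums((obs - pred)^2))
  ci <- unname(stats::quantile(errs, c(0.025, 0.975)))
  obs_err <- mean(case$obs_errors)
  structure(list(case_id = case$case_id, type = case$type, errors = errs,
                 ci_lower = ci[1], ci_upper = ci[2],
                 observed_mean_error = obs_err,
                 within_ci = obs_err >= ci[1] && obs_err <= ci[2],
                 n_draws = as.integer(n_draws)),
            class = "bootstrap_result")
}

#' Summarize bootstrap results across cases
#'
#' @param results list of `bootstrap_result`s (at least one).
#' @return List with `table` (one row per case: case id, type, CI bounds,
#'   observed mean error, within-CI flag), `n`, `n_within` and `fraction`.
#' @export
assess_cases <- function(results) {
  if (length(results) == 0L) stop("need at least one bootstrap result")
  tab <- do.call(rbind, lapply(results, function(r)
    data.frame(case_id = r$case_id, type = r$type,
               observed_mean_error_N = r$observed_mean_error,
               ci_lower_N = r$ci_lower, ci_upper_N = r$ci_upper,
               within_ci = r$within_ci, n_draws = r$n_draws)))
  rownames(tab) <- NULL
  list(table = tab, n = nrow(tab), n_within = sum(tab$within_ci),
       fraction = mean(tab$within_ci))
}
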