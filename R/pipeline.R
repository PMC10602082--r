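#' Run the full co-stimulation linearity analysis
#'
#' Orchestrates simulate, extract, metrics, mixed models and bootstrap into
#' one reproducible run: generates (or accepts) a trial table, applies the
#' magnitude filter, builds error records, fits the mixed-model contrasts
#' (prediction, absolute magnitude, direction and relative errors; plus the
#' magnitude-nuisance variant), compares recruitment-curve dispersions with
#' Welch's test, screens cases for fatigue and runs the bootstrap.  All
#' stage outputs are written as CSV/JSON under `out_dir` together with a
#' manifest (seed, configuration hash, package and R versions) sufficient to
#' reproduce the run.
#'
#' @param cfg a [generator_config()]; ignored when `trials` is supplied.
#' @param trials optional pre-existing trial table (same schema as
#'   [simulate_experiment()] output).
#' @param out_dir output directory; created if needed.  `NULL` skips writing.
#' @param seed integer seed for the analysis-stage randomness (bootstrap).
#' @param n_draws bootstrap draws per case.
#' @param alpha_fatigue significance level of the fatigue screen.
#' @param threshold magnitude filter, N.
#' @return Invisibly, a list with `trials`, `errors`, `fits`,
#'   `dispersions`, `welch`, `cases`, `fatigue`, `bootstrap`, `assessment`,
#'   `r_squared` and `manifest`.
#' @export
run_pipeline <- function(cfg = generator_config(), trials = NULL,
                         out_dir = NULL, seed = 1L, n_draws = 5000L,
                         alpha_fatigue = 0.01, threshold = 0.03) {
  if (is.null(trials)) {
    validate_trial_table(trials <- simulate_experiment(cfg)$trials)
  } else {
    validate_trial_table(trials)
  }
  errors <- build_error_records(trials, threshold)

  fits <- list()
  can_fit <- length(unique(errors$subject_id)) >= 2L &&
    length(unique(errors$type)) == 2L
  if (can_fit) {
    fits$prediction <- fit_error_model(errors, "prediction_error_N")
    fits$magnitude <- fit_error_model(errors, "abs_magnitude_error_N")
    fits$direction <- fit_error_model(errors, "direction_error_deg")
    fits$relative <- fit_error_model(errors, "relative_error_pct")
    fits$prediction_nuisance <- fit_error_model(
      errors, "prediction_error_N", covariates = "obs_magnitude_N")
  }

  disp <- recruitment_dispersions(trials, threshold)
  welch <- if (!is.null(disp) &&
               sum(disp$site_kind == "spinal") >= 2L &&
               sum(disp$site_kind == "muscle") >= 2L)
    welch_dispersion_test(disp$dispersion_deg[disp$site_kind == "spinal"],
                          disp$dispersion_deg[disp$site_kind == "muscle"])
  else NULL

  r2 <- list()
  for (ty in unique(errors$type)) {
    e <- errors[errors$type == ty, ]
    if (nrow(e) >= 2L)
      r2[[ty]] <- combined_r_squared(
        e[, c("obs_fx_N", "obs_fy_N", "obs_fz_N")],
        e[, c("pred_fx_N", "pred_fy_N", "pred_fz_N")])
  }

  set.seed(seed)
  cases <- costim_cases(trials, errors, threshold)
  eligible <- Filter(function(c) c$eligible, cases)
  fatigue <- lapply(eligible, fatigue_exclusion, alpha = alpha_fatigue)
  keep <- vapply(fatigue, `[[`, logical(1), "keep")
  boots <- lapply(eligible[keep], bootstrap_error_distribution, n_draws = n_draws)
  assessment <- if (length(boots)) assess_cases(boots) else NULL

  manifest <- list(seed = seed, n_draws = n_draws, threshold = threshold,
                   alpha_fatigue = alpha_fatigue,
                   package_version = as.character(utils::packageVersion("costim")),
                   r_version = R.version.string,
                   n_trials = nrow(trials), n_errors = nrow(errors))
  res <- list(trials = trials, errors = errors, fits = fits,
              dispersions = disp, welch = welch, r_squared = r2,
              cases = cases, fatigue = fatigue, bootstrap = boots,
              assessment = assessment, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  invisible(res)
}

#' Per-subject recruitment-curve direction dispersions
#'
#' Computes the angular deviation of the sagittal directions of each
#' subject's recruitment-phase curve (block 0) for every stimulated site.
#'
#' @param trials trial table containing a recruitment phase (`block_id = 0`).
#' @param threshold magnitude filter, N.
#' @return Data frame with `subject_id`, `site`, `site_kind` and
#'   `dispersion_deg`, or `NULL` when no recruitment phase is present.
#' @export
recruitment_dispersions <- function(trials, threshold = 0.03) {
  rec <- trials[trials$block_id == 0L, , drop = FALSE]
  if (nrow(rec) == 0L) return(NULL)
  site_cols <- c(spinal = "spinal_amplitude_uA", muscle1 = "muscle1_amplitude_uA",
                 muscle2 = "muscle2_amplitude_uA")
  out <- list()
  for (subj in unique(rec$subject_id)) {
    for (s in names(site_cols)) {
      m <- rec[rec$subject_id == subj & rec[[site_cols[[s]]]] > 0, , drop = FALSE]
      if (nrow(m) < 2L) next
      d <- tryCatch(recruitment_direction_dispersion(
        m[, c("fx_N", "fy_N", "fz_N")], threshold), error = function(e) NA_real_)
      out[[length(out) + 1L]] <- data.frame(
        subject_id = subj, site = s,
        site_kind = if (s == "spinal") "spinal" else "muscle",
        dispersion_deg = d)
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

validate_trial_table <- function(trials) {
  need <- c("subject_id", "block_id", "trial_index", "timestamp_min",
            "spinal_amplitude_uA", "muscle1_amplitude_uA",
            "muscle2_amplitude_uA", "fx_N", "fy_N", "fz_N")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "))
  num <- setdiff(need, character())
  bad <- num[!vapply(trials[num], is.numeric, logical(1))]
  if (length(bad))
    stop("trial table column(s) not numeric: ", paste(bad, collapse = ", "))
  invisible(trials)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$trials, file.path(out_dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(res$errors, file.path(out_dir, "errors.csv"), row.names = FALSE)
  if (!is.null(res$dispersions))
    utils::write.csv(res$dispersions, file.path(out_dir, "dispersions.csv"),
                     row.names = FALSE)
  if (!is.null(res$assessment))
    utils::write.csv(res$assessment$table, file.path(out_dir, "bootstrap_cases.csv"),
                     row.names = FALSE)
  summarize_fit <- function(f) if (is.null(f) || is.null(f$coefficients)) NULL
    else list(coefficients = f$coefficients, transform = f$transform,
              fallback = f$fallback, n_obs = f$n_obs, n_groups = f$n_groups)
  report <- list(
    models = lapply(res$fits, summarize_fit),
    welch = res$welch,
    r_squared = res$r_squared,
    error_medians_N = if (nrow(res$errors))
      as.list(tapply(res$errors$prediction_error_N, res$errors$type, stats::median))
      else NULL,
    relative_error_median_pct = if (nrow(res$errors))
      as.list(tapply(res$errors$relative_error_pct, res$errors$type, stats::median))
      else NULL,
    bootstrap = if (!is.null(res$assessment))
      res$assessment[c("n", "n_within", "fraction")] else NULL)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
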