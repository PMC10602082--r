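#!/usr/bin/env Rscript
# Stage 4: group-level inference.
#
# Mixed-effects contrasts of each error measure by co-stimulation type
# (spinal/muscle vs muscle/muscle), with subject as a random factor
# (intercept and type slope) and maximum-likelihood estimation; the
# magnitude-nuisance variant adds the observed co-stimulation magnitude as
# a fixed covariate.  A separate traces run feeds the windowed time-course
# analysis and the early (100-300 ms) vs late (300-500 ms) contrast.

suppressPackageStartupMessages(library(costim))
errors <- read.csv("results/errors.csv")

responses <- c(prediction = "prediction_error_N",
               magnitude = "abs_magnitude_error_N",
               direction = "direction_error_deg",
               relative = "relative_error_pct")
fits <- list()
cat("Mixed-model contrasts (spinal/muscle - muscle/muscle):\n")
for (nm in names(responses)) {
  fit <- fit_error_model(errors, response = responses[[nm]])
  fits[[nm]] <- fit
  co <- fit$coefficients[fit$coefficients$term == "typespinal/muscle", ]
  cat(sprintf("  %-10s effect %+.3f +/- %.3f (%s scale), p = %.2g%s\n", nm,
              co$estimate, co$se, fit$transform, co$p,
              if (fit$fallback) " [intercept-only fallback]" else ""))
}
fit_nuis <- fit_error_model(errors, covariates = "obs_magnitude_N")
co <- fit_nuis$coefficients[fit_nuis$coefficients$term == "typespinal/muscle", ]
cat(sprintf("  %-10s effect %+.3f +/- %.3f (%s scale), p = %.2g\n",
            "pred+mag", co$estimate, co$se, fit_nuis$transform, co$p))
fits$prediction_nuisance <- fit_nuis

out <- lapply(fits, function(f)
  list(coefficients = f$coefficients, transform = f$transform,
       fallback = f$fallback, n_obs = f$n_obs, n_groups = f$n_groups))
jsonlite::write_json(out, "results/models.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)

# Time-course analysis on a traces run (smaller: traces are bulky).
cfg <- generator_config(n_subjects = 3, n_blocks = 3, recruitment_repeats = 0,
                        seed = 404)
ex <- simulate_experiment(cfg, traces = TRUE)
wa <- windowed_error_analysis(ex$trials, ex$traces)
write.csv(wa$summary, "results/windowed_errors.csv", row.names = FALSE)
el <- early_late_contrast(ex$trials, ex$traces)
co <- el$fit$coefficients[el$fit$coefficients$term == "periodlate", ]
cat(sprintf("Early vs late train windows (spinal/muscle only): effect %+.4f (%s scale), p = %.2g\n",
            co$estimate, el$fit$transform, co$p))
cat("Models written to results/models.json, windowed errors to results/windowed_errors.csv\n")
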