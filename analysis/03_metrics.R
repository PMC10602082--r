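#!/usr/bin/env Rscript
# Stage 3: linearity metrics.
#
# Pairs every co-stimulation trial with the same-block individual responses,
# forms the linear-summation prediction, and computes the four error
# measures plus the combined R-squared per co-stimulation type and the
# recruitment-curve direction dispersions (with Welch's test).

suppressPackageStartupMessages(library(costim))
trials <- read.csv("results/trials.csv")

errors <- build_error_records(trials)
rounded <- errors
num <- vapply(rounded, is.numeric, logical(1))
rounded[num] <- lapply(rounded[num], signif, digits = 6)
write.csv(rounded, "results/errors.csv", row.names = FALSE)

cat("Error records:", nrow(errors), "co-stimulation trials\n")
med <- tapply(errors$prediction_error_N, errors$type, median)
rel <- tapply(errors$relative_error_pct, errors$type, median)
for (ty in names(med))
  cat(sprintf("  %-13s median prediction error %.3f N (relative %.0f%%)\n",
              ty, med[[ty]], rel[[ty]]))

for (ty in unique(errors$type)) {
  e <- errors[errors$type == ty, ]
  r2 <- combined_r_squared(e[, c("obs_fx_N", "obs_fy_N", "obs_fz_N")],
                           e[, c("pred_fx_N", "pred_fy_N", "pred_fz_N")])
  cat(sprintf("  %-13s combined R-squared %.3f\n", ty, r2))
}

disp <- recruitment_dispersions(trials)
write.csv(disp, "results/dispersions.csv", row.names = FALSE)
sp <- disp$dispersion_deg[disp$site_kind == "spinal"]
mu <- disp$dispersion_deg[disp$site_kind == "muscle"]
w <- welch_dispersion_test(sp, mu)
cat(sprintf("Recruitment-curve dispersion: spinal %.1f +/- %.1f deg vs muscle %.1f +/- %.1f deg\n",
            mean(sp), sd(sp), mean(mu), sd(mu)))
cat(sprintf("  Welch's t = %.2f, df = %.1f, p = %.2g\n",
            w$statistic, w$df, w$p_value))
cat("Errors written to results/errors.csv, dispersions to results/dispersions.csv\n")
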