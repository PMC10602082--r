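#' Mixed-effects contrast of prediction errors
#'
#' Fits a linear mixed model by maximum likelihood for one error measure,
#' with a categorical fixed factor (by default the co-stimulation type,
#' spinal/muscle versus muscle/muscle), optional continuous covariates (for
#' instance the observed co-stimulation magnitude as a nuisance variable),
#' and by-subject random effects.  With `transform = "auto"` the response is
#' log transformed when a Shapiro-Wilk check on the untransformed model's
#' residuals rejects normality at alpha = 0.05; with `"log"` it always is.
#' Non-positive responses are dropped before a log transform, with a
#' message.  If the random-slope fit fails to converge the model falls back
#' to a by-subject random intercept, flagged in the result.
#'
#' Fixed-effect p-values use Satterthwaite degrees of freedom by default;
#' `p_method = "wald"` gives normal-approximation Wald p-values instead.
#'
#' @param data data frame of error records (see [build_error_records()]).
#' @param response name of the response column, e.g. `"prediction_error_N"`,
#'   `"abs_magnitude_error_N"`, `"direction_error_deg"`,
#'   `"relative_error_pct"`.
#' @param factor name of the categorical fixed factor (two levels present).
#' @param covariates optional character vector of extra fixed-effect columns.
#' @param group grouping column for random effects (>= 2 levels).
#' @param transform `"auto"`, `"none"` or `"log"`.
#' @param random `"intercept+slope"` (random intercept and slope for the
#'   factor, per group) or `"intercept"`.
#' @param p_method `"satterthwaite"` or `"wald"`.
#' @return An object of class `error_model_fit`: `coefficients` (term,
#'   estimate, se, df, t, p), `transform`, `fallback`, `converged`,
#'   `n_obs`, `n_groups`, `formula` and the underlying `fit`.
#' @export
fit_error_model <- function(data, response = "prediction_error_N",
                            factor = "type", covariates = NULL,
                            group = "subject_id",
                            transform = c("auto", "none", "log"),
                            random = c("intercept+slope", "intercept"),
                            p_method = c("satterthwaite", "wald")) {
  transform <- match.arg(transform)
  random <- match.arg(random)
  p_method <- match.arg(p_method)
  stopifnot(response %in% names(data), factor %in% names(data),
            group %in% names(data))
  d <- data
  d$.y <- d[[response]]
  d$.g <- base::factor(d[[group]])
  d$.f <- base::factor(d[[factor]])
  d <- d[stats::complete.cases(d[, c(".y", ".g", ".f", covariates)]), ]
  if (nlevels(droplevels(d$.g)) < 2L)
    stop("random structure unidentifiable with a single subject")
  if (nlevels(droplevels(d$.f)) < 2L)
    stop("both levels of '", factor, "' must be present")

  rhs_fixed <- paste(c(".f", covariates), collapse = " + ")
  re <- if (random == "intercept+slope") "(1 + .f | .g)" else "(1 | .g)"
  form <- stats::as.formula(paste(".y ~", rhs_fixed, "+", re))

  do_fit <- function(formula, dat) {
    lmerTest::lmer(formula, data = dat, REML = FALSE,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore"))
  }
  fit_once <- function(dat, use_log) {
    dd <- dat
    if (use_log) {
      bad <- dd$.y <= 0
      if (any(bad)) {
        message(sum(bad), " non-positive response value(s) excluded before log transform")
        dd <- dd[!bad, , drop = FALSE]
      }
      dd$.y <- log(dd$.y)
    }
    fallback <- FALSE
    fit <- tryCatch(suppressMessages(do_fit(form, dd)),
                    error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) && random == "intercept+slope") {
      fallback <- TRUE
      form2 <- stats::as.formula(paste(".y ~", rhs_fixed, "+ (1 | .g)"))
      fit <- tryCatch(suppressMessages(do_fit(form2, dd)),
                      error = function(e) NULL, warning = function(w) NULL)
    }
    list(fit = fit, fallback = fallback, data = dd)
  }

  use_log <- transform == "log"
  if (transform == "auto") {
    f0 <- fit_once(d, use_log = FALSE)
    if (!is.null(f0$fit)) {
      r <- stats::residuals(f0$fit)
      if (length(r) > 4999) r <- sample(r, 4999)
      if (length(r) >= 3 && stats::shapiro.test(r)$p.value < 0.05)
        use_log <- TRUE
    }
    if (!use_log) {
      res <- f0
    } else res <- fit_once(d, use_log = TRUE)
  } else {
    res <- fit_once(d, use_log)
  }
  if (is.null(res$fit))
    return(structure(list(coefficients = NULL, transform = if (use_log) "log" else "none",
                          fallback = res$fallback, converged = FALSE,
                          n_obs = nrow(res$data), n_groups = nlevels(droplevels(d$.g)),
                          formula = deparse(form), fit = NULL),
                     class = "error_model_fit"))
  co <- stats::coef(summary(res$fit))
  p <- if (p_method == "satterthwaite") co[, "Pr(>|t|)"]
       else 2 * stats::pnorm(-abs(co[, "t value"]))
  terms <- rownames(co)
  terms <- sub("^\\.f", paste0(factor, ""), terms)
  coefs <- data.frame(term = terms, estimate = co[, "Estimate"],
                      se = co[, "Std. Error"],
                      df = if ("df" %in% colnames(co)) co[, "df"] else NA_real_,
                      t = co[, "t value"], p = p, row.names = NULL)
  structure(list(coefficients = coefs,
                 transform = if (use_log) "log" else "none",
                 fallback = res$fallback, converged = TRUE,
                 n_obs = nrow(res$data),
                 n_groups = nlevels(droplevels(d$.g)),
                 formula = deparse(form), fit = res$fit),
            class = "error_model_fit")
}

#' @export
print.error_model_fit <- function(x, ...) {
  cat("<error_model_fit>", x$formula, "\n")
  cat(sprintf("  n = %d obs, %d subjects; transform = %s%s%s\n", x$n_obs,
              x$n_groups, x$transform,
              if (x$fallback) "; random-intercept fallback" else "",
              if (!x$converged) "; DID NOT CONVERGE" else ""))
  if (!is.null(x$coefficients)) {
    print(format(x$coefficients, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' Welch's t test on recruitment-curve dispersions
#'
#' Compares per-curve angular deviations between spinal and muscle
#' recruitment curves with Welch's unequal-variance two-sample t test.  When
#' both groups are degenerate (zero variance) the test short-circuits:
#' p = 1 if the group means are equal, p = 0 otherwise.
#'
#' @param spinal_dispersions,muscle_dispersions numeric vectors (>= 2 values
#'   each) of per-curve angular deviations, degrees.
#' @return List with `statistic`, `p_value`, `df`, and the group means.
#' @export
welch_dispersion_test <- function(spinal_dispersions, muscle_dispersions) {
  x <- spinal_dispersions; y <- muscle_dispersions
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(statistic = if (same) 0 else Inf,
                p_value = if (same) 1 else 0, df = NA_real_,
                mean_spinal = mean(x), mean_muscle = mean(y)))
  }
  tt <- stats::t.test(x, y)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_spinal = mean(x), mean_muscle = mean(y))
}

# Mean windowed vectors of the same-block individual trials for each
# constituent site of a co-stimulation trial; NULL when either is missing.
matched_individual_windows <- function(tr, singles, traces, site_cols,
                                       width_ms, duration_ms) {
  a <- as.numeric(tr[site_cols]); names(a) <- names(site_cols)
  active <- names(a)[a > 0]
  parts <- lapply(active, function(s) {
    m <- singles[singles$subject_id == tr$subject_id &
                 singles$block_id == tr$block_id &
                 singles[[site_cols[[s]]]] == a[[s]], , drop = FALSE]
    if (nrow(m) == 0L) return(NULL)
    ws <- lapply(seq_len(nrow(m)), function(j) {
      key <- sprintf("s%d_t%d", m$subject_id[j], m$trial_index[j])
      if (is.null(traces[[key]])) return(NULL)
      wv <- windowed_vectors(demean_trace(traces[[key]]), width_ms, duration_ms)
      as.matrix(wv[, c("fx", "fy", "fz")])
    })
    ws <- ws[!vapply(ws, is.null, logical(1))]
    if (length(ws) == 0L) return(NULL)
    Reduce(`+`, ws) / length(ws)
  })
  if (any(vapply(parts, is.null, logical(1)))) return(NULL)
  list(active = active, pred = parts[[1]] + parts[[2]])
}

#' Windowed prediction errors across the stimulation train
#'
#' Splits each co-stimulation trace and its same-block individual-site
#' traces into contiguous windows (50 ms by default) over the first
#' `duration_ms` of the train, sums the individual windowed vectors into
#' per-window predictions, and reports one prediction error per window per
#' co-stimulation trial, together with per-subject mean and standard error
#' by type and window.
#'
#' @param trials trial table.
#' @param traces named list of traces (`s<subject>_t<trial_index>`).
#' @param width_ms window width, ms.
#' @param duration_ms analyzed span from onset, ms; 500 ms by default so the
#'   same span applies to the 600 ms spinal and 520 ms muscle trains.
#' @param threshold magnitude filter, N, applied to whole-train vectors.
#' @return List with `errors` (subject_id, block_id, trial_index, type,
#'   window_start_ms, prediction_error_N) and `summary` (per subject x type
#'   x window mean and SEM).
#' @export
windowed_error_analysis <- function(trials, traces, width_ms = 50,
                                    duration_ms = 500, threshold = 0.03) {
  kept <- apply_magnitude_filter(trials, threshold)$kept
  site_cols <- c(spinal = "spinal_amplitude_uA", muscle1 = "muscle1_amplitude_uA",
                 muscle2 = "muscle2_amplitude_uA")
  amp <- as.matrix(kept[, site_cols])
  n_active <- rowSums(amp > 0)
  singles <- kept[n_active == 1L, , drop = FALSE]
  costim <- kept[n_active == 2L, , drop = FALSE]
  out <- list(); skipped <- 0L
  for (i in seq_len(nrow(costim))) {
    tr <- costim[i, ]
    key <- sprintf("s%d_t%d", tr$subject_id, tr$trial_index)
    if (is.null(traces[[key]])) { skipped <- skipped + 1L; next }
    obs <- windowed_vectors(demean_trace(traces[[key]]), width_ms, duration_ms)
    mm <- matched_individual_windows(tr, singles, traces, site_cols,
                                     width_ms, duration_ms)
    if (is.null(mm)) { skipped <- skipped + 1L; next }
    err <- prediction_error(mm$pred, as.matrix(obs[, c("fx", "fy", "fz")]))
    out[[length(out) + 1L]] <- data.frame(
      subject_id = tr$subject_id, block_id = tr$block_id,
      trial_index = tr$trial_index,
      type = if ("spinal" %in% mm$active) "spinal/muscle" else "muscle/muscle",
      window_start_ms = obs$window_start_ms,
      prediction_error_N = err)
  }
  if (skipped > 0L)
    message(skipped, " co-stimulation trial(s) skipped in windowed analysis")
  errors <- if (length(out)) do.call(rbind, out) else
    data.frame(subject_id = integer(), block_id = integer(),
               trial_index = integer(), type = character(),
               window_start_ms = numeric(), prediction_error_N = numeric())
  rownames(errors) <- NULL
  summary <- if (nrow(errors)) {
    agg <- stats::aggregate(prediction_error_N ~ subject_id + type + window_start_ms,
                            errors, function(v) c(mean = mean(v),
                                                  sem = stats::sd(v) / sqrt(length(v))))
    data.frame(agg[, 1:3], mean_error_N = agg$prediction_error_N[, "mean"],
               sem_N = agg$prediction_error_N[, "sem"])
  } else NULL
  list(errors = errors, summary = summary)
}

#' Early versus late prediction errors in the stimulation train
#'
#' For spinal/muscle co-stimulation trials only, computes prediction errors
#' on an early (100-300 ms) and a late (300-500 ms) window of the train -
#' each a 200 ms window average, predicted from the matching windows of the
#' same-block individual traces - and contrasts the two periods in a mixed
#' model with period as the fixed factor and the usual by-subject random
#' structure.
#'
#' @inheritParams windowed_error_analysis
#' @param early,late two-element vectors of window bounds, ms after onset.
#' @param ... passed to [fit_error_model()] (e.g. `transform`, `random`).
#' @return List with `errors` (one row per trial x period) and `fit` (an
#'   `error_model_fit` of error on period).
#' @export
early_late_contrast <- function(trials, traces, early = c(100, 300),
                                late = c(300, 500), threshold = 0.03, ...) {
  kept <- apply_magnitude_filter(trials, threshold)$kept
  site_cols <- c(spinal = "spinal_amplitude_uA", muscle1 = "muscle1_amplitude_uA",
                 muscle2 = "muscle2_amplitude_uA")
  amp <- as.matrix(kept[, site_cols])
  n_active <- rowSums(amp > 0)
  singles <- kept[n_active == 1L, , drop = FALSE]
  costim <- kept[n_active == 2L & kept$spinal_amplitude_uA > 0, , drop = FALSE]
  periods <- list(early = early, late = late)
  out <- list()
  for (i in seq_len(nrow(costim))) {
    tr <- costim[i, ]
    key <- sprintf("s%d_t%d", tr$subject_id, tr$trial_index)
    if (is.null(traces[[key]])) next
    obs_tr <- demean_trace(traces[[key]])
    a <- as.numeric(tr[site_cols]); names(a) <- names(site_cols)
    active <- names(a)[a > 0]
    for (pn in names(periods)) {
      w <- periods[[pn]]
      obs <- window_mean(obs_tr, obs_tr$onset_ms + w[1], obs_tr$onset_ms + w[2])
      parts <- lapply(active, function(s) {
        m <- singles[singles$subject_id == tr$subject_id &
                     singles$block_id == tr$block_id &
                     singles[[site_cols[[s]]]] == a[[s]], , drop = FALSE]
        if (nrow(m) == 0L) return(NULL)
        vs <- lapply(seq_len(nrow(m)), function(j) {
          k2 <- sprintf("s%d_t%d", m$subject_id[j], m$trial_index[j])
          if (is.null(traces[[k2]])) return(NULL)
          t2 <- demean_trace(traces[[k2]])
          window_mean(t2, t2$onset_ms + w[1], t2$onset_ms + w[2])
        })
        vs <- vs[!vapply(vs, is.null, logical(1))]
        if (length(vs) == 0L) return(NULL)
        Reduce(`+`, vs) / length(vs)
      })
      if (any(vapply(parts, is.null, logical(1)))) next
      pred <- parts[[1]] + parts[[2]]
      out[[length(out) + 1L]] <- data.frame(
        subject_id = tr$subject_id, block_id = tr$block_id,
        trial_index = tr$trial_index, period = pn,
        prediction_error_N = prediction_error(pred, obs))
    }
  }
  errors <- do.call(rbind, out)
  rownames(errors) <- NULL
  fit <- if (!is.null(errors) && nrow(errors) > 0)
    fit_error_model(errors, response = "prediction_error_N", factor = "period", ...)
  else NULL
  list(errors = errors, fit = fit)
}
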