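#' Linearity metrics for co-stimulation force vectors
#'
#' The linear-summation null predicts that the force evoked by stimulating
#' two sites together equals the component-wise sum of the forces evoked by
#' each site alone.  `predict_costim()` forms that prediction;
#' `prediction_error()` is the Euclidean distance between predicted and
#' observed co-stimulation vectors; `magnitude_error()` the signed difference
#' of magnitudes (observed minus predicted); `direction_error()` the 3-D
#' angle between the two vectors; `relative_error()` the prediction error as
#' a percentage of the observed co-stimulation magnitude.
#'
#' @param v_a,v_b,pred,obs force vectors (length 3) or n x 3 matrices of
#'   vectors (rowwise, vectorized over rows).
#' @return `predict_costim()` a force vector (or matrix); the error functions
#'   numeric values, one per row.
#' @examples
#' predict_costim(c(0.5, 0, 0), c(0, 0.5, 0))
#' prediction_error(c(1, 0, 0), c(0, 1, 0))   # sqrt(2)
#' direction_error(c(1, 0, 0), c(1, 1, 0))    # 45 degrees
#' @export
predict_costim <- function(v_a, v_b) {
  a <- as_force_matrix(v_a); b <- as_force_matrix(v_b)
  stopifnot(nrow(a) == nrow(b))
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("force vectors must be finite")
  s <- a + b
  colnames(s) <- c("fx", "fy", "fz")
  if (nrow(s) == 1L) drop(s) else s
}

#' @rdname predict_costim
#' @export
prediction_error <- function(pred, obs) {
  p <- as_force_matrix(pred); o <- as_force_matrix(obs)
  stopifnot(nrow(p) == nrow(o))
  sqrt(rowSums((o - p)^2))
}

#' @rdname predict_costim
#' @export
magnitude_error <- function(pred, obs) {
  vec_magnitude(obs) - vec_magnitude(pred)
}

#' @rdname predict_costim
#' @export
direction_error <- function(pred, obs) {
  p <- as_force_matrix(pred); o <- as_force_matrix(obs)
  stopifnot(nrow(p) == nrow(o))
  mp <- sqrt(rowSums(p^2)); mo <- sqrt(rowSums(o^2))
  d <- rowSums(p * o) / (mp * mo)
  out <- acos(pmin(1, pmax(-1, d))) * 180 / pi
  bad <- mp == 0 | mo == 0
  if (any(bad)) {
    warning("direction error undefined for zero-magnitude vectors; returning NA")
    out[bad] <- NA_real_
  }
  out
}

#' @rdname predict_costim
#' @export
relative_error <- function(pred, obs) {
  100 * prediction_error(pred, obs) / vec_magnitude(obs)
}

#' Combined coefficient of determination across force axes
#'
#' Pools the three axes into one R-squared: one minus the summed squared
#' residuals over all axes divided by the summed total sums of squares, each
#' axis centered by its own observed mean.  Equals 1 for perfect prediction
#' and 0 when every prediction equals the per-axis observed mean.
#'
#' @param observed,predicted n x 3 matrices (or data frames) of matched
#'   observed and predicted force vectors, n >= 2.
#' @return A single dimensionless value (<= 1), or `NA` with a warning when
#'   the observed values have zero total sum of squares.
#' @export
combined_r_squared <- function(observed, predicted) {
  o <- as_force_matrix(observed); p <- as_force_matrix(predicted)
  stopifnot(nrow(o) == nrow(p))
  if (nrow(o) < 2L) stop("need at least 2 observations")
  rss <- sum((o - p)^2)
  tss <- sum(sweep(o, 2, colMeans(o))^2)
  if (tss == 0) {
    warning("zero total sum of squares; combined R-squared undefined")
    return(NA_real_)
  }
  1 - rss / tss
}

#' Circular angular deviation
#'
#' The circular-statistics dispersion of a set of directions:
#' `sqrt(2 * (1 - R))` radians (reported in degrees), where `R` is the mean
#' resultant length of the unit vectors at the given angles.  It is 0 when
#' all angles coincide and at most `sqrt(2)` rad (about 81.03 degrees) as
#' `R -> 0`.
#'
#' @param angles_deg at least two angles, degrees.
#' @return Angular deviation in degrees.
#' @examples
#' angular_deviation(c(0, 90))   # sqrt(2 - sqrt(2)) rad ~ 43.9 degrees
#' @export
angular_deviation <- function(angles_deg) {
  if (length(angles_deg) < 2L) stop("need at least 2 angles")
  th <- angles_deg * pi / 180
  R <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  sqrt(2 * (1 - R)) * 180 / pi
}

#' Direction dispersion of a recruitment curve
#'
#' Angular deviation of the sagittal-plane directions of a recruitment
#' curve's force vectors, after discarding vectors at or below the magnitude
#' threshold (whose directions are not reliable).
#'
#' @param vectors n x 3 matrix or data frame of force vectors along the
#'   curve (columns fx, fy, fz, in grid order).
#' @param threshold magnitude threshold, N.
#' @return Dispersion in degrees.
#' @export
recruitment_direction_dispersion <- function(vectors, threshold = 0.03) {
  v <- as_force_matrix(vectors)
  v <- v[vec_magnitude(v) > threshold, , drop = FALSE]
  if (nrow(v) < 2L)
    stop("fewer than 2 vectors above the magnitude threshold")
  angular_deviation(sagittal_angle(v))
}

#' Build per-trial prediction-error records
#'
#' Pairs every co-stimulation trial with the individual-site responses
#' recorded in the same block: for each constituent site and amplitude, the
#' same-block single-site trials are averaged (vector mean) and the two site
#' means are summed to form the prediction.  Trials with evoked magnitude at
#' or below the threshold are excluded throughout, and co-stimulation trials
#' lacking a same-block individual response for either site are skipped with
#' a message.
#'
#' @param trials trial table as produced by [simulate_experiment()] (or read
#'   from CSV with the same columns).
#' @param threshold magnitude filter, N (strictly-greater-than).
#' @return Data frame of error records: trial keys, `type`
#'   (`"spinal/muscle"` or `"muscle/muscle"`), predicted and observed
#'   components, `prediction_error_N`, `magnitude_error_N`,
#'   `abs_magnitude_error_N`, `direction_error_deg`, `relative_error_pct`,
#'   `obs_magnitude_N` and `window` (`"whole"`).
#' @export
build_error_records <- function(trials, threshold = 0.03) {
  flt <- apply_magnitude_filter(trials, threshold)
  kept <- flt$kept
  site_cols <- c(spinal = "spinal_amplitude_uA", muscle1 = "muscle1_amplitude_uA",
                 muscle2 = "muscle2_amplitude_uA")
  amp <- as.matrix(kept[, site_cols])
  n_active <- rowSums(amp > 0)
  singles <- kept[n_active == 1L, , drop = FALSE]
  costim <- kept[n_active == 2L, , drop = FALSE]
  out <- list(); skipped <- 0L
  for (i in seq_len(nrow(costim))) {
    tr <- costim[i, ]
    a <- as.numeric(tr[site_cols]); names(a) <- names(site_cols)
    active <- names(a)[a > 0]
    part <- lapply(active, function(s) {
      m <- singles[singles$subject_id == tr$subject_id &
                   singles$block_id == tr$block_id &
                   singles[[site_cols[[s]]]] == a[[s]], , drop = FALSE]
      if (nrow(m) == 0L) return(NULL)
      colMeans(m[, c("fx_N", "fy_N", "fz_N")])
    })
    if (any(vapply(part, is.null, logical(1)))) { skipped <- skipped + 1L; next }
    pred <- predict_costim(part[[1]], part[[2]])
    obs <- as.numeric(tr[c("fx_N", "fy_N", "fz_N")])
    me <- magnitude_error(pred, obs)
    out[[length(out) + 1L]] <- data.frame(
      subject_id = tr$subject_id, block_id = tr$block_id,
      trial_index = tr$trial_index, timestamp_min = tr$timestamp_min,
      type = if ("spinal" %in% active) "spinal/muscle" else "muscle/muscle",
      site_a = active[1], site_b = active[2],
      amp_a_uA = a[[active[1]]], amp_b_uA = a[[active[2]]],
      pred_fx_N = pred[[1]], pred_fy_N = pred[[2]], pred_fz_N = pred[[3]],
      obs_fx_N = obs[1], obs_fy_N = obs[2], obs_fz_N = obs[3],
      prediction_error_N = prediction_error(pred, obs),
      magnitude_error_N = me,
      abs_magnitude_error_N = abs(me),
      direction_error_deg = direction_error(pred, obs),
      relative_error_pct = relative_error(pred, obs),
      obs_magnitude_N = vec_magnitude(obs),
      window = "whole")
  }
  if (skipped > 0L)
    message(skipped, " co-stimulation trial(s) skipped: no same-block individual response")
  if (length(out) == 0L) return(empty_error_records())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_error_records <- function() {
  data.frame(subject_id = integer(), block_id = integer(),
             trial_index = integer(), timestamp_min = numeric(),
             type = character(), site_a = character(), site_b = character(),
             amp_a_uA = numeric(), amp_b_uA = numeric(),
             pred_fx_N = numeric(), pred_fy_N = numeric(), pred_fz_N = numeric(),
             obs_fx_N = numeric(), obs_fy_N = numeric(), obs_fz_N = numeric(),
             prediction_error_N = numeric(), magnitude_error_N = numeric(),
             abs_magnitude_error_N = numeric(),
             direction_error_deg = numeric(), relative_error_pct = numeric(),
             obs_magnitude_N = numeric(), window = character())
}
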