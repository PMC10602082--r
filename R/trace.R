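#' Construct a force trace
#'
#' A force trace holds uniformly sampled 3-axis transducer readings around one
#' stimulation train.  Sample times must be strictly increasing and uniformly
#' spaced (relative tolerance 1e-6); non-uniform recordings are rejected
#' rather than resampled.
#'
#' @param time_ms sample times in milliseconds.
#' @param fx,fy,fz force samples per axis, newtons.
#' @param onset_ms stimulation onset time, ms (default 0).
#' @return An object of class `force_trace`: a list with elements `time_ms`,
#'   `f` (n x 3 matrix), `onset_ms`, `sampling_rate_hz` and a `demeaned` flag.
#' @export
force_trace <- function(time_ms, fx, fy, fz, onset_ms = 0) {
  n <- length(time_ms)
  stopifnot(n >= 2L, length(fx) == n, length(fy) == n, length(fz) == n)
  dt <- diff(time_ms)
  if (any(dt <= 0)) stop("sample times must be strictly increasing")
  if (diff(range(dt)) > 1e-6 * mean(dt))
    stop("sample times must be uniformly spaced; non-uniform traces are rejected")
  structure(list(time_ms = as.numeric(time_ms),
                 f = cbind(fx = as.numeric(fx), fy = as.numeric(fy),
                           fz = as.numeric(fz)),
                 onset_ms = onset_ms,
                 sampling_rate_hz = 1000 / mean(dt),
                 demeaned = FALSE),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("<force_trace> %d samples @ %.6g Hz, t = [%.6g, %.6g] ms, onset %.6g ms%s\n",
              length(x$time_ms), x$sampling_rate_hz, min(x$time_ms),
              max(x$time_ms), x$onset_ms,
              if (isTRUE(x$demeaned)) ", demeaned" else ""))
  invisible(x)
}

#' Subtract the pre-stimulus baseline from a force trace
#'
#' Removes, per axis, the mean force over the 400 ms immediately preceding
#' stimulation onset (the half-open window `[onset - 400, onset)`), so that
#' evoked forces are measured relative to the resting baseline.  The
#' operation is idempotent up to floating error.
#'
#' @param trace a [force_trace()] with at least 400 ms of pre-onset samples.
#' @param baseline_ms baseline span before onset, ms.
#' @return The demeaned [force_trace()].
#' @export
demean_trace <- function(trace, baseline_ms = 400) {
  stopifnot(inherits(trace, "force_trace"))
  idx <- trace$time_ms >= trace$onset_ms - baseline_ms &
         trace$time_ms < trace$onset_ms
  span <- trace$onset_ms - min(trace$time_ms)
  if (span < baseline_ms - 1e-9 || !any(idx))
    stop(sprintf("insufficient pre-onset baseline: need %g ms, trace has %g ms",
                 baseline_ms, span))
  base <- colMeans(trace$f[idx, , drop = FALSE])
  trace$f <- sweep(trace$f, 2, base)
  trace$demeaned <- TRUE
  trace
}

# Mean force over a half-open window [start, end) in absolute trace time.
window_mean <- function(trace, start_ms, end_ms) {
  idx <- trace$time_ms >= start_ms & trace$time_ms < end_ms
  dt <- 1000 / trace$sampling_rate_hz
  if (min(trace$time_ms) > start_ms + 1e-9 ||
      max(trace$time_ms) < end_ms - dt - 1e-9)
    stop(sprintf("trace does not cover the window [%g, %g) ms", start_ms, end_ms))
  colMeans(trace$f[idx, , drop = FALSE])
}

#' Extract the isometric force vector from a trace
#'
#' The evoked isometric force is the per-axis average over a 200 ms window
#' beginning 300 ms after stimulation onset, by which time the first-order
#' rise has settled onto the plateau.  The window is half-open,
#' `[onset + 300, onset + 500)` ms by default.
#'
#' @param trace a (normally demeaned) [force_trace()] covering the window.
#' @param window_start_ms window start relative to onset, ms.
#' @param window_ms window length, ms.
#' @return Named numeric force vector `c(fx, fy, fz)` in newtons.
#' @export
extract_force_vector <- function(trace, window_start_ms = 300, window_ms = 200) {
  stopifnot(inherits(trace, "force_trace"), window_ms > 0)
  window_mean(trace, trace$onset_ms + window_start_ms,
              trace$onset_ms + window_start_ms + window_ms)
}

#' Split a trace into contiguous windowed force vectors
#'
#' Computes mean force vectors over contiguous half-open windows of `width_ms`
#' covering `[onset, onset + duration_ms)`, for the time-course analysis of
#' prediction errors across the stimulation train.
#'
#' @param trace a demeaned [force_trace()].
#' @param width_ms window width, ms (> 0); must divide `duration_ms`.
#' @param duration_ms analyzed span from onset, ms.
#' @return Data frame with `window_start_ms`, `fx`, `fy`, `fz`.
#' @export
windowed_vectors <- function(trace, width_ms = 50, duration_ms = 600) {
  stopifnot(inherits(trace, "force_trace"))
  if (width_ms <= 0) stop("window width must be positive")
  k <- duration_ms / width_ms
  if (abs(k - round(k)) > 1e-9)
    stop("window width must divide the analyzed span")
  starts <- trace$onset_ms + width_ms * (seq_len(round(k)) - 1L)
  v <- t(vapply(starts, function(s) window_mean(trace, s, s + width_ms),
                numeric(3)))
  data.frame(window_start_ms = starts - trace$onset_ms,
             fx = v[, 1], fy = v[, 2], fz = v[, 3])
}

#' Filter trials by evoked force magnitude
#'
#' Keeps trials whose evoked force magnitude is strictly greater than the
#' threshold (0.03 N by default), excluding responses too small to define a
#' reliable direction above background noise.
#'
#' @param trials data frame with columns `fx_N`, `fy_N`, `fz_N` (or a
#'   precomputed `magnitude_N` column).
#' @param threshold magnitude threshold, N.
#' @return List with `kept` and `dropped` data frames; both carry a
#'   `magnitude_N` column.
#' @export
apply_magnitude_filter <- function(trials, threshold = 0.03) {
  if (nrow(trials) == 0L)
    return(list(kept = trials, dropped = trials))
  mag <- if ("magnitude_N" %in% names(trials)) trials$magnitude_N
         else vec_magnitude(trials[, c("fx_N", "fy_N", "fz_N")])
  trials$magnitude_N <- mag
  keep <- mag > threshold
  list(kept = trials[keep, , drop = FALSE],
       dropped = trials[!keep, , drop = FALSE])
}

#' Re-extract trial force vectors from recorded traces
#'
#' Runs baseline subtraction and window averaging on each trial's trace and
#' replaces the trial table's force columns with the extracted vectors,
#' adding `magnitude_N`, `sagittal_angle_deg` and a `qc_pass` flag from the
#' magnitude filter.
#'
#' @param trials trial table (see [simulate_experiment()]).
#' @param traces named list of [force_trace()]s, `s<subject>_t<trial_index>`.
#' @param threshold magnitude threshold, N, for `qc_pass`.
#' @inheritParams extract_force_vector
#' @return The trial table with extracted force columns.
#' @export
extract_trials <- function(trials, traces, window_start_ms = 300,
                           window_ms = 200, threshold = 0.03) {
  keys <- sprintf("s%d_t%d", trials$subject_id, trials$trial_index)
  missing <- setdiff(keys, names(traces))
  if (length(missing) > 0)
    stop("no trace found for trials: ", paste(utils::head(missing, 5), collapse = ", "))
  v <- t(vapply(keys, function(k)
    extract_force_vector(demean_trace(traces[[k]]), window_start_ms, window_ms),
    numeric(3)))
  trials$fx_N <- v[, 1]; trials$fy_N <- v[, 2]; trials$fz_N <- v[, 3]
  trials$magnitude_N <- vec_magnitude(v)
  trials$sagittal_angle_deg <- sagittal_angle(v)
  trials$qc_pass <- trials$magnitude_N > threshold
  trials
}
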