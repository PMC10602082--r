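#' Force-vector utilities
#'
#' A force vector is a numeric triple (fx, fy, fz) in newtons, expressed in a
#' body-referenced frame: +x rostral, +y dorsal, +z lateral.  The sagittal
#' plane is x-y; flexion forces point rostral-dorsal (angles near +45 to
#' +90 degrees), extension forces caudal-ventral (angles near -90 to -180).
#'
#' @param v numeric vector of length 3, or a matrix with 3 columns where each
#'   row is one force vector.
#' @return `vec_magnitude()` returns the Euclidean norm in newtons (one value
#'   per row for matrix input).  `sagittal_angle()` returns the angle
#'   `atan2(fy, fx)` in degrees on (-180, 180]; it is `NA` for a zero-length
#'   vector, where direction is undefined.
#' @examples
#' vec_magnitude(c(3, 4, 0))
#' sagittal_angle(c(0, 1, 0))
#' @export
vec_magnitude <- function(v) {
  v <- as_force_matrix(v)
  sqrt(rowSums(v^2))
}

#' @rdname vec_magnitude
#' @export
sagittal_angle <- function(v) {
  v <- as_force_matrix(v)
  ang <- atan2(v[, 2], v[, 1]) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang[rowSums(v^2) == 0] <- NA_real_
  ang
}

# Coerce a length-3 vector or n x 3 matrix/data.frame to an n x 3 matrix.
as_force_matrix <- function(v) {
  if (is.data.frame(v)) v <- as.matrix(v)
  if (is.null(dim(v))) {
    if (length(v) != 3L) stop("a force vector must have exactly 3 components")
    v <- matrix(v, nrow = 1L)
  }
  if (ncol(v) != 3L) stop("force vectors must have 3 columns (fx, fy, fz)")
  storage.mode(v) <- "double"
  v
}

# Unit vector in the sagittal plane at `angle_deg` degrees from +x (rostral).
sagittal_unit <- function(angle_deg) {
  th <- angle_deg * pi / 180
  cbind(fx = cos(th), fy = sin(th), fz = 0)
}
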