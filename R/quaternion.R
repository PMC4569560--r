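#' Unit-quaternion utilities
#'
#' Orientation helpers used to pose meshes and integrate rigid-body
#' rotation; scalar-first convention `q = c(w, x, y, z)`.
#'
#' @param q,p unit quaternions.
#' @param axis rotation axis (3-vector, any norm).
#' @param angle rotation angle \[rad\].
#' @param w world-frame angular velocity \[rad/s\].
#' @param dt timestep \[s\].
#' @return a quaternion (numeric length 4); `quat_to_matrix()` returns the
#'   3x3 rotation matrix.
#' @name quaternions
NULL

#' @rdname quaternions
#' @export
quat_identity <- function() c(1, 0, 0, 0)

#' @rdname quaternions
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n == 0) stop("cannot normalize a zero quaternion", call. = FALSE)
  q / n
}

#' @rdname quaternions
#' @export
quat_multiply <- function(p, q) {
  c(
    p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1]
  )
}

## rotation matrix (applies to column vectors) of a unit quaternion
#' @rdname quaternions
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' @rdname quaternions
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / vec_norm(axis)
  c(cos(angle / 2), sin(angle / 2) * axis)
}

## advance orientation by world-frame angular velocity w over dt,
## dq/dt = 1/2 * (0, w) * q, then renormalize
#' @rdname quaternions
#' @export
quat_integrate <- function(q, w, dt) {
  dq <- 0.5 * quat_multiply(c(0, w), q)
  quat_normalize(q + dt * dq)
}

## uniform random unit quaternion (uses the session RNG)
#' @rdname quaternions
#' @export
quat_random <- function() quat_normalize(rnorm(4))
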