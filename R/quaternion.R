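# Quaternion helpers. Quaternions are numeric length-4 vectors c(w, x, y, z)
# (scalar first) or n x 4 matrices of per-sample attitudes.

#' Normalize a quaternion to unit length
#' @param q numeric length-4 quaternion or n x 4 matrix
#' @return quaternion(s) of unit norm
#' @keywords internal
quat_normalize <- function(q) {
  if (is.matrix(q)) q / sqrt(rowSums(q^2)) else q / sqrt(sum(q^2))
}

#' Hamilton product of two quaternions
#' @param a,b length-4 quaternions
#' @return length-4 quaternion a * b
#' @keywords internal
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Quaternion conjugate (inverse rotation for unit quaternions)
#' @param q length-4 quaternion or n x 4 matrix
#' @keywords internal
quat_conjugate <- function(q) {
  if (is.matrix(q)) cbind(q[, 1], -q[, 2:4, drop = FALSE]) else c(q[1], -q[2:4])
}

#' Quaternion from an axis and a rotation angle
#' @param axis length-3 rotation axis (need not be unit)
#' @param angle rotation angle in radians
#' @keywords internal
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Uniform random unit quaternion
#' @keywords internal
quat_random <- function() quat_normalize(stats::rnorm(4))

#' Rotate 3-vectors by quaternions
#'
#' Applies the rotation encoded by `q` to each row of `v`.
#'
#' @param q length-4 quaternion (applied to all rows) or n x 4 matrix of
#'   per-row quaternions
#' @param v length-3 vector or n x 3 matrix
#' @return matrix of rotated vectors, same shape as `v`
#' @keywords internal
quat_rotate <- function(q, v) {
  single <- is.null(dim(v))
  if (single) v <- matrix(v, ncol = 3)
  if (is.null(dim(q))) q <- matrix(q, nrow(v), 4, byrow = TRUE)
  w <- q[, 1]
  u <- q[, 2:4, drop = FALSE]
  rowcross <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  t2 <- 2 * rowcross(u, v)
  out <- v + w * t2 + rowcross(u, t2)
  if (single) out[1, ] else out
}

#' Quaternion rotating one direction onto another
#'
#' Returns the minimal rotation taking unit direction `a` to unit
#' direction `b`. Antiparallel inputs rotate by pi about any orthogonal axis.
#'
#' @param a,b length-3 directions (normalized internally)
#' @keywords internal
quat_between <- function(a, b) {
  a <- a / sqrt(sum(a^2))
  b <- b / sqrt(sum(b^2))
  d <- sum(a * b)
  if (d > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (d < -1 + 1e-12) {
    # pick any axis orthogonal to a
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- ax - sum(ax * a) * a
    return(quat_from_axis_angle(ax, pi))
  }
  axis <- c(a[2] * b[3] - a[3] * b[2],
            a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
  quat_normalize(c(1 + d, axis))
}
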