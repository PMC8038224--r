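# Quaternion algebra for orientation tracks.
#
# Convention: unit quaternions q = (w, x, y, z) represent the rotation taking
# body-frame (segment or sensor casing) coordinates to global coordinates,
# v_global = R(q) v_body.  Tracks are stored as n x 4 matrices, one row per
# sample.

#' Normalize quaternions to unit length
#'
#' @param q numeric length-4 vector or n x 4 matrix (w, x, y, z).
#' @return object of the same shape with each quaternion scaled to unit norm.
#' @export
quat_normalize <- function(q) {
  q <- quat_as_matrix(q)
  n <- sqrt(rowSums(q^2))
  if (any(n < .Machine$double.eps)) stop("cannot normalize a zero quaternion")
  q / n
}

quat_as_matrix <- function(q) {
  if (is.null(dim(q))) {
    stopifnot(length(q) == 4L)
    q <- matrix(q, nrow = 1L)
  }
  stopifnot(ncol(q) == 4L)
  q
}

#' Hamilton product of quaternion tracks
#'
#' Row-wise product `p * q`; either argument may be a single quaternion, which
#' is recycled against the other track.
#'
#' @param p,q length-4 vectors or n x 4 matrices.
#' @return n x 4 matrix of products.
#' @export
quat_multiply <- function(p, q) {
  p <- quat_as_matrix(p); q <- quat_as_matrix(q)
  n <- max(nrow(p), nrow(q))
  if (nrow(p) == 1L) p <- p[rep(1L, n), , drop = FALSE]
  if (nrow(q) == 1L) q <- q[rep(1L, n), , drop = FALSE]
  stopifnot(nrow(p) == nrow(q))
  pw <- p[, 1]; px <- p[, 2]; py <- p[, 3]; pz <- p[, 4]
  qw <- q[, 1]; qx <- q[, 2]; qy <- q[, 3]; qz <- q[, 4]
  cbind(
    pw * qw - px * qx - py * qy - pz * qz,
    pw * qx + px * qw + py * qz - pz * qy,
    pw * qy - px * qz + py * qw + pz * qx,
    pw * qz + px * qy - py * qx + pz * qw
  )
}

#' Quaternion conjugate
#'
#' @param q length-4 vector or n x 4 matrix.
#' @return same shape; for unit quaternions this is the inverse rotation.
#' @export
quat_conjugate <- function(q) {
  q <- quat_as_matrix(q)
  cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4])
}

#' Rotate 3-vectors by quaternions
#'
#' Applies v' = q v q*, i.e. expresses body-frame vectors in the global frame.
#' Use `quat_conjugate(q)` to go the other way.
#'
#' @param q length-4 vector or n x 4 matrix of unit quaternions.
#' @param v length-3 vector or n x 3 matrix.
#' @return n x 3 matrix of rotated vectors.
#' @export
quat_rotate <- function(q, v) {
  q <- quat_as_matrix(q)
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
  stopifnot(ncol(v) == 3L)
  n <- max(nrow(q), nrow(v))
  if (nrow(q) == 1L) q <- q[rep(1L, n), , drop = FALSE]
  if (nrow(v) == 1L) v <- v[rep(1L, n), , drop = FALSE]
  w <- q[, 1]; u <- q[, 2:4, drop = FALSE]
  # v' = v + 2 w (u x v) + 2 u x (u x v)
  t2 <- 2 * cross3(u, v)
  v + w * t2 + cross3(u, t2)
}

# row-wise cross product of n x 3 matrices
cross3 <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

#' Quaternion from axis and angle
#'
#' @param axis length-3 rotation axis (need not be unit length).
#' @param angle rotation angle(s) in radians; vectorized.
#' @return n x 4 quaternion matrix (n = length(angle)).
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  h <- angle / 2
  cbind(cos(h), sin(h) * axis[1], sin(h) * axis[2], sin(h) * axis[3])
}

#' Rotation matrix from a single quaternion
#'
#' @param q length-4 unit quaternion.
#' @return 3 x 3 rotation matrix with R v_body = v_global.
#' @export
quat_to_rotmat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Quaternion from a rotation matrix
#'
#' Shepperd's method; returns the representative with nonnegative w.
#'
#' @param R 3 x 3 proper rotation matrix.
#' @return length-4 unit quaternion.
#' @export
rotmat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

#' Geodesic angle between two rotations
#'
#' @param p,q unit quaternions (length-4 or row-matched n x 4 matrices).
#' @return rotation angle(s) in degrees needed to take one onto the other.
#' @export
quat_angle_deg <- function(p, q) {
  p <- quat_as_matrix(p); q <- quat_as_matrix(q)
  n <- max(nrow(p), nrow(q))
  if (nrow(p) == 1L) p <- p[rep(1L, n), , drop = FALSE]
  if (nrow(q) == 1L) q <- q[rep(1L, n), , drop = FALSE]
  d <- abs(rowSums(p * q) / (sqrt(rowSums(p^2)) * sqrt(rowSums(q^2))))
  2 * acos(pmin(d, 1)) * 180 / pi
}
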