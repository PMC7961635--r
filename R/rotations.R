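# Rotation utilities: unit quaternions (w, x, y, z) and 3x3 matrices.
# Quaternions are the interchange representation for orientation streams
# (IMU data arrives as quaternions); the kinematic recursion works in
# matrix form and converts at the boundary.

#' Create a unit quaternion
#'
#' Quaternions are length-4 numeric vectors in scalar-first order
#' `(w, x, y, z)` and are normalized on construction.
#'
#' @param w,x,y,z quaternion components.
#' @return A normalized quaternion (numeric vector of length 4).
#' @export
quat <- function(w, x, y, z) {
  quat_normalize(c(w, x, y, z))
}

#' @rdname quat
#' @param q a length-4 numeric vector.
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("cannot normalize a near-zero quaternion")
  q / n
}

#' Quaternion algebra
#'
#' Hamilton product, conjugate, and conversions between quaternions,
#' rotation matrices and axis-angle form. All rotations are active and
#' right-handed.
#'
#' @param a,b,q quaternions `(w, x, y, z)`.
#' @name quat-algebra
NULL

#' @rdname quat-algebra
#' @export
quat_multiply <- function(a, b) {
  quat_normalize(c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  ))
}

#' @rdname quat-algebra
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' @rdname quat-algebra
#' @export
quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' @rdname quat-algebra
#' @param R a 3x3 rotation matrix.
#' @export
matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  quat_normalize(q)
}

#' @rdname quat-algebra
#' @param axis rotation axis (length-3, need not be unit).
#' @param angle rotation angle in radians.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Rotation matrix about an arbitrary axis (Rodrigues)
#'
#' @param axis rotation axis (length-3, need not be unit).
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- skew(axis)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Logarithm map of a rotation matrix
#'
#' Returns the rotation vector (axis times angle) of `R`; its norm is the
#' geodesic angle. Used as the orientation residual in inverse kinematics.
#'
#' @param R a 3x3 rotation matrix.
#' @return numeric length-3 rotation vector, norm in \[0, pi\].
#' @export
rotation_log <- function(R) {
  cos_theta <- min(1, max(-1, (R[1, 1] + R[2, 2] + R[3, 3] - 1) / 2))
  theta <- acos(cos_theta)
  if (theta < 1e-10) {
    # first-order: R ~ I + skew(v)
    return(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2)
  }
  if (pi - theta < 1e-6) {
    # near pi: axis from the symmetric part
    A <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(A), 0))
    # fix signs from off-diagonals
    i <- which.max(axis)
    if (axis[i] > 0) {
      axis <- A[, i] / axis[i]
      axis <- axis / sqrt(sum(axis^2))
    }
    return(theta * axis)
  }
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  theta / (2 * sin(theta)) * v
}

#' Geodesic angle between two rotations
#'
#' @param qa,qb orientations as quaternions.
#' @return angle in radians in \[0, pi\].
#' @export
quat_geodesic <- function(qa, qb) {
  d <- abs(sum(qa * qb))
  2 * acos(min(1, d))
}

#' Spherical linear interpolation between quaternions
#'
#' @param qa,qb endpoint orientations (quaternions).
#' @param s interpolation fraction in \[0, 1\].
#' @return interpolated unit quaternion.
#' @export
quat_slerp <- function(qa, qb, s) {
  d <- sum(qa * qb)
  if (d < 0) { qb <- -qb; d <- -d }
  if (d > 1 - 1e-10) {
    return(quat_normalize((1 - s) * qa + s * qb))
  }
  th <- acos(min(1, d))
  quat_normalize((sin((1 - s) * th) * qa + sin(s * th) * qb) / sin(th))
}

#' Skew-symmetric (cross-product) matrix of a 3-vector
#'
#' @param v length-3 numeric vector.
#' @return 3x3 matrix `S` with `S %*% w == cross(v, w)`.
#' @export
skew <- function(v) {
  matrix(c(0, -v[3], v[2],
           v[3], 0, -v[1],
           -v[2], v[1], 0), nrow = 3, byrow = TRUE)
}

# cross product, small helper used throughout the dynamics code
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
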