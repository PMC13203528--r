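#' Hamilton quaternion product
#'
#' Multiplies two quaternions `p` and `q` (scalar-first convention,
#' `c(q0, q1, q2, q3)`) using the Hamilton product. The product norm is
#' multiplicative: `||p x q|| = ||p|| * ||q||`.
#'
#' @param p,q Numeric vectors of length 4, scalar component first.
#' @return Numeric vector of length 4.
#' @examples
#' quat_multiply(c(0, 1, 0, 0), c(0, 0, 1, 0))  # i * j = k
#' @export
quat_multiply <- function(p, q) {
  stopifnot(length(p) == 4L, length(q) == 4L)
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

#' Quaternion conjugate
#'
#' @param q Numeric vector of length 4, scalar component first.
#' @return The conjugate quaternion `c(q0, -q1, -q2, -q3)`.
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Normalize a quaternion to unit length
#'
#' @param q Numeric vector of length 4.
#' @return Unit quaternion.
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < .Machine$double.eps) stop("cannot normalize a zero quaternion")
  q / n
}

#' Rotation matrix of a unit quaternion
#'
#' Builds the 3x3 rotation matrix mapping body-frame vectors into the
#' global frame. The third row of the matrix equals the predicted gravity
#' direction used by the attitude filter's accelerometer correction.
#'
#' @param q Unit quaternion (scalar first). A norm deviating from 1 by more
#'   than `tol` is an error.
#' @param tol Unit-norm tolerance (default `1e-6`).
#' @return A 3x3 orthonormal rotation matrix with determinant +1.
#' @export
quat_to_rotmat <- function(q, tol = 1e-6) {
  stopifnot(length(q) == 4L)
  if (abs(sqrt(sum(q^2)) - 1) > tol)
    stop("quat_to_rotmat() requires a unit quaternion (|norm - 1| <= ", tol, ")")
  q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]
  matrix(c(
    1 - 2 * (q2^2 + q3^2), 2 * (q1 * q2 - q0 * q3), 2 * (q1 * q3 + q0 * q2),
    2 * (q1 * q2 + q0 * q3), 1 - 2 * (q1^2 + q3^2), 2 * (q2 * q3 - q0 * q1),
    2 * (q1 * q3 - q0 * q2), 2 * (q2 * q3 + q0 * q1), 1 - 2 * (q1^2 + q2^2)),
    nrow = 3, byrow = TRUE)
}

# quaternion from Euler angles (radians), R = Rz(yaw) Ry(pitch) Rx(roll),
# body -> global. Internal helper shared by the synthetic generator.
quat_from_euler <- function(roll, pitch, yaw) {
  cr <- cos(roll / 2); sr <- sin(roll / 2)
  cp <- cos(pitch / 2); sp <- sin(pitch / 2)
  cy <- cos(yaw / 2); sy <- sin(yaw / 2)
  c(cy * cp * cr + sy * sp * sr,
    cy * cp * sr - sy * sp * cr,
    cy * sp * cr + sy * cp * sr,
    sy * cp * cr - cy * sp * sr)
}
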