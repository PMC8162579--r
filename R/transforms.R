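# Rigid-transform primitives.
#
# Frame convention used throughout the package: right-handed, Y up, X forward,
# Z to the subject's right.  Rotations are 3x3 orthonormal matrices acting on
# column vectors; lengths are meters and angles radians everywhere inside the
# package (degrees appear only at I/O and reporting boundaries).

#' Elementary rotation matrices
#'
#' @param a Angle in radians.
#' @return A 3x3 rotation matrix about the named axis.
#' @name elementary-rotations
NULL

#' @rdname elementary-rotations
#' @export
rot_x <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
}

#' @rdname elementary-rotations
#' @export
rot_y <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}

#' @rdname elementary-rotations
#' @export
rot_z <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

#' Rotation about an arbitrary unit axis (Rodrigues' formula)
#'
#' @param axis Unit 3-vector.
#' @param angle Angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rot_axis_angle <- function(axis, angle) {
  a <- as.numeric(axis)
  K <- skew3(a)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Cross product of one 3-vector against the columns of a 3xN matrix.
cross3_mat <- function(a, B) {
  rbind(a[2] * B[3, ] - a[3] * B[2, ],
        a[3] * B[1, ] - a[1] * B[3, ],
        a[1] * B[2, ] - a[2] * B[1, ])
}

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

#' Construct a rigid transform
#'
#' A rigid transform maps local coordinates `x` to world coordinates
#' `R x + p`.
#'
#' @param R 3x3 orthonormal rotation matrix (det +1).
#' @param p Translation 3-vector (m).
#' @return An object of class `rigid_transform` with fields `R` and `p`.
#' @export
new_transform <- function(R = diag(3), p = c(0, 0, 0)) {
  R <- matrix(as.numeric(R), 3, 3)
  p <- as.numeric(p)
  stopifnot(length(p) == 3)
  structure(list(R = R, p = p), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("  rotation:\n")
  print(round(x$R, 6))
  cat("  translation:", format(x$p, digits = 6), "\n")
  invisible(x)
}

#' Compose, invert, and apply rigid transforms
#'
#' `t_compose(a, b)` is the transform mapping through `b` then `a`;
#' `t_inverse(a)` is the inverse transform; `t_apply(a, x)` maps a 3-vector
#' or the columns of a 3xN matrix.
#'
#' @param a,b `rigid_transform` objects.
#' @param x 3-vector or 3xN matrix.
#' @return A `rigid_transform`, or mapped coordinates for `t_apply`.
#' @export
t_compose <- function(a, b) {
  new_transform(a$R %*% b$R, a$p + as.numeric(a$R %*% b$p))
}

#' @rdname t_compose
#' @export
t_inverse <- function(a) {
  Rt <- t(a$R)
  new_transform(Rt, -as.numeric(Rt %*% a$p))
}

#' @rdname t_compose
#' @export
t_apply <- function(a, x) {
  if (is.matrix(x)) a$R %*% x + a$p else as.numeric(a$R %*% x) + a$p
}

is_rotation <- function(R, tol = 1e-10) {
  max(abs(t(R) %*% R - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' Intrinsic Z-X-Y Euler angles
#'
#' The root (pelvis-to-ground) orientation is parameterized by successive
#' body-fixed rotations about Z (tilt), then X (list), then Y (rotation):
#' `R = Rz(a) Rx(b) Ry(c)`.  Valid for |b| < pi/2, which holds throughout
#' normal gait.
#'
#' @param R 3x3 rotation matrix.
#' @return Numeric 3-vector `c(a, b, c)` in radians.
#' @keywords internal
euler_zxy_from_rot <- function(R) {
  b <- asin(max(-1, min(1, R[3, 2])))
  a <- atan2(-R[1, 2], R[2, 2])
  c_ <- atan2(-R[3, 1], R[3, 3])
  c(a, b, c_)
}

rot_from_euler_zxy <- function(e) {
  rot_z(e[1]) %*% rot_x(e[2]) %*% rot_y(e[3])
}
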