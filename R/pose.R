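#' Rigid pose with six degrees of freedom
#'
#' A rigid transform parameterized by three translation offsets (mm) and
#' three orientation angles (degrees): roll \code{theta} about the local x
#' axis, yaw \code{phi} about the local y axis and pitch \code{eta} about the
#' local z axis. The zero pose is the identity transform.
#'
#' @param dx,dy,dz Translation offsets in mm.
#' @param theta,phi,eta Roll, yaw and pitch angles in degrees. Stored
#'   normalized to the interval (-360, 360].
#' @return An object of class \code{rigid_pose}.
#' @examples
#' rigid_pose(dy = 10)           # pure vertical shift
#' rigid_pose(phi = 187)         # yaw about the vertical axis
#' @export
rigid_pose <- function(dx = 0, dy = 0, dz = 0, theta = 0, phi = 0, eta = 0) {
  stopifnot(is.finite(c(dx, dy, dz, theta, phi, eta)))
  norm_ang <- function(a) ifelse(a > -360 & a <= 360, a, a %% 360)
  structure(list(dx = dx, dy = dy, dz = dz,
                 theta = norm_ang(theta), phi = norm_ang(phi),
                 eta = norm_ang(eta)),
            class = "rigid_pose")
}

#' @export
print.rigid_pose <- function(x, ...) {
  cat(sprintf("rigid_pose: t = (%.4g, %.4g, %.4g) mm, (roll, yaw, pitch) = (%.4g, %.4g, %.4g) deg\n",
              x$dx, x$dy, x$dz, x$theta, x$phi, x$eta))
  invisible(x)
}

deg2rad <- function(a) a * pi / 180

rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Rotation matrix from roll/yaw/pitch angles
#'
#' Composes the three single-axis rotations in the fixed order
#' R = Rz(eta) Ry(phi) Rx(theta): roll first, then yaw, then pitch. All
#' angles are right-handed about the respective axis and given in degrees.
#'
#' @param theta Roll about the x axis (degrees).
#' @param phi Yaw about the y axis (degrees).
#' @param eta Pitch about the z axis (degrees).
#' @return A 3x3 orthonormal rotation matrix with determinant +1.
#' @examples
#' rotation_from_angles(0, 0, 0)            # identity
#' rotation_from_angles(90, 0, 0) %*% c(0, 1, 0)  # (0, 0, 1)
#' @export
rotation_from_angles <- function(theta, phi, eta) {
  rot_z(deg2rad(eta)) %*% rot_y(deg2rad(phi)) %*% rot_x(deg2rad(theta))
}

pose_rotation <- function(pose) {
  rotation_from_angles(pose$theta, pose$phi, pose$eta)
}

pose_translation <- function(pose) {
  c(pose$dx, pose$dy, pose$dz)
}

# Rotation of the turntable: right-handed about the +y (vertical) axis,
# positive = counter-clockwise viewed from above.
stage_rotation <- function(angle_deg) {
  rot_y(deg2rad(angle_deg))
}
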