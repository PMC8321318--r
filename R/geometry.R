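#' Flat-panel detector specification
#'
#' @param n_u,n_v Number of detector columns / rows (pixels).
#' @param pixel_size Isotropic pixel pitch in mm.
#' @return An object of class \code{detector_spec}.
#' @examples
#' detector_spec(2048, 2048, 0.142)
#' @export
detector_spec <- function(n_u, n_v, pixel_size) {
  stopifnot(n_u >= 1, n_v >= 1, pixel_size > 0)
  structure(list(n_u = as.integer(n_u), n_v = as.integer(n_v),
                 pixel_size = pixel_size),
            class = "detector_spec")
}

#' One source/detector pair of a stereo cone-beam system
#'
#' Distances are measured along the pair's nominal optical axis: \code{sod}
#' from the focal spot to the rotation axis, \code{sdd} from the focal spot
#' to the detector plane. \code{dsod} models the measurement error of the
#' SOD; a positive value moves the source away from the rotation axis while
#' the detector keeps its measured distance \code{sdd} from the source.
#'
#' @param sod Source-to-rotation-axis distance (mm), > 0.
#' @param sdd Source-to-detector distance (mm), > sod.
#' @param detector_spec A [detector_spec()].
#' @param dsod SOD measurement-error offset (mm); \code{sod + dsod} must be
#'   positive.
#' @param detector_pose A [rigid_pose()] describing the detector
#'   misalignment (translations in the nominal detector frame, rotations
#'   about the detector center).
#' @return An object of class \code{sd_pair}.
#' @export
source_detector_pair <- function(sod, sdd, detector_spec,
                                 dsod = 0, detector_pose = rigid_pose()) {
  stopifnot(sod > 0, sdd > sod, (sod + dsod) > 0,
            inherits(detector_spec, "detector_spec"),
            inherits(detector_pose, "rigid_pose"))
  structure(list(sod = sod, sdd = sdd, dsod = dsod,
                 detector_pose = detector_pose,
                 detector_spec = detector_spec),
            class = "sd_pair")
}

#' Stereo cone-beam geometry
#'
#' Bundles two source/detector pairs, the stereo angle \code{alpha} between
#' their optical axes and the pose of the calibration phantom relative to
#' the rotation-axis frame. The world frame has its origin at the rotation
#' center, +x along pair 1's nominal optical axis (source to detector),
#' +y along the rotation axis (up), and +z completing a right-handed frame.
#' Pair 2's entire nominal frame is pair 1's rotated by \code{alpha} about
#' the rotation axis.
#'
#' With nothing masked the geometry carries 21 free parameters: 6 phantom
#' pose DOF, the stereo angle, and per pair one SOD offset plus 6 detector
#' pose DOF.
#'
#' @param pair1,pair2 Two [source_detector_pair()] objects.
#' @param alpha Stereo angle between the two optical axes, degrees, in
#'   (0, 180).
#' @param phantom_pose A [rigid_pose()] for the phantom.
#' @return An object of class \code{stereo_geometry}.
#' @export
stereo_geometry <- function(pair1, pair2, alpha = 90,
                            phantom_pose = rigid_pose()) {
  stopifnot(inherits(pair1, "sd_pair"), inherits(pair2, "sd_pair"),
            alpha > 0, alpha < 180, inherits(phantom_pose, "rigid_pose"))
  structure(list(pair1 = pair1, pair2 = pair2, alpha = alpha,
                 phantom_pose = phantom_pose),
            class = "stereo_geometry")
}

#' @export
print.stereo_geometry <- function(x, ...) {
  cat("stereo_geometry\n")
  cat(sprintf("  pair 1: sod %.4g mm (dsod %+.4g), sdd %.4g mm, %dx%d px @ %.4g mm\n",
              x$pair1$sod, x$pair1$dsod, x$pair1$sdd,
              x$pair1$detector_spec$n_u, x$pair1$detector_spec$n_v,
              x$pair1$detector_spec$pixel_size))
  cat(sprintf("  pair 2: sod %.4g mm (dsod %+.4g), sdd %.4g mm, %dx%d px @ %.4g mm\n",
              x$pair2$sod, x$pair2$dsod, x$pair2$sdd,
              x$pair2$detector_spec$n_u, x$pair2$detector_spec$n_v,
              x$pair2$detector_spec$pixel_size))
  cat(sprintf("  stereo angle alpha: %.6g deg\n", x$alpha))
  cat("  phantom "); print(x$phantom_pose)
  invisible(x)
}

geometry_pair <- function(geom, system) {
  if (system == 1L) geom$pair1 else geom$pair2
}

pair_system_rotation <- function(geom, system) {
  if (system == 1L) 0 else geom$alpha
}

#' World position of a marker at a given stage angle
#'
#' Applies the phantom pose (orientation, then translation) and then the
#' turntable rotation about the +y axis: R_axis(angle) (R_o p + t_o). The
#' phantom translation is expressed in the static room frame and therefore
#' rotates with the stage.
#'
#' @param phantom_pose A [rigid_pose()].
#' @param stage_angle Turntable angle in degrees (counter-clockwise about +y
#'   viewed from above).
#' @param p_local Marker position in the phantom frame, length-3 (mm), or an
#'   n x 3 matrix of positions.
#' @return A length-3 vector (or n x 3 matrix) of world coordinates in mm.
#' @export
marker_world_position <- function(phantom_pose, stage_angle, p_local) {
  R <- stage_rotation(stage_angle) %*% pose_rotation(phantom_pose)
  t_o <- stage_rotation(stage_angle) %*% pose_translation(phantom_pose)
  if (is.matrix(p_local)) {
    sweep(p_local %*% t(R), 2, -as.numeric(t_o))
  } else {
    as.numeric(R %*% p_local + t_o)
  }
}

#' Source and detector frame of one pair
#'
#' Builds the world-frame acquisition geometry of one source/detector pair:
#' source position, detector center, and the orthonormal in-plane detector
#' axes (\code{e_u} horizontal, \code{e_v} vertical). In the aligned case at
#' system rotation 0 the source sits at (-(sod+dsod), 0, 0), the detector
#' center at (sdd-sod-dsod, 0, 0), \code{e_u} = +z and \code{e_v} = +y.
#' The detector pose then translates the center by (dx, dy, dz) expressed in
#' the nominal detector frame (x = optical axis, y = vertical, z =
#' horizontal) and rotates the in-plane axes about the detector center;
#' finally the whole frame is rotated about the rotation axis by
#' \code{system_rotation} (0 for pair 1, alpha for pair 2).
#'
#' @param pair A [source_detector_pair()].
#' @param system_rotation Rotation of the whole pair frame about the
#'   rotation axis, degrees.
#' @return A list with \code{source}, \code{det_center}, \code{e_u},
#'   \code{e_v} (world mm / unit vectors) and the pair's
#'   \code{detector_spec}.
#' @export
pair_frame <- function(pair, system_rotation = 0) {
  axis0 <- c(1, 0, 0)   # nominal optical axis, source -> detector
  v0 <- c(0, 1, 0)      # nominal vertical (detector v)
  u0 <- c(0, 0, 1)      # nominal horizontal (detector u)
  src <- -(pair$sod + pair$dsod) * axis0
  dc <- (pair$sdd - pair$sod - pair$dsod) * axis0

  dp <- pair$detector_pose
  # translation expressed in the nominal detector frame (x, y, z) =
  # (axis, vertical, horizontal)
  dc <- dc + dp$dx * axis0 + dp$dy * v0 + dp$dz * u0
  Rd <- pose_rotation(dp)
  B <- cbind(axis0, v0, u0)  # local-to-world basis
  e_u <- as.numeric(B %*% (Rd %*% c(0, 0, 1)))
  e_v <- as.numeric(B %*% (Rd %*% c(0, 1, 0)))

  Rs <- stage_rotation(system_rotation)
  list(source = as.numeric(Rs %*% src),
       det_center = as.numeric(Rs %*% dc),
       e_u = as.numeric(Rs %*% e_u),
       e_v = as.numeric(Rs %*% e_v),
       detector_spec = pair$detector_spec)
}

frame_normal <- function(frame) {
  u <- frame$e_u; v <- frame$e_v
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Project world points onto a detector
#'
#' Intersects the ray from the source through each point with the detector
#' plane and expresses the intersection in the in-plane (e_u, e_v) basis
#' about the detector center. A point projects in the field of view when
#' |u| <= n_u pixel_size / 2 and |v| <= n_v pixel_size / 2.
#'
#' @param frame A pair frame from [pair_frame()].
#' @param p_world Length-3 world point (mm) or an n x 3 matrix.
#' @return A data.frame with columns \code{u_mm}, \code{v_mm},
#'   \code{in_fov} (logical) and \code{valid} (FALSE for degenerate rays:
#'   ray parallel to the detector plane or point not in front of the
#'   source).
#' @export
project_point <- function(frame, p_world) {
  if (!is.matrix(p_world)) p_world <- matrix(p_world, 1, 3)
  n <- frame_normal(frame)
  d <- sweep(p_world, 2, frame$source)          # ray directions
  denom <- as.numeric(d %*% n)
  num <- sum((frame$det_center - frame$source) * n)
  tpar <- ifelse(abs(denom) < 1e-12, NA_real_, num / denom)
  valid <- is.finite(tpar) & tpar > 0
  x <- sweep(d * ifelse(is.finite(tpar), tpar, 0), 2, -frame$source)
  rel <- sweep(x, 2, frame$det_center)
  u <- as.numeric(rel %*% frame$e_u)
  v <- as.numeric(rel %*% frame$e_v)
  u[!valid] <- NA_real_
  v[!valid] <- NA_real_
  spec <- frame$detector_spec
  in_fov <- valid &
    abs(u) <= spec$n_u * spec$pixel_size / 2 &
    abs(v) <= spec$n_v * spec$pixel_size / 2
  data.frame(u_mm = u, v_mm = v, in_fov = in_fov, valid = valid)
}

#' Reference projections of all markers at all angles for both systems
#'
#' Evaluates the full forward model: for every stage angle each marker is
#' moved by [marker_world_position()] and projected through each pair's
#' frame. Degenerate rays yield records with \code{in_fov = FALSE} and NA
#' coordinates rather than an error.
#'
#' @param geom A [stereo_geometry()].
#' @param phantom A [build_phantom()] model.
#' @param angles Stage angles in degrees (non-empty).
#' @return A reference table: data.frame with columns \code{system},
#'   \code{angle_index} (0-based), \code{angle_deg}, \code{marker_id},
#'   \code{u_mm}, \code{v_mm}, \code{in_fov}, \code{valid}.
#' @export
project_all <- function(geom, phantom, angles) {
  stopifnot(length(angles) >= 1)
  P <- phantom_marker_matrix(phantom)
  K <- nrow(P)
  N <- length(angles)
  Ro <- pose_rotation(geom$phantom_pose)
  to <- pose_translation(geom$phantom_pose)
  P0 <- sweep(P %*% t(Ro), 2, -to)  # pose applied, before stage rotation

  ar <- deg2rad(angles)
  ca <- cos(ar); sa <- sin(ar)
  # stage rotation about +y: x' = c x + s z ; z' = -s x + c z
  world <- matrix(0, N * K, 3)
  idx <- rep(seq_len(N), each = K)
  x0 <- P0[, 1][rep(seq_len(K), N)]
  y0 <- P0[, 2][rep(seq_len(K), N)]
  z0 <- P0[, 3][rep(seq_len(K), N)]
  world[, 1] <- ca[idx] * x0 + sa[idx] * z0
  world[, 2] <- y0
  world[, 3] <- -sa[idx] * x0 + ca[idx] * z0

  out <- lapply(c(1L, 2L), function(i) {
    fr <- pair_frame(geometry_pair(geom, i), pair_system_rotation(geom, i))
    pr <- project_point(fr, world)
    data.frame(system = i,
               angle_index = rep(seq_len(N) - 1L, each = K),
               angle_deg = rep(angles, each = K),
               marker_id = rep(phantom$markers$id, N),
               u_mm = pr$u_mm, v_mm = pr$v_mm,
               in_fov = pr$in_fov, valid = pr$valid)
  })
  rbind(out[[1]], out[[2]])
}

#' Convert detector coordinates between mm and pixels
#'
#' The detector origin (u, v) = (0, 0) in mm sits at the panel center.
#' Pixel indices are 0-based with column 0 at the left (most negative u)
#' and row 0 at the top (most positive v), so the center of pixel
#' (col, row) = (0, 0) lies at (-(n_u-1)/2, +(n_v-1)/2) pixel pitches.
#'
#' @param u_mm,v_mm Detector coordinates in mm.
#' @param col,row 0-based pixel indices (may be fractional).
#' @param spec A [detector_spec()].
#' @return A data.frame with \code{col}, \code{row} (for \code{mm_to_px})
#'   or \code{u_mm}, \code{v_mm} (for \code{px_to_mm}).
#' @export
mm_to_px <- function(u_mm, v_mm, spec) {
  data.frame(col = u_mm / spec$pixel_size + (spec$n_u - 1) / 2,
             row = (spec$n_v - 1) / 2 - v_mm / spec$pixel_size)
}

#' @rdname mm_to_px
#' @export
px_to_mm <- function(col, row, spec) {
  data.frame(u_mm = (col - (spec$n_u - 1) / 2) * spec$pixel_size,
             v_mm = ((spec$n_v - 1) / 2 - row) * spec$pixel_size)
}

#' Merge the two systems into one single-source view sequence
#'
#' A calibrated stereo acquisition of N stage angles per system can be
#' treated as a single-source acquisition of 2N views: N views of pair 1 at
#' the given angles followed by N views of pair 2, i.e. pair-1-style views
#' at angles shifted by the stereo angle alpha. Because the sources are
#' stationary and the object rotates, rotating the pair-2 frame by alpha is
#' equivalent to shifting its stage angles by alpha.
#'
#' @param geom A calibrated [stereo_geometry()].
#' @param angles Stage angles in degrees.
#' @return A list of 2N single-view frames, each a [pair_frame()] result
#'   augmented with \code{system} and \code{angle_deg}. In each view the
#'   frame is expressed in the rotating sample frame (the frame in which
#'   the object is static), so view N+k uses the pair-2 frame counter-
#'   rotated by the stage angle.
#' @export
merge_stereo_angles <- function(geom, angles) {
  views <- vector("list", 2L * length(angles))
  for (i in c(1L, 2L)) {
    fr0 <- pair_frame(geometry_pair(geom, i), pair_system_rotation(geom, i))
    for (k in seq_along(angles)) {
      # express the static pair frame in the sample frame: counter-rotate
      # by the stage angle
      R <- stage_rotation(-angles[k])
      v <- list(source = as.numeric(R %*% fr0$source),
                det_center = as.numeric(R %*% fr0$det_center),
                e_u = as.numeric(R %*% fr0$e_u),
                e_v = as.numeric(R %*% fr0$e_v),
                detector_spec = fr0$detector_spec,
                system = i,
                angle_deg = angles[k] + if (i == 2L) geom$alpha else 0)
      views[[(i - 1L) * length(angles) + k]] <- v
    }
  }
  views
}

#' Export per-view cone-beam vector geometry
#'
#' Writes each view as the 12 numbers used by vector-geometry cone-beam
#' reconstruction engines: source position, detector center and the two
#' pixel-step vectors (direction times pixel pitch) along u and v.
#'
#' @param views A view list from [merge_stereo_angles()].
#' @param path Optional CSV output path; when given the table is written
#'   with one row per view.
#' @return A data.frame with 12 numeric columns (\code{src_x} ... ,
#'   \code{det_x} ..., \code{u_x} ..., \code{v_x} ...), invisibly when
#'   written to file.
#' @export
export_cone_vectors <- function(views, path = NULL) {
  rows <- t(vapply(views, function(v) {
    ps <- v$detector_spec$pixel_size
    c(v$source, v$det_center, v$e_u * ps, v$e_v * ps)
  }, numeric(12)))
  df <- as.data.frame(rows)
  names(df) <- c("src_x_mm", "src_y_mm", "src_z_mm",
                 "det_x_mm", "det_y_mm", "det_z_mm",
                 "u_x_mm", "u_y_mm", "u_z_mm",
                 "v_x_mm", "v_y_mm", "v_z_mm")
  if (!is.null(path)) {
    write_table_csv(df, path)
    return(invisible(df))
  }
  df
}
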