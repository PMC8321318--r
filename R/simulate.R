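#' Rendering options for the radiograph simulator
#'
#' Markers are rendered as attenuating spheres on a flat background:
#' per-pixel intensity = background * exp(-attenuation * chord), where the
#' chord is the analytic intersection length of the pixel-center ray with
#' the sphere. The default attenuation is chosen so the central chord of a
#' marker transmits 5% of the beam - strong but unsaturated contrast.
#'
#' @param attenuation Linear attenuation coefficient of the marker material
#'   (1/mm). \code{NULL} picks the default for \code{marker_diameter}.
#' @param marker_diameter Marker diameter (mm) used for the default
#'   attenuation.
#' @param background_level Flat open-beam intensity (counts).
#' @param noise \code{"none"} (default) or \code{"poisson"}; in Poisson
#'   mode the per-pixel intensity is used as the photon expectation.
#' @param render_mode \code{"images"} or \code{"exact_centers"} (no images,
#'   truth table only).
#' @param supersample Odd sub-sampling factor per pixel side (1 = pixel
#'   center only, 3 = 3x3 sub-rays averaged).
#' @return A list of class \code{render_options}.
#' @export
render_options <- function(attenuation = NULL, marker_diameter = 4.95,
                           background_level = 10000,
                           noise = c("none", "poisson"),
                           render_mode = c("images", "exact_centers"),
                           supersample = 1) {
  noise <- match.arg(noise)
  render_mode <- match.arg(render_mode)
  if (is.null(attenuation))
    attenuation <- -log(0.05) / marker_diameter
  stopifnot(attenuation > 0, background_level > 0,
            supersample >= 1, supersample %% 2 == 1)
  structure(list(attenuation = attenuation,
                 background_level = background_level, noise = noise,
                 render_mode = render_mode,
                 supersample = as.integer(supersample)),
            class = "render_options")
}

# chord length of the ray source -> point through a sphere (center c, radius r)
# vectorized over points given as coordinate vectors
sphere_chords <- function(src, px, py, pz, center, radius) {
  dx <- px - src[1]; dy <- py - src[2]; dz <- pz - src[3]
  dn <- sqrt(dx * dx + dy * dy + dz * dz)
  ox <- center[1] - src[1]; oy <- center[2] - src[2]; oz <- center[3] - src[3]
  t0 <- (ox * dx + oy * dy + oz * dz) / dn
  d2 <- (ox * ox + oy * oy + oz * oz) - t0 * t0
  h2 <- radius^2 - d2
  chord <- numeric(length(px))
  hit <- h2 > 0 & t0 > 0
  chord[hit] <- 2 * sqrt(h2[hit])
  chord
}

#' Render one simulated radiograph
#'
#' Analytic rendering of the phantom's markers as attenuating spheres seen
#' by one system at one stage angle. Only the markers are rendered; the
#' phantom body is assumed radiolucent relative to the metal beads. Markers
#' outside the field of view contribute nothing.
#'
#' @param geom A [stereo_geometry()].
#' @param phantom A [build_phantom()] model.
#' @param system 1 or 2.
#' @param angle Stage angle (degrees).
#' @param opts A [render_options()].
#' @return Numeric matrix (n_v rows x n_u columns, row 1 = top) of
#'   intensities in counts.
#' @export
render_projection <- function(geom, phantom, system, angle,
                              opts = render_options()) {
  pair <- geometry_pair(geom, system)
  fr <- pair_frame(pair, pair_system_rotation(geom, system))
  spec <- pair$detector_spec
  img <- matrix(opts$background_level, spec$n_v, spec$n_u)
  r <- phantom$marker_diameter / 2
  P <- marker_world_position(geom$phantom_pose, angle,
                             phantom_marker_matrix(phantom))
  proj <- project_point(fr, P)
  ss <- opts$supersample
  offs <- (seq_len(ss) - (ss + 1) / 2) / ss   # sub-pixel offsets
  for (k in seq_len(nrow(P))) {
    if (!proj$valid[k]) next
    # conservative apparent radius (magnification at the marker)
    mag <- sqrt(sum((fr$det_center - fr$source)^2)) /
      max(sqrt(sum((P[k, ] - fr$source)^2)) - r, r)
    rad_px <- r * mag / spec$pixel_size
    cpx <- mm_to_px(proj$u_mm[k], proj$v_mm[k], spec)
    cols <- max(0, floor(cpx$col - rad_px - 2)):
      min(spec$n_u - 1, ceiling(cpx$col + rad_px + 2))
    rows <- max(0, floor(cpx$row - rad_px - 2)):
      min(spec$n_v - 1, ceiling(cpx$row + rad_px + 2))
    if (!length(cols) || !length(rows) || min(cols) > max(cols)) next
    grid <- expand.grid(col = cols, row = rows)
    acc <- 0
    for (ou in offs) for (ov in offs) {
      uv <- px_to_mm(grid$col + ou, grid$row + ov, spec)
      px <- fr$det_center[1] + uv$u_mm * fr$e_u[1] + uv$v_mm * fr$e_v[1]
      py <- fr$det_center[2] + uv$u_mm * fr$e_u[2] + uv$v_mm * fr$e_v[2]
      pz <- fr$det_center[3] + uv$u_mm * fr$e_u[3] + uv$v_mm * fr$e_v[3]
      acc <- acc + exp(-opts$attenuation *
                         sphere_chords(fr$source, px, py, pz, P[k, ], r))
    }
    trans <- acc / (ss * ss)
    idx <- cbind(grid$row + 1L, grid$col + 1L)
    img[idx] <- img[idx] * trans
  }
  if (opts$noise == "poisson")
    img[] <- stats::rpois(length(img), lambda = img)
  img
}

#' Simulate a full stereo calibration dataset
#'
#' Generates radiographs (unless in \code{exact_centers} mode) for both
#' systems at every stage angle, a constant flatfield image per system, and
#' the exact ground-truth center table computed with the same forward model
#' as [project_all()].
#'
#' @param geom A [stereo_geometry()] (the ground-truth geometry).
#' @param phantom A [build_phantom()] model.
#' @param angles Stage angles in degrees (non-empty).
#' @param opts A [render_options()].
#' @param seed Optional seed applied before noise generation, making
#'   Poisson datasets reproducible.
#' @return A list of class \code{simulated_dataset} with \code{images}
#'   (list indexed \code{[[system]][[angle index]]} or NULL),
#'   \code{flatfield} (list per system), \code{truth} (reference table with
#'   pixel coordinates appended), \code{geometry}, \code{phantom},
#'   \code{angles}, \code{opts}.
#' @export
simulate_dataset <- function(geom, phantom, angles,
                             opts = render_options(), seed = NULL) {
  stopifnot(length(angles) >= 1)
  if (!is.null(seed)) set.seed(seed)
  truth <- project_all(geom, phantom, angles)
  spec_of <- function(i) geometry_pair(geom, i)$detector_spec
  for (i in c(1L, 2L)) {
    sel <- truth$system == i
    px <- mm_to_px(truth$u_mm[sel], truth$v_mm[sel], spec_of(i))
    truth$u_px[sel] <- px$col
    truth$v_px[sel] <- px$row
  }
  images <- NULL
  flat <- NULL
  if (opts$render_mode == "images") {
    images <- lapply(c(1L, 2L), function(i)
      lapply(angles, function(a)
        render_projection(geom, phantom, i, a, opts)))
    flat <- lapply(c(1L, 2L), function(i) {
      spec <- spec_of(i)
      matrix(opts$background_level, spec$n_v, spec$n_u)
    })
  }
  structure(list(images = images, flatfield = flat, truth = truth,
                 geometry = geom, phantom = phantom, angles = angles,
                 opts = opts),
            class = "simulated_dataset")
}

#' Write a simulated dataset to a directory
#'
#' Images go to 16-bit TIFF files named \code{sys\{i\}_ang\{nnnn\}.tif},
#' flatfields to \code{flat_sys\{i\}.tif}, and the truth table to
#' \code{truth.csv}. Intensities are scaled by \code{1/max_counts} into the
#' 16-bit range.
#'
#' @param ds A [simulate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @param max_counts Full-scale intensity mapped to 65535.
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(ds, dir, max_counts = 65535) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(ds$images)) {
    for (i in c(1L, 2L)) {
      for (n in seq_along(ds$angles)) {
        path <- file.path(dir, sprintf("sys%d_ang%04d.tif", i, n - 1L))
        write_image_tiff(ds$images[[i]][[n]], path, max_counts = max_counts)
      }
      write_image_tiff(ds$flatfield[[i]],
                       file.path(dir, sprintf("flat_sys%d.tif", i)),
                       max_counts = max_counts)
    }
  }
  truth <- ds$truth
  out <- data.frame(system = truth$system, angle_index = truth$angle_index,
                    angle_deg = truth$angle_deg,
                    marker_id = truth$marker_id,
                    u_mm = truth$u_mm, v_mm = truth$v_mm,
                    u_px = truth$u_px, v_px = truth$v_px,
                    in_fov = truth$in_fov)
  write_table_csv(out, file.path(dir, "truth.csv"))
  invisible(dir)
}
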