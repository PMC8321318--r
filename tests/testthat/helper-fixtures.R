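# Shared fixtures: small geometries and phantoms built in code.

# study-scale pair 1 values used throughout
STUDY_SOD1 <- 779
STUDY_SDD1 <- 1123

study_spec <- function() detector_spec(2048, 2048, 0.142)

aligned_pair1 <- function(spec = study_spec(), dsod = 0,
                          pose = rigid_pose()) {
  source_detector_pair(STUDY_SOD1, STUDY_SDD1, spec, dsod = dsod,
                       detector_pose = pose)
}

aligned_geometry <- function(spec = study_spec()) {
  stereo_geometry(aligned_pair1(spec),
                  source_detector_pair(783, 1141, spec),
                  alpha = 90)
}

# one-marker phantom whose single bead sits at the rotation center when the
# phantom pose cancels its lattice coordinates
one_marker_phantom <- function() {
  build_phantom(brick_lattice(), list(marker_placement(3, 2)))
}

pose_centering <- function(phantom, marker = 1) {
  m <- phantom$markers[marker, ]
  rigid_pose(dx = -m$x_mm, dy = -m$y_mm, dz = -m$z_mm)
}

# small-detector study geometry for image-based tests: full phantom in view,
# beads ~6 px across
small_image_setup <- function(misaligned = TRUE) {
  spec <- detector_spec(512, 512, 0.6)
  base <- base_geometry(STUDY_SOD1, STUDY_SDD1, 783, 1141, spec1 = spec)
  beta <- if (misaligned)
    parameter_vector(c(dx_o = -3, dy_o = 5, phi_o = 20, theta_o = 1,
                       dx_1d = 4, dy_1d = -6, theta_1d = 2, alpha = 92))
  else parameter_vector()
  list(base = base, beta = beta, geom = apply_beta(base, beta),
       phantom = default_phantom(), angles = (0:5) * 60)
}

expect_all_close <- function(actual, expected, tol = 1e-9) {
  expect_true(max(abs(actual - expected)) <= tol,
              label = sprintf("max abs deviation %.3g <= %.3g",
                              max(abs(actual - expected)), tol))
}

ORIENTATION_PARAMS <- c("theta_o", "phi_o", "eta_o", "alpha",
                        "theta_1d", "phi_1d", "eta_1d",
                        "theta_2d", "phi_2d", "eta_2d")
NONOPTICAL_TRANSLATIONS <- c("dx_o", "dy_o", "dz_o",
                             "dy_1d", "dz_1d", "dy_2d", "dz_2d")
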