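#' Reference simulated-study configuration
#'
#' The simulated validation setup for the calibration procedure: two
#' 2048 x 2048 flat panels with 142 um pixels, measured SOD/SDD of
#' \{779, 1123\} mm (pair 1) and \{783, 1141\} mm (pair 2), 61 stage
#' angles per system over a full turn, the default five-marker phantom,
#' and a known ground-truth misalignment vector (phantom shifted by up to
#' ~13 mm and yawed 187 degrees, detectors displaced by 10-20 mm and
#' tilted by up to ~4 degrees, stereo angle 94.1 degrees, SOD offsets of
#' 7.21 and 11.9 mm). Calibration starts blind: all parameters 0, stereo
#' angle 90 degrees.
#'
#' @param n_angles Number of stage angles per system (default 61).
#' @return A list with \code{base} ([base_geometry()]), \code{beta_true}
#'   ([parameter_vector()]), \code{phantom}, \code{angles} (degrees) and
#'   \code{beta_init} (the blind initialization).
#' @examples
#' cfg <- sim_study_config(n_angles = 7)
#' truth <- project_all(apply_beta(cfg$base, cfg$beta_true),
#'                      cfg$phantom, cfg$angles)
#' @export
sim_study_config <- function(n_angles = 61) {
  gt <- c(dx_o = -7.96, dy_o = 12.6, dz_o = -12.6,
          theta_o = 4.08, phi_o = 187, eta_o = 4.29,
          alpha = 94.1, dsod_1 = 7.21, dsod_2 = 11.9,
          dx_1d = 19.7, dy_1d = -18.5, dz_1d = -10.1,
          theta_1d = 3.81, phi_1d = 2.02, eta_1d = 2.08,
          dx_2d = -10.2, dy_2d = -17.8, dz_2d = 14.0,
          theta_2d = 4.24, phi_2d = 2.01, eta_2d = 0.67)
  spec <- detector_spec(2048, 2048, 0.142)
  list(base = base_geometry(779, 1123, 783, 1141, spec1 = spec),
       beta_true = parameter_vector(gt),
       phantom = default_phantom(),
       angles = (seq_len(n_angles) - 1) * (360 / n_angles),
       beta_init = parameter_vector())
}
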