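PARAM_NAMES <- c("dx_o", "dy_o", "dz_o", "theta_o", "phi_o", "eta_o",
                 "alpha", "dsod_1", "dsod_2",
                 "dx_1d", "dy_1d", "dz_1d", "theta_1d", "phi_1d", "eta_1d",
                 "dx_2d", "dy_2d", "dz_2d", "theta_2d", "phi_2d", "eta_2d")

PARAM_UNITS <- c(dx_o = "mm", dy_o = "mm", dz_o = "mm",
                 theta_o = "deg", phi_o = "deg", eta_o = "deg",
                 alpha = "deg", dsod_1 = "mm", dsod_2 = "mm",
                 dx_1d = "mm", dy_1d = "mm", dz_1d = "mm",
                 theta_1d = "deg", phi_1d = "deg", eta_1d = "deg",
                 dx_2d = "mm", dy_2d = "mm", dz_2d = "mm",
                 theta_2d = "deg", phi_2d = "deg", eta_2d = "deg")

default_bounds <- function(alpha_nominal = 90) {
  lower <- c(dx_o = -100, dy_o = -100, dz_o = -100,
             theta_o = -45, phi_o = -Inf, eta_o = -45,
             alpha = alpha_nominal - 30, dsod_1 = -50, dsod_2 = -50,
             dx_1d = -100, dy_1d = -100, dz_1d = -100,
             theta_1d = -45, phi_1d = -45, eta_1d = -45,
             dx_2d = -100, dy_2d = -100, dz_2d = -100,
             theta_2d = -45, phi_2d = -45, eta_2d = -45)
  upper <- c(dx_o = 100, dy_o = 100, dz_o = 100,
             theta_o = 45, phi_o = Inf, eta_o = 45,
             alpha = alpha_nominal + 30, dsod_1 = 50, dsod_2 = 50,
             dx_1d = 100, dy_1d = 100, dz_1d = 100,
             theta_1d = 45, phi_1d = 45, eta_1d = 45,
             dx_2d = 100, dy_2d = 100, dz_2d = 100,
             theta_2d = 45, phi_2d = 45, eta_2d = 45)
  list(lower = lower[PARAM_NAMES], upper = upper[PARAM_NAMES])
}

#' The 21-DOF stereo misalignment parameter vector
#'
#' Named vector of the 21 calibration degrees of freedom: phantom pose
#' \{dx_o, dy_o, dz_o, theta_o, phi_o, eta_o\}, stereo angle \code{alpha},
#' SOD offsets \{dsod_1, dsod_2\} and per detector
#' \{dx_id, dy_id, dz_id, theta_id, phi_id, eta_id\}. Translations are in
#' mm, angles in degrees. Each entry carries bounds and a fixed/free mask;
#' masked (fixed) entries never change during optimization.
#'
#' @param values Named numeric vector (subset of the 21 names) of initial
#'   values; unnamed entries default to 0 except \code{alpha}, which
#'   defaults to \code{alpha_init}.
#' @param alpha_init Initial stereo angle (degrees), default 90.
#' @param fixed Character vector of parameter names to fix at their initial
#'   values.
#' @param lower,upper Optional named bound overrides.
#' @return An object of class \code{parameter_vector}: list with
#'   \code{values}, \code{fixed} (logical mask), \code{lower},
#'   \code{upper}, \code{units}.
#' @examples
#' beta <- parameter_vector(c(phi_o = 187, alpha = 94.1))
#' n_free(fix_parameters(beta, c("dsod_1", "dsod_2")))  # 19
#' @export
parameter_vector <- function(values = numeric(), alpha_init = 90,
                             fixed = character(), lower = NULL,
                             upper = NULL) {
  v <- stats::setNames(numeric(length(PARAM_NAMES)), PARAM_NAMES)
  v["alpha"] <- alpha_init
  if (length(values)) {
    bad <- setdiff(names(values), PARAM_NAMES)
    if (length(bad)) stop("unknown parameter name(s): ",
                          paste(bad, collapse = ", "))
    v[names(values)] <- values
  }
  b <- default_bounds(alpha_nominal = alpha_init)
  if (!is.null(lower)) b$lower[names(lower)] <- lower
  if (!is.null(upper)) b$upper[names(upper)] <- upper
  mask <- stats::setNames(rep(FALSE, length(PARAM_NAMES)), PARAM_NAMES)
  obj <- structure(list(values = v, fixed = mask,
                        lower = b$lower, upper = b$upper,
                        units = PARAM_UNITS),
                   class = "parameter_vector")
  if (length(fixed)) obj <- fix_parameters(obj, fixed)
  obj
}

#' @export
print.parameter_vector <- function(x, ...) {
  df <- data.frame(value = x$values, unit = x$units,
                   fixed = x$fixed)
  cat(sprintf("parameter_vector: %d free of %d DOF\n",
              n_free(x), length(x$values)))
  print(df)
  invisible(x)
}

#' Fix (mask) parameters at their current values
#'
#' Masked entries are pinned during optimization; calibration stages whose
#' free set is entirely masked are skipped. Eliminating \code{dsod_1} and
#' \code{dsod_2} (the real-data mode, where SOD offsets are degenerate with
#' the detector translations along the optical axes) leaves 19 free DOF.
#'
#' @param beta A [parameter_vector()].
#' @param names Parameter names to fix.
#' @return The updated \code{parameter_vector}.
#' @export
fix_parameters <- function(beta, names) {
  bad <- setdiff(names, PARAM_NAMES)
  if (length(bad)) stop("unknown parameter name(s): ",
                        paste(bad, collapse = ", "))
  beta$fixed[names] <- TRUE
  beta
}

#' Number of free (unmasked) parameters
#' @param beta A [parameter_vector()].
#' @return Integer count of free entries.
#' @export
n_free <- function(beta) sum(!beta$fixed)

#' Base (measured) geometry of a stereo system
#'
#' Holds the quantities that are measured, not calibrated: per-pair SOD and
#' SDD, the detector specifications, and the nominal stereo angle. A
#' [parameter_vector()] applied to a base geometry with [apply_beta()]
#' yields a full [stereo_geometry()].
#'
#' @param sod1,sdd1,sod2,sdd2 Measured distances (mm).
#' @param spec1,spec2 [detector_spec()] objects (spec2 defaults to spec1).
#' @param alpha_nominal Nominal stereo angle (degrees).
#' @return An object of class \code{base_geometry}.
#' @export
base_geometry <- function(sod1, sdd1, sod2, sdd2,
                          spec1 = detector_spec(2048, 2048, 0.142),
                          spec2 = spec1, alpha_nominal = 90) {
  structure(list(sod1 = sod1, sdd1 = sdd1, sod2 = sod2, sdd2 = sdd2,
                 spec1 = spec1, spec2 = spec2,
                 alpha_nominal = alpha_nominal),
            class = "base_geometry")
}

#' Realize a stereo geometry from base measurements and a parameter vector
#'
#' @param base A [base_geometry()].
#' @param beta A [parameter_vector()] (or named numeric of the 21 values).
#' @return A [stereo_geometry()].
#' @export
apply_beta <- function(base, beta) {
  v <- if (inherits(beta, "parameter_vector")) beta$values else beta
  stopifnot(all(PARAM_NAMES %in% names(v)))
  p1 <- source_detector_pair(
    base$sod1, base$sdd1, base$spec1, dsod = v[["dsod_1"]],
    detector_pose = rigid_pose(v[["dx_1d"]], v[["dy_1d"]], v[["dz_1d"]],
                               v[["theta_1d"]], v[["phi_1d"]], v[["eta_1d"]]))
  p2 <- source_detector_pair(
    base$sod2, base$sdd2, base$spec2, dsod = v[["dsod_2"]],
    detector_pose = rigid_pose(v[["dx_2d"]], v[["dy_2d"]], v[["dz_2d"]],
                               v[["theta_2d"]], v[["phi_2d"]], v[["eta_2d"]]))
  stereo_geometry(p1, p2, alpha = v[["alpha"]],
                  phantom_pose = rigid_pose(v[["dx_o"]], v[["dy_o"]],
                                            v[["dz_o"]], v[["theta_o"]],
                                            v[["phi_o"]], v[["eta_o"]]))
}
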