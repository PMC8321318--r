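# Internal lean forward model: detector coordinates of every marker at
# every angle for one system, in angle-major order (K markers per angle).
# Returns a 2-column matrix (u_mm, v_mm); NA rows mark degenerate rays.
forward_uv <- function(geom, phantom, angles, system) {
  P <- phantom_marker_matrix(phantom)
  K <- nrow(P)
  N <- length(angles)
  Ro <- pose_rotation(geom$phantom_pose)
  to <- pose_translation(geom$phantom_pose)
  P0 <- sweep(P %*% t(Ro), 2, -to)
  ar <- deg2rad(angles)
  ca <- cos(ar); sa <- sin(ar)
  idx <- rep(seq_len(N), each = K)
  x0 <- rep(P0[, 1], N); y0 <- rep(P0[, 2], N); z0 <- rep(P0[, 3], N)
  wx <- ca[idx] * x0 + sa[idx] * z0
  wy <- y0
  wz <- -sa[idx] * x0 + ca[idx] * z0

  fr <- pair_frame(geometry_pair(geom, system),
                   pair_system_rotation(geom, system))
  n <- frame_normal(fr)
  dx <- wx - fr$source[1]; dy <- wy - fr$source[2]; dz <- wz - fr$source[3]
  denom <- dx * n[1] + dy * n[2] + dz * n[3]
  num <- sum((fr$det_center - fr$source) * n)
  tpar <- num / denom
  ok <- is.finite(tpar) & tpar > 0 & abs(denom) > 1e-12
  rx <- fr$source[1] + tpar * dx - fr$det_center[1]
  ry <- fr$source[2] + tpar * dy - fr$det_center[2]
  rz <- fr$source[3] + tpar * dz - fr$det_center[3]
  u <- rx * fr$e_u[1] + ry * fr$e_u[2] + rz * fr$e_u[3]
  v <- rx * fr$e_v[1] + ry * fr$e_v[2] + rz * fr$e_v[3]
  u[!ok] <- NA_real_; v[!ok] <- NA_real_
  cbind(u, v)
}

# Precompiled cost closure. Matches measurement records to forward-model
# rows once, then evaluates the reprojection cost for arbitrary parameter
# values. Out-of-FOV references stay in the cost at their computed (u, v);
# degenerate rays incur a fixed penalty per record so the optimizer is
# repelled, never crashed.
make_cost <- function(measurements, base, phantom, systems = c(1L, 2L),
                      variant = c("l1", "l2"), eps = 1e-9,
                      units = c("mm", "px")) {
  variant <- match.arg(variant)
  units <- match.arg(units)
  m <- measurements[measurements$valid & measurements$system %in% systems, ]
  if (nrow(m) == 0) stop("no valid measurements for the selected systems")
  ids <- phantom$markers$id
  K <- length(ids)
  sys_parts <- list()
  for (s in unique(m$system)) {
    ms <- m[m$system == s, ]
    angles <- sort(unique(ms$angle_deg))
    ai <- match(ms$angle_deg, angles)
    ki <- match(ms$marker_id, ids)
    if (anyNA(ki)) stop("measurement marker_id not present in phantom")
    scale <- if (units == "px") {
      sp <- if (s == 1L) base$spec1 else base$spec2
      1 / sp$pixel_size
    } else 1
    sys_parts[[as.character(s)]] <- list(
      system = as.integer(s), angles = angles,
      rows = (ai - 1L) * K + ki,
      u = ms$u_mm, v = ms$v_mm, scale = scale)
  }
  penalty <- 1e6
  function(values) {
    geom <- apply_beta(base, values)
    total <- 0
    for (p in sys_parts) {
      uv <- forward_uv(geom, phantom, p$angles, p$system)
      du <- (uv[p$rows, 1] - p$u) * p$scale
      dv <- (uv[p$rows, 2] - p$v) * p$scale
      bad <- !is.finite(du) | !is.finite(dv)
      if (any(bad)) {
        total <- total + penalty * sum(bad)
        du <- du[!bad]; dv <- dv[!bad]
      }
      total <- total + if (variant == "l1")
        sum(sqrt(du * du + dv * dv + eps * eps)) else
        sum(du * du + dv * dv)
    }
    total
  }
}

# Residual-vector closure for least-squares refinement: stacked (du, dv)
# over all valid records of the selected systems.
make_resid <- function(measurements, base, phantom, systems = c(1L, 2L),
                       units = c("mm", "px")) {
  units <- match.arg(units)
  m <- measurements[measurements$valid & measurements$system %in% systems, ]
  if (nrow(m) == 0) stop("no valid measurements for the selected systems")
  ids <- phantom$markers$id
  K <- length(ids)
  sys_parts <- list()
  for (s in unique(m$system)) {
    ms <- m[m$system == s, ]
    angles <- sort(unique(ms$angle_deg))
    scale <- if (units == "px") {
      sp <- if (s == 1L) base$spec1 else base$spec2
      1 / sp$pixel_size
    } else 1
    sys_parts[[as.character(s)]] <- list(
      system = as.integer(s), angles = angles,
      rows = (match(ms$angle_deg, angles) - 1L) * K +
        match(ms$marker_id, ids),
      u = ms$u_mm, v = ms$v_mm, scale = scale)
  }
  function(values) {
    geom <- apply_beta(base, values)
    out <- lapply(sys_parts, function(p) {
      uv <- forward_uv(geom, phantom, p$angles, p$system)
      c((uv[p$rows, 1] - p$u) * p$scale, (uv[p$rows, 2] - p$v) * p$scale)
    })
    r <- unlist(out, use.names = FALSE)
    r[!is.finite(r)] <- 1e3
    r
  }
}

#' Reprojection cost of a parameter vector
#'
#' The calibration cost: the total Euclidean distance between the
#' model-predicted (reference) marker projections under \code{beta} and the
#' measured detector coordinates, summed over all valid measurement records
#' of the selected systems. References falling outside the detector field
#' of view are kept in the sum at their computed coordinates, so the cost
#' cannot be lowered by pushing markers off the detector.
#'
#' @param beta A [parameter_vector()] or named numeric of the 21 values.
#' @param measurements A measurement table (columns \code{system},
#'   \code{angle_deg}, \code{marker_id}, \code{u_mm}, \code{v_mm},
#'   \code{valid}).
#' @param base A [base_geometry()].
#' @param phantom A [build_phantom()] model.
#' @param systems Which systems' records enter the cost.
#' @param variant \code{"l1"} (sum of distances, the default) or
#'   \code{"l2"} (sum of squared distances).
#' @param eps Smoothing length (mm) applied inside the square root of the
#'   L1 variant so the cost is differentiable at zero residual. The
#'   default 0 evaluates the exact sum of distances; the optimizer uses
#'   the smoothed version ([calib_config()]'s \code{eps}).
#' @param units Evaluate residuals in \code{"mm"} (default) or
#'   \code{"px"}.
#' @return The scalar cost (mm or px, by \code{units}).
#' @export
calib_cost <- function(beta, measurements, base, phantom,
                       systems = c(1L, 2L), variant = "l1", eps = 0,
                       units = "mm") {
  v <- if (inherits(beta, "parameter_vector")) beta$values else beta
  fn <- make_cost(measurements, base, phantom, systems = systems,
                  variant = variant, eps = eps, units = units)
  fn(v)
}

#' Calibration configuration
#'
#' @param tol Outer-loop convergence tolerance on both the cost decrease
#'   and the maximum parameter update (mm / deg).
#' @param max_outer Outer iteration cap.
#' @param scan_step Step (degrees) of the stage-1 global scan over
#'   \code{phi_o}.
#' @param variant Cost variant, \code{"l1"} (default) or \code{"l2"}.
#' @param eps L1 smoothing length (mm).
#' @param units \code{"mm"} or \code{"px"} residual units.
#' @param maxit Iteration cap per stage optimization.
#' @param accelerate Run a Levenberg-Marquardt refinement of all free
#'   parameters at the end of each outer iteration. The step is a pure
#'   accelerator: it is accepted only when it lowers the staged cost and
#'   respects the parameter bounds, so the cost trace stays non-increasing
#'   and the estimate remains a minimizer of the configured cost.
#' @param verbose Print per-stage progress.
#' @return A list of class \code{calib_config}.
#' @export
calib_config <- function(tol = 1e-6, max_outer = 30, scan_step = 5,
                         variant = "l1", eps = 1e-9, units = "mm",
                         maxit = 200, accelerate = TRUE, verbose = FALSE) {
  structure(list(tol = tol, max_outer = max_outer, scan_step = scan_step,
                 variant = variant, eps = eps, units = units,
                 maxit = maxit, accelerate = accelerate, verbose = verbose),
            class = "calib_config")
}

# Guarded Levenberg-Marquardt refinement over the free parameters.
# Returns the input beta untouched unless the refined point lowers the
# configured cost and stays inside the bounds.
lm_refine <- function(beta, measurements, base, phantom, config) {
  free <- names(beta$values)[!beta$fixed]
  if (!length(free)) return(beta)
  resid_fn <- make_resid(measurements, base, phantom,
                         systems = c(1L, 2L), units = config$units)
  v <- beta$values
  fn <- function(x) {
    v[free] <- x
    resid_fn(v)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(beta$values[free], fn = fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit)) return(beta)
  cand <- beta
  cand$values[free] <- fit$par
  if (any(cand$values < beta$lower | cand$values > beta$upper))
    return(beta)
  fn_cost <- function(b) calib_cost(b, measurements, base, phantom,
                                    systems = c(1L, 2L),
                                    variant = config$variant,
                                    eps = config$eps, units = config$units)
  if (fn_cost(cand) < fn_cost(beta)) cand else beta
}

#' Default staged calibration schedule
#'
#' The stages of the full stereo calibration, executed in order inside each
#' outer iteration: (1) phantom yaw \code{phi_o} and height \code{dy_o}
#' (with a coarse global scan of \code{phi_o} on the first pass, since the
#' yaw is entirely unknown); (2) phantom translations; (3) phantom
#' orientations; (4) phantom 6-DOF plus the stereo angle on both datasets;
#' (5) \code{dsod_1}, then detector 1's 6 DOF jointly with it; (6) the same
#' for system 2; (7) all unmasked DOF jointly on both datasets.
#'
#' @param dsod_mode How stages 5/6 treat the SOD offset relative to the
#'   detector DOF: \code{"sequential_joint"} (offset alone, then jointly
#'   with the detector pose; default), \code{"sequential"} (offset alone,
#'   then detector pose alone) or \code{"joint"} (one joint stage).
#' @return A list of stages, each with \code{free} (parameter names),
#'   \code{systems}, \code{label} and optionally \code{scan = TRUE}.
#' @export
default_schedule <- function(dsod_mode = c("sequential_joint", "sequential",
                                           "joint")) {
  dsod_mode <- match.arg(dsod_mode)
  d1 <- c("dx_1d", "dy_1d", "dz_1d", "theta_1d", "phi_1d", "eta_1d")
  d2 <- c("dx_2d", "dy_2d", "dz_2d", "theta_2d", "phi_2d", "eta_2d")
  det_stages <- function(i, det) {
    ds <- paste0("dsod_", i)
    switch(dsod_mode,
      sequential_joint = list(
        list(free = ds, systems = i, label = paste0("dsod", i)),
        list(free = c(ds, det), systems = i,
             label = paste0("detector", i))),
      sequential = list(
        list(free = ds, systems = i, label = paste0("dsod", i)),
        list(free = det, systems = i, label = paste0("detector", i))),
      joint = list(
        list(free = c(ds, det), systems = i,
             label = paste0("detector", i))))
  }
  c(list(
      list(free = c("phi_o", "dy_o"), systems = 1L, scan = TRUE,
           label = "vertical_alignment"),
      list(free = c("dx_o", "dy_o", "dz_o"), systems = 1L,
           label = "phantom_translation"),
      list(free = c("theta_o", "phi_o", "eta_o"), systems = 1L,
           label = "phantom_orientation"),
      list(free = c("dx_o", "dy_o", "dz_o", "theta_o", "phi_o", "eta_o",
                    "alpha"),
           systems = c(1L, 2L), label = "phantom_and_alpha")),
    det_stages(1L, d1),
    det_stages(2L, d2),
    list(list(free = PARAM_NAMES, systems = c(1L, 2L),
              label = "joint_refinement")))
}

# per-parameter finite-difference steps: 1e-4 mm, 1e-5 deg
param_ndeps <- function(names) {
  ifelse(PARAM_UNITS[names] == "deg", 1e-5, 1e-4)
}

#' Optimize a subset of parameters at fixed others
#'
#' Bound-constrained local minimization (L-BFGS-B with central-difference
#' gradients) of the reprojection cost over \code{free}, holding every
#' other entry of \code{beta} at its current value. Never returns a worse
#' point than the input: if the optimizer fails or ends above the starting
#' cost, the input is kept and a warning records the failure.
#'
#' @param beta A [parameter_vector()].
#' @param free Names of the parameters to optimize (masked entries are
#'   silently excluded).
#' @param measurements,base,phantom As in [calib_cost()].
#' @param systems Which systems' data to use.
#' @param config A [calib_config()].
#' @return The updated [parameter_vector()] with attribute \code{"cost"}.
#' @export
optimize_stage <- function(beta, free, measurements, base, phantom,
                           systems = c(1L, 2L), config = calib_config()) {
  free <- free[!beta$fixed[free]]
  if (!length(free)) {
    attr(beta, "cost") <- calib_cost(beta, measurements, base, phantom,
                                     systems = systems,
                                     variant = config$variant,
                                     eps = config$eps, units = config$units)
    return(beta)
  }
  fn_full <- make_cost(measurements, base, phantom, systems = systems,
                       variant = config$variant, eps = config$eps,
                       units = config$units)
  v <- beta$values
  fn <- function(x) {
    v[free] <- x
    fn_full(v)
  }
  f0 <- fn(beta$values[free])
  res <- tryCatch(
    stats::optim(beta$values[free], fn, method = "L-BFGS-B",
                 lower = beta$lower[free], upper = beta$upper[free],
                 control = list(maxit = config$maxit, factr = 10,
                                pgtol = 0,
                                ndeps = param_ndeps(free))),
    error = function(e) {
      warning("stage optimization failed (", conditionMessage(e),
              "); keeping best-so-far parameters")
      NULL
    })
  if (!is.null(res) && is.finite(res$value) && res$value <= f0) {
    beta$values[free] <- res$par
    attr(beta, "cost") <- res$value
  } else {
    if (!is.null(res))
      warning("stage optimization did not improve the cost; keeping input")
    attr(beta, "cost") <- f0
  }
  beta
}

# Stage-1 global search: coarse scan of phi_o over [0, 360) with dy_o
# re-solved at every scan point, then local refinement of both. Needed
# because the phantom yaw is completely unknown at start-up while the cost
# in phi_o is highly multimodal.
scan_phi_o <- function(beta, measurements, base, phantom, systems, config) {
  fn_full <- make_cost(measurements, base, phantom, systems = systems,
                       variant = config$variant, eps = config$eps,
                       units = config$units)
  v <- beta$values
  grid <- seq(0, 360 - config$scan_step, by = config$scan_step)
  best <- NULL
  for (phi in grid) {
    v["phi_o"] <- phi
    opt <- stats::optimize(function(y) {
      v["dy_o"] <- y
      fn_full(v)
    }, lower = max(beta$lower["dy_o"], -200),
       upper = min(beta$upper["dy_o"], 200), tol = 1e-3)
    if (is.null(best) || opt$objective < best$cost)
      best <- list(phi = phi, dy = opt$minimum, cost = opt$objective)
  }
  beta$values["phi_o"] <- best$phi
  beta$values["dy_o"] <- best$dy
  beta
}

#' Staged calibration of the stereo geometry
#'
#' Estimates the 21-DOF misalignment vector by iterating the staged
#' schedule until either the outer-loop cost decrease or the maximum
#' parameter update falls below the tolerance, or the iteration cap is
#' reached. Accepted stage solutions never increase the cost.
#'
#' @param measurements Measurement table covering both systems.
#' @param base A [base_geometry()] with SOD/SDD fixed to their measured
#'   values.
#' @param phantom A [build_phantom()] model (>= 1 marker).
#' @param beta_init Starting [parameter_vector()]; defaults to all zero
#'   with \code{alpha = 90}.
#' @param schedule A stage list from [default_schedule()].
#' @param config A [calib_config()].
#' @return A \code{calibration_result}: list with \code{beta} (estimated
#'   [parameter_vector()]), \code{cost} (final), \code{outer_costs}
#'   (two-system cost before iterating and after each outer iteration, a
#'   non-increasing sequence), \code{history}
#'   (per-stage cost trace), \code{residuals} (per-record final
#'   reprojection residuals, mm), \code{converged}, \code{outer_iterations}
#'   and \code{n_free}.
#' @export
calibrate_geometry <- function(measurements, base, phantom,
                               beta_init = parameter_vector(),
                               schedule = default_schedule(),
                               config = calib_config()) {
  stopifnot(nrow(phantom$markers) >= 1)
  if (!any(measurements$valid))
    stop("no valid measurements")
  beta <- beta_init
  cost_of <- function(b) calib_cost(b, measurements, base, phantom,
                                    systems = c(1L, 2L),
                                    variant = config$variant,
                                    eps = config$eps, units = config$units)
  have2 <- any(measurements$valid & measurements$system == 2L)
  hist <- list()
  cost_prev <- cost_of(beta)
  outer_costs <- cost_prev
  converged <- FALSE
  iter <- 0L
  for (outer in seq_len(config$max_outer)) {
    iter <- outer
    vals_prev <- beta$values
    for (si in seq_along(schedule)) {
      st <- schedule[[si]]
      free <- st$free[!beta$fixed[st$free]]
      if (!length(free)) next
      systems <- st$systems
      if (!have2) systems <- systems[systems == 1L]
      if (!length(systems)) next
      if (isTRUE(st$scan) && outer == 1L &&
          all(c("phi_o", "dy_o") %in% free)) {
        beta <- scan_phi_o(beta, measurements, base, phantom, systems,
                           config)
      }
      beta <- optimize_stage(beta, st$free, measurements, base, phantom,
                             systems = systems, config = config)
      hist[[length(hist) + 1]] <- data.frame(
        outer = outer, stage = si, label = st$label,
        cost = attr(beta, "cost"))
      if (config$verbose)
        message(sprintf("outer %d stage %d (%s): cost %.6g",
                        outer, si, st$label, attr(beta, "cost")))
    }
    if (isTRUE(config$accelerate)) {
      beta <- lm_refine(beta, measurements, base, phantom, config)
      hist[[length(hist) + 1]] <- data.frame(
        outer = outer, stage = length(schedule) + 1L,
        label = "lm_refinement", cost = cost_of(beta))
    }
    cost_now <- cost_of(beta)
    outer_costs <- c(outer_costs, cost_now)
    dcost <- cost_prev - cost_now
    dpar <- max(abs(beta$values - vals_prev))
    cost_prev <- cost_now
    if (dcost < config$tol || dpar < config$tol) {
      converged <- TRUE
      break
    }
  }
  geom <- apply_beta(base, beta)
  refs <- project_all(geom, phantom,
                      sort(unique(measurements$angle_deg)))
  res <- merge(measurements[measurements$valid, ],
               refs[, c("system", "angle_deg", "marker_id", "u_mm", "v_mm")],
               by = c("system", "angle_deg", "marker_id"),
               suffixes = c("_mea", "_ref"))
  res$residual_mm <- sqrt((res$u_mm_ref - res$u_mm_mea)^2 +
                          (res$v_mm_ref - res$v_mm_mea)^2)
  structure(list(beta = beta, cost = cost_prev,
                 outer_costs = outer_costs,
                 history = do.call(rbind, hist),
                 residuals = res[order(res$system, res$angle_deg,
                                       res$marker_id), ],
                 converged = converged, outer_iterations = iter,
                 n_free = n_free(beta)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration_result: cost %.6g mm over %d records, %s after %d outer iteration(s), %d free DOF\n",
              x$cost, nrow(x$residuals),
              if (x$converged) "converged" else "NOT converged",
              x$outer_iterations, x$n_free))
  cat(sprintf("  residuals: median %.3g mm, max %.3g mm\n",
              stats::median(x$residuals$residual_mm),
              max(x$residuals$residual_mm)))
  invisible(x)
}

#' Build a measurement table from a reference (truth) table
#'
#' Turns exact analytically projected marker centers into the measurement
#' format expected by [calibrate_geometry()]; records outside the field of
#' view are marked invalid.
#'
#' @param truth A reference table from [project_all()].
#' @return A measurement table.
#' @export
measurements_from_truth <- function(truth) {
  data.frame(system = truth$system, angle_index = truth$angle_index,
             angle_deg = truth$angle_deg, marker_id = truth$marker_id,
             u_mm = truth$u_mm, v_mm = truth$v_mm,
             valid = truth$in_fov & truth$valid)
}
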