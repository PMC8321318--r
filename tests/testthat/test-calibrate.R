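# shared exact-center measurements at a reduced angle count; the study
# conditions themselves (61 angles) are exercised in the acceptance suite
cfg <- sim_study_config(n_angles = 15)
truth <- project_all(apply_beta(cfg$base, cfg$beta_true),
                     cfg$phantom, cfg$angles)
meas <- measurements_from_truth(truth)

test_that("the reprojection cost is a sum of Euclidean distances", {
  expect_lt(calib_cost(cfg$beta_true, meas, cfg$base, cfg$phantom), 1e-9)

  # single-record 3-4-5 triangle and degree-1 homogeneity
  ph1 <- one_marker_phantom()
  base1 <- base_geometry(779, 1123, 783, 1141)
  ref1 <- project_all(apply_beta(base1, parameter_vector()), ph1, 0)
  m1 <- measurements_from_truth(ref1[1, ])
  m345 <- m1; m345$u_mm <- m345$u_mm + 3; m345$v_mm <- m345$v_mm + 4
  expect_equal(calib_cost(parameter_vector(), m345, base1, ph1,
                          systems = 1L), 5, tolerance = 1e-9)
  m2x <- m1; m2x$u_mm <- m2x$u_mm + 6; m2x$v_mm <- m2x$v_mm + 8
  expect_equal(calib_cost(parameter_vector(), m2x, base1, ph1,
                          systems = 1L), 10, tolerance = 1e-9)

  # references pushed off the detector still count
  far <- parameter_vector(c(dy_o = 90))
  expect_gt(calib_cost(far, m1, base1, ph1, systems = 1L), 100)
  expect_true(is.finite(calib_cost(far, m1, base1, ph1, systems = 1L)))

  expect_error(calib_cost(parameter_vector(),
                          transform(m1, valid = FALSE), base1, ph1),
               "no valid measurements")
})

test_that("masking pins parameters and adjusts the free-DOF count", {
  beta <- parameter_vector()
  expect_equal(n_free(beta), 21)
  expect_equal(n_free(fix_parameters(beta, c("dsod_1", "dsod_2"))), 19)
  expect_error(fix_parameters(beta, "dsod_3"), "unknown parameter")

  # masking everything makes calibration a no-op
  all_fixed <- fix_parameters(beta, names(beta$values))
  res <- calibrate_geometry(meas, cfg$base, cfg$phantom,
                            beta_init = all_fixed,
                            config = calib_config(max_outer = 2))
  expect_equal(res$beta$values, all_fixed$values)
  expect_equal(res$n_free, 0)
})

test_that("optimize_stage recovers a single perturbed parameter", {
  for (p in c("dy_o", "theta_1d")) {
    beta <- cfg$beta_true
    beta$values[p] <- beta$values[p] + 0.05
    out <- optimize_stage(beta, p, meas, cfg$base, cfg$phantom,
                          systems = c(1L, 2L))
    expect_lt(abs(out$values[p] - cfg$beta_true$values[p]), 1e-6)
  }

  # at the optimum the stage returns the input unchanged
  out0 <- optimize_stage(cfg$beta_true, c("dx_o", "dy_o"), meas,
                         cfg$base, cfg$phantom)
  expect_all_close(out0$values, cfg$beta_true$values, 1e-9)
})

test_that("the coarse yaw scan lands in the 187-degree basin from a blind start", {
  sched <- default_schedule()[1]  # vertical-alignment stage only
  res <- calibrate_geometry(meas, cfg$base, cfg$phantom,
                            schedule = sched,
                            config = calib_config(max_outer = 1,
                                                  accelerate = FALSE))
  # the 5-degree scan grid plus a 2-parameter refinement under otherwise
  # misaligned conditions localizes the yaw to within ~2 grid steps
  expect_lt(abs(res$beta$values["phi_o"] - 187), 10)
})

test_that("staged calibration recovers the ground truth from a blind start", {
  res <- calibrate_geometry(meas, cfg$base, cfg$phantom)
  expect_true(res$converged)
  err <- res$beta$values - cfg$beta_true$values
  expect_lt(max(abs(err[ORIENTATION_PARAMS])), 0.1)
  expect_lt(max(abs(err[NONOPTICAL_TRANSLATIONS])), 0.170)
  expect_lt(res$cost, 1e-6 * res$outer_costs[1])

  # outer-loop cost trace never increases
  expect_true(all(diff(res$outer_costs) <= 1e-12))

  # gauge freedom: a full turn added to the yaw is the same optimum
  shifted <- res$beta
  shifted$values["phi_o"] <- shifted$values["phi_o"] + 360
  expect_equal(calib_cost(shifted, meas, cfg$base, cfg$phantom),
               calib_cost(res$beta, meas, cfg$base, cfg$phantom),
               tolerance = 1e-9)
})

test_that("compensated optical-axis perturbations barely move the cost", {
  # the (dsod_i, dx_id) pair is near-degenerate: shifting the source by
  # delta and the detector along the axis by delta*sdd/sod preserves the
  # magnification
  eps <- 0.5
  fn <- function(v) calib_cost(v, meas, cfg$base, cfg$phantom,
                               systems = 1L)
  v0 <- cfg$beta_true$values
  v_sod <- v0; v_sod["dsod_1"] <- v_sod["dsod_1"] - eps
  v_dx <- v0; v_dx["dx_1d"] <- v_dx["dx_1d"] - eps * 1123 / 779
  v_both <- v_sod; v_both["dx_1d"] <- v_dx["dx_1d"]
  expect_gt(fn(v_sod) / fn(v_both), 10)
  expect_gt(fn(v_dx) / fn(v_both), 10)
})

test_that("the flattest directions of the cost are the optical translations", {
  # numerical Hessian of the smooth (L2) cost at the optimum; its two
  # smallest eigenvectors must live in the (dx_id, dsod_i) subspace
  cfg9 <- sim_study_config(n_angles = 9)
  t9 <- project_all(apply_beta(cfg9$base, cfg9$beta_true),
                    cfg9$phantom, cfg9$angles)
  m9 <- measurements_from_truth(t9)
  fn <- function(v) calib_cost(v, m9, cfg9$base, cfg9$phantom,
                               variant = "l2")
  v0 <- cfg9$beta_true$values
  n <- length(v0)
  h <- ifelse(grepl("theta|phi|eta|alpha", names(v0)), 1e-3, 1e-2)
  f0 <- fn(v0)
  H <- matrix(0, n, n)
  fi <- numeric(n)
  for (i in 1:n) {
    vi <- v0; vi[i] <- vi[i] + h[i]; fi[i] <- fn(vi)
  }
  for (i in 1:n) for (j in i:n) {
    vij <- v0; vij[i] <- vij[i] + h[i]; vij[j] <- vij[j] + h[j]
    H[i, j] <- H[j, i] <- (fn(vij) - fi[i] - fi[j] + f0) / (h[i] * h[j])
  }
  e <- eigen(H, symmetric = TRUE)
  soft <- names(v0) %in% c("dx_1d", "dsod_1", "dx_2d", "dsod_2")
  for (k in c(n, n - 1))
    expect_gt(sum(e$vectors[soft, k]^2), 0.9)
})

test_that("orientations stay within 0.1 degree under 0.1 px center noise", {
  # 0.1 px Gaussian noise on the measured centers at the study conditions
  # (61 angles, 142 um pixels), five fixed seeds
  cfg61 <- sim_study_config()
  t61 <- project_all(apply_beta(cfg61$base, cfg61$beta_true),
                     cfg61$phantom, cfg61$angles)
  m61 <- measurements_from_truth(t61)
  sigma <- 0.1 * 0.142
  gtv <- cfg61$beta_true$values
  for (s in 1:5) {
    set.seed(s)
    mn <- m61
    mn$u_mm <- mn$u_mm + stats::rnorm(nrow(mn), 0, sigma)
    mn$v_mm <- mn$v_mm + stats::rnorm(nrow(mn), 0, sigma)
    res <- calibrate_geometry(mn, cfg61$base, cfg61$phantom)
    err <- res$beta$values - gtv
    expect_lt(max(abs(err[ORIENTATION_PARAMS])), 0.1)
  }
})

test_that("masked-SOD calibration absorbs magnification into the detector shift", {
  res <- calibrate_geometry(
    meas, cfg$base, cfg$phantom,
    beta_init = parameter_vector(fixed = c("dsod_1", "dsod_2")))
  expect_true(res$converged)
  expect_equal(res$n_free, 19)
  expect_lt(res$cost, 1e-3 * res$outer_costs[1])
  gtv <- cfg$beta_true$values
  # expected compensation: dx that keeps (sdd+dx)/(sod+dsod) fixed at dsod=0
  pred1 <- (1123 + gtv["dx_1d"]) * 779 / (779 + gtv["dsod_1"]) - 1123
  pred2 <- (1141 + gtv["dx_2d"]) * 783 / (783 + gtv["dsod_2"]) - 1141
  expect_lt(abs(res$beta$values["dx_1d"] - pred1), 1)
  expect_lt(abs(res$beta$values["dx_2d"] - pred2), 1)
  err <- res$beta$values - gtv
  expect_lt(max(abs(err[ORIENTATION_PARAMS])), 0.1)
})
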