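test_that("rotation_from_angles composes Rz(eta) Ry(phi) Rx(theta) and stays orthonormal", {
  expect_equal(rotation_from_angles(0, 0, 0), diag(3))
  expect_all_close(rotation_from_angles(90, 0, 0) %*% c(0, 1, 0),
                   c(0, 0, 1), 1e-12)

  # independent oracle: explicit single-axis matrices multiplied by hand
  single <- function(theta, phi, eta) {
    r <- pi / 180
    Rx <- rbind(c(1, 0, 0),
                c(0, cos(theta * r), -sin(theta * r)),
                c(0, sin(theta * r), cos(theta * r)))
    Ry <- rbind(c(cos(phi * r), 0, sin(phi * r)),
                c(0, 1, 0),
                c(-sin(phi * r), 0, cos(phi * r)))
    Rz <- rbind(c(cos(eta * r), -sin(eta * r), 0),
                c(sin(eta * r), cos(eta * r), 0),
                c(0, 0, 1))
    Rz %*% Ry %*% Rx
  }
  expect_all_close(rotation_from_angles(10, 20, 30), single(10, 20, 30),
                   1e-12)

  set.seed(7)
  for (i in 1:20) {
    a <- stats::runif(3, -360, 360)
    R <- rotation_from_angles(a[1], a[2], a[3])
    expect_all_close(crossprod(R), diag(3), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
})

test_that("marker_world_position applies pose then stage rotation about +y", {
  zero <- rigid_pose()
  expect_equal(marker_world_position(zero, 0, c(1, 2, 3)), c(1, 2, 3))
  expect_all_close(marker_world_position(zero, 180, c(0, 0, 5)),
                   c(0, 0, -5), 1e-12)
  # a point on the rotation axis is invariant to the stage angle
  p <- rigid_pose(dy = 10)
  for (a in c(0, 37, 180, 271))
    expect_all_close(marker_world_position(p, a, c(0, 0, 0)),
                     c(0, 10, 0), 1e-12)
})

test_that("pair_frame places source and detector per the distance convention", {
  fr <- pair_frame(aligned_pair1())
  expect_equal(fr$source, c(-779, 0, 0))
  expect_equal(fr$det_center, c(344, 0, 0))
  expect_equal(fr$e_u, c(0, 0, 1))
  expect_equal(fr$e_v, c(0, 1, 0))

  fr90 <- pair_frame(aligned_pair1(), system_rotation = 90)
  expect_equal(sqrt(sum(fr90$source^2)), 779, tolerance = 1e-12)
  expect_all_close(fr90$source, c(0, 0, 779), 1e-9)

  frd <- pair_frame(aligned_pair1(dsod = 10))
  expect_equal(sqrt(sum(frd$source^2)), 789, tolerance = 1e-12)
  # detector keeps the measured SDD from the source
  expect_equal(sqrt(sum((frd$det_center - frd$source)^2)), 1123,
               tolerance = 1e-12)
})

test_that("project_point obeys the cone-beam magnification law", {
  fr <- pair_frame(aligned_pair1())
  p0 <- project_point(fr, c(0, 0, 0))
  expect_equal(c(p0$u_mm, p0$v_mm), c(0, 0))

  pv <- project_point(fr, c(0, 10, 0))
  expect_equal(pv$v_mm, 10 * 1123 / 779, tolerance = 1e-12)
  expect_equal(pv$u_mm, 0)

  pu <- project_point(fr, c(0, 0, 5))
  expect_equal(pu$u_mm, 5 * 1123 / 779, tolerance = 1e-12)

  # magnification closed form at random heights
  set.seed(11)
  for (h in stats::runif(5, -60, 60)) {
    p <- project_point(fr, c(0, h, 0))
    expect_equal(p$v_mm, h * 1123 / 779, tolerance = 1e-12)
  }

  # point behind the source is a degenerate ray, flagged not thrown
  pb <- project_point(fr, c(-1000, 0, 0))
  expect_false(pb$valid)
  expect_false(pb$in_fov)
})

test_that("project_all yields one record per system, angle and marker", {
  geom <- aligned_geometry()
  ph <- default_phantom()
  angles <- (0:60) * (360 / 61)
  tab <- project_all(geom, ph, angles)
  expect_equal(nrow(tab), 61 * 2 * 5)
  expect_equal(as.integer(table(tab$system)), c(305L, 305L))

  # marker at the rotation center projects to the principal point always
  ph1 <- one_marker_phantom()
  g <- stereo_geometry(aligned_pair1(), aligned_pair1(), alpha = 90,
                       phantom_pose = pose_centering(ph1))
  t1 <- project_all(g, ph1, angles)
  expect_all_close(t1$u_mm, 0, 1e-9)
  expect_all_close(t1$v_mm, 0, 1e-9)
})

test_that("reference table is periodic in the phantom yaw", {
  ph <- default_phantom()
  base <- base_geometry(779, 1123, 783, 1141)
  g1 <- apply_beta(base, parameter_vector(c(phi_o = 20, dy_o = 3)))
  g2 <- apply_beta(base, parameter_vector(c(phi_o = 380, dy_o = 3)))
  angles <- seq(0, 300, by = 60)
  t1 <- project_all(g1, ph, angles)
  t2 <- project_all(g2, ph, angles)
  expect_all_close(t1$u_mm, t2$u_mm, 1e-12)
  expect_all_close(t1$v_mm, t2$v_mm, 1e-12)
})

test_that("yaw offset and opposite stage-angle shift cancel", {
  # holds for poses whose only out-of-yaw content commutes with the
  # rotation axis: pitch 0, translation along y
  ph <- default_phantom()
  base <- base_geometry(779, 1123, 783, 1141)
  delta <- 17
  g1 <- apply_beta(base, parameter_vector(c(phi_o = 50, theta_o = 3,
                                            dy_o = 8)))
  g2 <- apply_beta(base, parameter_vector(c(phi_o = 50 + delta,
                                            theta_o = 3, dy_o = 8)))
  angles <- seq(0, 300, by = 60)
  t1 <- project_all(g1, ph, angles)
  t2 <- project_all(g2, ph, angles - delta)
  expect_all_close(t1$u_mm, t2$u_mm, 1e-9)
  expect_all_close(t1$v_mm, t2$v_mm, 1e-9)
})

test_that("merge_stereo_angles reproduces pair-2 projections as shifted pair-1 views", {
  base <- base_geometry(779, 1123, 783, 1141)
  beta <- parameter_vector(c(alpha = 94.1, dx_2d = -10.2, theta_2d = 4.24,
                             dy_1d = -18.5))
  geom <- apply_beta(base, beta)
  angles <- seq(0, 330, by = 30)
  N <- length(angles)
  views <- merge_stereo_angles(geom, angles)
  expect_length(views, 2 * N)
  expect_equal(views[[N + 3]]$angle_deg, angles[3] + 94.1)

  fr2 <- pair_frame(geom$pair2, geom$alpha)
  p <- c(12, -7, 4)  # static point in the sample frame
  for (k in c(1, 5, 12)) {
    direct <- project_point(fr2,
                            as.numeric(stereocal:::stage_rotation(angles[k]) %*% p))
    merged <- project_point(views[[N + k]], p)
    expect_all_close(c(merged$u_mm, merged$v_mm),
                     c(direct$u_mm, direct$v_mm), 1e-9)
  }
})

test_that("cone-vector export is consistent with the projector", {
  geom <- aligned_geometry()
  views <- merge_stereo_angles(geom, c(0, 90))
  tab <- export_cone_vectors(views)
  expect_equal(unlist(tab[1, 1:6], use.names = FALSE),
               c(-779, 0, 0, 344, 0, 0))
  expect_all_close(sqrt(rowSums(tab[, 7:9]^2)), 0.142, 1e-12)
  expect_all_close(sqrt(rowSums(tab[, 10:12]^2)), 0.142, 1e-12)

  # round-trip: reproject a point from the exported row alone
  base <- base_geometry(779, 1123, 783, 1141)
  geom2 <- apply_beta(base, parameter_vector(c(dx_1d = 5, theta_1d = 3,
                                               phi_1d = -2, dy_o = 4)))
  views2 <- merge_stereo_angles(geom2, c(40))
  row <- as.numeric(export_cone_vectors(views2)[1, ])
  src <- row[1:3]; det <- row[4:6]
  eu <- row[7:9] / sqrt(sum(row[7:9]^2))
  ev <- row[10:12] / sqrt(sum(row[10:12]^2))
  nrm <- c(eu[2] * ev[3] - eu[3] * ev[2],
           eu[3] * ev[1] - eu[1] * ev[3],
           eu[1] * ev[2] - eu[2] * ev[1])
  p <- c(9, -13, 6)
  tt <- sum((det - src) * nrm) / sum((p - src) * nrm)
  hit <- src + tt * (p - src)
  ref <- project_point(views2[[1]], p)
  expect_all_close(c(sum((hit - det) * eu), sum((hit - det) * ev)),
                   c(ref$u_mm, ref$v_mm), 1e-9)
})
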