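test_that("flatfield/log correction has its closed forms and is monotone", {
  flat <- matrix(4000, 8, 8)
  dark <- matrix(100, 8, 8)
  expect_equal(flatfield_log_correct(flat, flat), matrix(0, 8, 8))
  expect_all_close(flatfield_log_correct(flat * exp(-1), flat),
                   matrix(1, 8, 8), 1e-12)
  raw <- dark + (flat - dark) * exp(-2)
  expect_all_close(flatfield_log_correct(raw, flat, dark),
                   matrix(2, 8, 8), 1e-12)

  expect_error(flatfield_log_correct(matrix(1, 4, 4), flat), "shape")
  expect_error(flatfield_log_correct(flat, dark, flat), "exceed")

  # monotone decreasing in the raw intensity
  r1 <- flatfield_log_correct(matrix(1000, 8, 8), flat)
  r2 <- flatfield_log_correct(matrix(2000, 8, 8), flat)
  expect_true(all(r1 > r2))
})

test_that("template matching finds isolated beads and nothing in flat images", {
  s <- small_image_setup(misaligned = FALSE)
  ph1 <- one_marker_phantom()
  geom <- stereo_geometry(s$geom$pair1, s$geom$pair2, alpha = 90,
                          phantom_pose = pose_centering(ph1))
  ds <- simulate_dataset(geom, ph1, 0, render_options())
  cor <- flatfield_log_correct(ds$images[[1]][[1]], ds$flatfield[[1]])
  tr <- 2.475 * (1123 / 779) / 0.6
  cand <- find_candidates(cor, tr)
  expect_equal(nrow(cand), 1)
  expect_lt(sqrt((cand$col - ds$truth$u_px[1])^2 +
                   (cand$row - ds$truth$v_px[1])^2), 1)

  expect_equal(nrow(find_candidates(matrix(5, 128, 128), tr)), 0)

  # two beads five template radii apart -> exactly two candidates
  t2 <- bead_template(6)
  img <- matrix(0, 160, 160)
  put <- function(img, r0, c0) {
    h <- (nrow(t2) - 1) / 2
    img[(r0 - h):(r0 + h), (c0 - h):(c0 + h)] <-
      img[(r0 - h):(r0 + h), (c0 - h):(c0 + h)] + t2
    img
  }
  img <- put(img, 60, 60)
  img <- put(img, 60, 90)  # 30 px = 5 template radii
  cand2 <- find_candidates(img, 6)
  expect_equal(nrow(cand2), 2)
})

test_that("centroid refinement reaches sub-pixel accuracy on rendered beads", {
  # exactly symmetric synthetic disk at an integer pixel
  t2 <- bead_template(5)
  img <- matrix(0, 64, 64)
  h <- (nrow(t2) - 1) / 2
  img[(40 - h):(40 + h), (25 - h):(25 + h)] <- t2
  ref <- refine_center(img, col = 24, row = 39, window_radius = 9)
  expect_true(ref$valid)
  expect_equal(ref$col, 24)  # 0-based
  expect_equal(ref$row, 39)

  # rendered bead with a fractional-pixel truth center
  s <- small_image_setup()
  ds <- simulate_dataset(s$geom, s$phantom, 25, render_options())
  cor <- flatfield_log_correct(ds$images[[1]][[1]], ds$flatfield[[1]])
  tru <- ds$truth[ds$truth$system == 1, ]
  for (k in seq_len(nrow(tru))) {
    r <- refine_center(cor, tru$u_px[k], tru$v_px[k], 8)
    expect_true(r$valid)
    expect_lt(sqrt((r$col - tru$u_px[k])^2 + (r$row - tru$v_px[k])^2), 0.1)
  }

  # constant window: no signal above background
  expect_false(refine_center(matrix(7, 40, 40), 20, 20, 5)$valid)
  # window clipped by the image edge
  expect_false(refine_center(cor, 2, 2, 8)$valid)
})

test_that("correspondence assignment is optimal, gated and permutation-invariant", {
  s <- small_image_setup(misaligned = FALSE)
  pred <- project_all(s$geom, s$phantom, c(0, 60))
  spec <- s$geom$pair1$detector_spec
  p1 <- pred[pred$system == 1 & pred$angle_index == 0, ]
  px <- mm_to_px(p1$u_mm, p1$v_mm, spec)
  cand <- data.frame(system = 1L, angle_index = 0L, angle_deg = 0,
                     col = px$col, row = px$row, score = 1)
  m <- match_correspondences(cand, pred[pred$angle_index == 0, ],
                             spec, spec, gate_px = 20)
  m1 <- m[m$system == 1 & m$valid, ]
  expect_equal(nrow(m1), 5)
  expect_all_close(m1$u_mm, p1$u_mm, 1e-9)

  # shuffling candidates never changes the assignment
  set.seed(3)
  cand_sh <- cand[sample(nrow(cand)), ]
  m_sh <- match_correspondences(cand_sh, pred[pred$angle_index == 0, ],
                                spec, spec, gate_px = 20)
  expect_equal(m_sh$u_mm, m$u_mm)
  expect_equal(m_sh$valid, m$valid)

  # a marker without a nearby candidate stays invalid
  m4 <- match_correspondences(cand[-2, ], pred[pred$angle_index == 0, ],
                              spec, spec, gate_px = 20)
  m41 <- m4[m4$system == 1, ]
  expect_equal(sum(m41$valid), 4)
  expect_false(m41$valid[m41$marker_id == p1$marker_id[2]])

  # near-overlapping predictions are ambiguous: both dropped in that view
  pred_ov <- p1
  pred_ov$u_mm[2] <- pred_ov$u_mm[1] + 0.5 * spec$pixel_size
  pred_ov$v_mm[2] <- pred_ov$v_mm[1]
  mo <- match_correspondences(cand, pred_ov, spec, spec, gate_px = 20)
  expect_false(any(mo$valid[mo$marker_id %in% p1$marker_id[1:2]]))
  expect_equal(sum(mo$valid), 3)
})

test_that("detection closes the loop on noiseless renders below 0.1 px RMS", {
  s <- small_image_setup()
  ds <- simulate_dataset(s$geom, s$phantom, s$angles, render_options())
  meas <- detect_dataset(ds, s$geom, s$phantom)
  j <- merge(meas[meas$valid, ], ds$truth,
             by = c("system", "angle_index", "marker_id"))
  expect_gte(nrow(j), 0.9 * sum(ds$truth$in_fov))
  rms <- sqrt(mean((j$u_px.x - j$u_px.y)^2 + (j$v_px.x - j$v_px.y)^2))
  expect_lt(rms, 0.1)
})
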