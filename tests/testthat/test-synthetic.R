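test_that("a motionless scenario produces zero observations and constant truth", {
  scn <- synthetic_scenario(nx = 12, ny = 12, max_depth = 0, sigma_n = 0,
                            p_out = 0, occluder_width = 0, n_frames = 3,
                            vacancy_margin = 0)
  sq <- generate_sequence(scn, seed = 4)
  for (t in 1:3) {
    expect_equal(sq$truth[[t + 1]]$vertices, sq$mesh0$vertices)
    expect_true(all(sq$frames[[t]]$flow$vectors == 0))
    expect_true(all(sq$frames[[t]]$flow$status == "valid"))
  }
})

test_that("the indentation displaces the center vertex by the step depth", {
  scn <- synthetic_scenario(nx = 11, ny = 11, sigma_n = 0, p_out = 0,
                            occluder_width = 0, max_depth = 10, n_frames = 10,
                            vacancy_margin = 0)
  sq <- generate_sequence(scn, seed = 4)
  center <- which(sq$mesh0$vertices[, 1] == 0 & sq$mesh0$vertices[, 2] == 0)
  expect_length(center, 1)
  # per-step depth 1 mm at the Gaussian peak, pressing away from the camera
  expect_equal(sq$frames[[1]]$flow$vectors[center, ], c(0, 0, 1),
               tolerance = 1e-12)
  expect_equal(sq$truth[[11]]$vertices[center, 3], scn$z0 + 10)
})

test_that("outlier injection follows the seeded draw at the configured rate", {
  scn <- synthetic_scenario(nx = 100, ny = 100, occluder_width = 0,
                            vacancy_margin = 0, n_frames = 1)
  sq <- generate_sequence(scn, seed = 123)
  n_out <- length(sq$corruption[[1]]$outliers)
  # binomial(10000, 0.1): within 3 sigma of the mean
  expect_gt(n_out, 10000 * 0.1 - 3 * sqrt(10000 * 0.1 * 0.9))
  expect_lt(n_out, 10000 * 0.1 + 3 * sqrt(10000 * 0.1 * 0.9))
  # replaying the seed reproduces the identical draw
  sq2 <- generate_sequence(scn, seed = 123)
  expect_identical(sq2$corruption[[1]]$outliers, sq$corruption[[1]]$outliers)
  # outlier vectors have the configured magnitude
  mag <- sqrt(rowSums(sq$frames[[1]]$flow$vectors[
    sq$corruption[[1]]$outliers, , drop = FALSE]^2))
  expect_equal(mag, rep(scn$m_out, n_out), tolerance = 1e-9)
})

test_that("generation is bit-reproducible for a fixed seed", {
  sq1 <- generate_sequence(synthetic_scenario(), seed = 42)
  sq2 <- generate_sequence(synthetic_scenario(), seed = 42)
  expect_identical(sq1$frames, sq2$frames)
  expect_identical(sq1$truth, sq2$truth)
  sq3 <- generate_sequence(synthetic_scenario(), seed = 43)
  expect_false(identical(sq1$frames, sq3$frames))
})

test_that("the occluder stays strictly nearer the camera than the surface", {
  sq <- default_sequence()
  for (t in seq_along(sq$frames)) {
    pts <- sq$frames[[t]]$instrument_points
    occ <- sq$corruption[[t]]$occluded
    expect_lt(max(pts[, 3]), min(sq$truth[[t + 1]]$vertices[occ, 3]))
    # contaminated vectors copy the rod's motion
    expect_true(all(sq$frames[[t]]$flow$vectors[occ, 1] ==
                      sq$scenario$occluder_motion[1]))
  }
  # rod covers roughly a tenth of the surface
  cover <- length(sq$corruption[[1]]$occluded) / nrow(sq$mesh0$vertices)
  expect_gt(cover, 0.05)
  expect_lt(cover, 0.15)
})

test_that("ground truth satisfies the smooth-field hypothesis away from corruption", {
  scn <- synthetic_scenario(sigma_n = 0, p_out = 0, occluder_width = 0,
                            vacancy_margin = 0)
  sq <- generate_sequence(scn, seed = 8)
  filt <- filter_scene_flow(sq$mesh0, sq$frames[[1]]$flow)
  rep <- attr(filt, "report")
  determined <- !rep$undetermined
  expect_lt(max(rep$score[determined], na.rm = TRUE), 0.5)
})

test_that("rendered observations have the analytic disparity and flow", {
  scn <- synthetic_scenario(nx = 20, ny = 20, spacing = 2, max_depth = 0,
                            occluder_width = 0, n_frames = 2)
  obs <- render_observations(scn, t = 0, quant_steps = Inf)
  d_expect <- scn$calib$f * scn$calib$b / scn$z0
  mid <- obs$disparity_t[200, 200]
  expect_equal(mid, d_expect, tolerance = 1e-9)
  # motionless: zero flow on the surface
  expect_true(all(abs(obs$flow_uv[!is.na(obs$flow_uv)]) < 1e-9))
  # deforming scenario: flow at a projected vertex matches the projected step
  scn2 <- synthetic_scenario(nx = 20, ny = 20, spacing = 2, occluder_width = 0)
  sq2 <- generate_sequence(scn2, seed = 2)
  obs2 <- render_observations(scn2, t = 0, quant_steps = Inf)
  v <- sq2$mesh0$vertices[190, ]
  p0 <- project_points(matrix(v, 1), scn2$calib)
  v1 <- sq2$truth[[2]]$vertices[190, ]
  p1 <- project_points(matrix(v1, 1), scn2$calib)
  fu <- bilinear_sample(obs2$flow_uv[, , 1], p0[1], p0[2])
  fv <- bilinear_sample(obs2$flow_uv[, , 2], p0[1], p0[2])
  expect_equal(c(fu, fv), c(p1[1] - p0[1], p1[2] - p0[2]), tolerance = 1e-3)
  # frustum check
  scn3 <- synthetic_scenario(nx = 300, ny = 300, spacing = 2)
  expect_error(render_observations(scn3), "frustum")
})

test_that("scenario validation rejects non-physical parameters", {
  expect_error(synthetic_scenario(sigma = 0), "sigma")
  expect_error(synthetic_scenario(spacing = -1), "spacing")
  expect_error(synthetic_scenario(p_out = 1.5), "p_out")
})
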