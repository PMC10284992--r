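test_that("dynamic term selects valid vertices with flow-updated targets", {
  C_p <- grid_mesh(3, 3, spacing = 1, z = 10)$vertices[1:3, ]
  C_p <- rbind(C_p, c(5, 5, 5))  # give it 4 rows? keep simple with 3
  C_p <- C_p[1:3, ]
  fl <- scene_flow(matrix(0, 3, 3))
  dyn <- build_dynamic_term(C_p, fl)
  expect_equal(as.matrix(dyn$I_tilde), diag(3))
  expect_equal(dyn$C_star, C_p)
  # valid set {1, 3} of N = 3
  fl2 <- scene_flow(matrix(1, 3, 3), c("valid", "vacant", "valid"))
  dyn2 <- build_dynamic_term(C_p, fl2)
  expect_equal(as.matrix(dyn2$I_tilde), rbind(c(1, 0, 0), c(0, 0, 1)))
  expect_equal(dyn2$C_star, C_p[c(1, 3), ] + 1)
  # random valid sets vs elementwise oracle
  for (s in 1:20) {
    set.seed(s)
    n <- 20L
    C <- matrix(rnorm(60), n, 3)
    vec <- matrix(rnorm(60), n, 3)
    st <- sample(c("valid", "vacant", "strain_outlier"), n, replace = TRUE,
                 prob = c(0.6, 0.2, 0.2))
    if (!any(st == "valid")) st[1] <- "valid"
    dyn3 <- build_dynamic_term(C, scene_flow(vec, st))
    v <- which(st == "valid")
    expect_equal(dyn3$C_star, C[v, , drop = FALSE] + vec[v, , drop = FALSE])
  }
  expect_error(build_dynamic_term(C_p, scene_flow(matrix(0, 3, 3),
                                                  rep("vacant", 3))),
               "no valid")
})

test_that("uniform translation is recovered exactly", {
  m <- grid_mesh(9, 9, spacing = 1, z = 100)
  tvec <- c(1.5, -2, 4)
  fl <- scene_flow(matrix(tvec, nrow(m$vertices), 3, byrow = TRUE))
  dyn <- build_dynamic_term(m$vertices, fl)
  esys <- smoothness_system(m, alpha = 1.5)
  C <- solve_frame(dyn, esys, m$vertices)
  expect_lt(max(abs(C - sweep(m$vertices, 2, tvec, "+"))), 1e-8)
})

test_that("solutions match the exhaustive dense bounded-LS oracle", {
  for (s in 1:50) {
    set.seed(s)
    nx <- sample(3:5, 1); ny <- sample(3:5, 1)
    m <- grid_mesh(nx, ny, spacing = 1, z = 100)
    n <- nrow(m$vertices)
    st <- ifelse(runif(n) < 0.7, "valid", "vacant")
    if (!any(st == "valid")) st[1] <- "valid"
    vec <- matrix(rnorm(3 * n, 0, 0.5), n, 3)
    fl <- scene_flow(vec, st)
    dyn <- build_dynamic_term(m$vertices, fl)
    alpha <- runif(1, 1, 2)
    esys <- smoothness_system(m, alpha = alpha)
    # random occluded subset with bounds near (often above) the unconstrained z
    k <- sample(1:5, 1)
    occ <- sample(n, k)
    pz <- m$vertices[occ, 3] + runif(k, -0.3, 0.6)
    oc <- occlusion_constraints(occ, pz)
    C <- solve_frame(dyn, esys, m$vertices, constraints = oc)
    # all bounds satisfied
    expect_true(all(C[occ, 3] >= pz - 1e-9))
    # dense oracle per column
    A <- as.matrix(rbind(dyn$I_tilde, alpha * esys$S))
    for (col in 1:3) {
      b <- c(dyn$C_star[, col], alpha * esys$delta[, col])
      xo <- if (col == 3) {
        oracle_bounded_ls(A, b, occ, pz)
      } else {
        qr.coef(qr(A), b)
      }
      expect_lt(max(abs(C[, col] - xo)), 1e-6)
    }
  }
})

test_that("coordinates are separable when no bound is active", {
  set.seed(99)
  m <- grid_mesh(5, 5, spacing = 1, z = 100)
  n <- nrow(m$vertices)
  fl <- scene_flow(matrix(rnorm(3 * n, 0, 0.3), n, 3))
  dyn <- build_dynamic_term(m$vertices, fl)
  esys <- smoothness_system(m, alpha = 1.2)
  # far-below bounds: never active
  oc <- occlusion_constraints(1:5, rep(0, 5))
  C_con <- solve_frame(dyn, esys, m$vertices, constraints = oc)
  C_unc <- solve_frame(dyn, esys, m$vertices)
  expect_lt(max(abs(C_con - C_unc)), 1e-10)
})

test_that("active bounds are met with equality and clamp the z solve", {
  set.seed(7)
  m <- grid_mesh(5, 5, spacing = 1, z = 100)
  n <- nrow(m$vertices)
  fl <- scene_flow(matrix(0, n, 3))
  dyn <- build_dynamic_term(m$vertices, fl)
  esys <- smoothness_system(m, alpha = 1.5)
  occ <- c(7L, 13L)
  pz <- c(100.5, 100.8)  # above the unconstrained solution z = 100
  C <- solve_frame(dyn, esys, m$vertices,
                   constraints = occlusion_constraints(occ, pz))
  expect_equal(C[occ, 3], pz, tolerance = 1e-8)
  expect_true(all(C[, 3] >= 100 - 1e-9))
})

test_that("dynamic and smoothness residuals trade off monotonically in alpha", {
  sq <- default_sequence()
  fr <- sq$frames[[3]]
  filt <- filter_scene_flow(sq$mesh0, fr$flow, instrument = fr$instrument)
  dyn <- build_dynamic_term(sq$mesh0$vertices, filt)
  alphas <- c(1, 1.25, 1.5, 1.75, 2)
  rd <- rs <- numeric(length(alphas))
  for (i in seq_along(alphas)) {
    esys <- smoothness_system(sq$mesh0, alpha = alphas[i])
    C <- solve_frame(dyn, esys, sq$mesh0$vertices)
    rd[i] <- attr(C, "residual_dynamic")
    rs[i] <- attr(C, "residual_smooth")
  }
  expect_true(all(diff(rd) > 0))
  expect_true(all(diff(rs) < 0))
})

test_that("components without valid vertices are frozen, not extrapolated", {
  # two disjoint patches: second patch all vacant
  f <- rbind(c(1, 2, 3), c(2, 3, 4), c(5, 6, 7), c(6, 7, 8))
  v <- rbind(c(0, 0, 10), c(1, 0, 10), c(0, 1, 10), c(1, 1, 10),
             c(5, 5, 20), c(6, 5, 20), c(5, 6, 20), c(6, 6, 20))
  m <- suppressMessages(triangle_mesh(v, f))
  st <- c(rep("valid", 4), rep("vacant", 4))
  fl <- scene_flow(matrix(rep(c(0, 0, 1), each = 8), 8, 3), st)
  dyn <- build_dynamic_term(m$vertices, fl)
  esys <- smoothness_system(m, alpha = 1.5)
  C <- solve_frame(dyn, esys, m$vertices)
  expect_equal(attr(C, "frozen"), 5:8)
  expect_equal(C[5:8, ], v[5:8, ], ignore_attr = TRUE)
  expect_lt(max(abs(C[1:4, ] - sweep(v[1:4, ], 2, c(0, 0, 1), "+"))), 1e-8)
})

test_that("a zero-flow sequence leaves the mesh unchanged", {
  m <- grid_mesh(8, 8, spacing = 1, z = 100)
  n <- nrow(m$vertices)
  frames <- replicate(5, list(flow = scene_flow(matrix(0, n, 3))),
                      simplify = FALSE)
  rec <- run_sequence(m, frames,
                      config = recover_config(filter = FALSE))
  for (t in 1:5) {
    expect_lt(max(abs(rec$meshes[[t + 1]]$vertices - m$vertices)), 1e-8)
  }
})

test_that("noise-free indentation is tracked to the alpha-limited bias", {
  scn <- synthetic_scenario(nx = 24, ny = 24, sigma = 5, sigma_n = 0,
                            p_out = 0, occluder_width = 0,
                            vacancy_margin = 0, n_frames = 5)
  sq <- generate_sequence(scn, seed = 1)
  errs <- sapply(c(0.25, 0.5, 1.5), function(a) {
    rec <- run_sequence(sq$mesh0, sq$frames,
                        config = recover_config(filter = FALSE, alpha = a))
    mean_vertex_error(rec$meshes[[6]], sq$truth[[6]])
  })
  # dynamic term is exact; residual error is the smoothness shrinkage toward
  # the initial shape, which grows with alpha and stays far below the 5 mm
  # indentation depth
  expect_true(all(diff(errs) > 0))
  expect_lt(errs[1], 0.05)
  expect_lt(errs[3], 0.15 * scn$max_depth)
})

test_that("a failing frame is skipped with carry-forward", {
  m <- grid_mesh(5, 5, spacing = 1, z = 100)
  n <- nrow(m$vertices)
  good <- list(flow = scene_flow(matrix(0, n, 3)))
  bad <- list(flow = scene_flow(matrix(0, n, 3), rep("vacant", n)))
  expect_warning(
    rec <- run_sequence(m, list(good, bad, good),
                        config = recover_config(filter = FALSE)),
    "skipped"
  )
  lg <- tidy(rec)
  expect_true(lg$skipped[2])
  expect_equal(rec$meshes[[3]]$vertices, rec$meshes[[2]]$vertices)
  expect_equal(glance(rec)$n_skipped, 1L)
})

test_that("occluded vertices satisfy their depth bounds at every frame", {
  sq <- default_sequence()
  rec <- default_recovery()
  for (t in seq_along(sq$frames)) {
    fr <- sq$frames[[t]]
    occ <- detect_occluded_vertices(rec$meshes[[t]], fr$instrument$mask,
                                    sq$calib)
    if (length(occ) == 0) next
    oc <- compute_depth_bounds(occ, fr$instrument_points,
                               rec$meshes[[t]]$vertices)
    expect_true(all(rec$meshes[[t + 1]]$vertices[oc$occluded, 3] >=
                      oc$p_z - 1e-9))
  }
})
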