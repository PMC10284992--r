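# random non-coplanar neighborhood with an affine displacement field
random_affine_case <- function(seed, n = 15L) {
  set.seed(seed)
  X <- matrix(runif(3 * n, -2, 2), n, 3)
  G <- matrix(runif(9, -0.5, 0.5), 3, 3)
  b <- runif(3, -1, 1)
  Y <- X %*% t(G) + matrix(b, n, 3, byrow = TRUE)
  list(X = X, Y = Y, G = G)
}

# wrap a point set as a star mesh so the filter machinery can run on it:
# vertex 1 connected to all others through a fan of faces
star_mesh <- function(X) {
  n <- nrow(X)
  faces <- cbind(1L, 2:(n - 1L), 3:n)
  triangle_mesh(X, faces)
}

test_that("VWLS recovers affine displacement fields to machine precision", {
  cfg <- filter_config(ring = 1)
  for (s in 1:200) {
    cs <- random_affine_case(s)
    mesh <- star_mesh(cs$X)
    flow <- scene_flow(cs$Y)
    fit <- estimate_gradient_vwls(mesh, flow, vertex = 1L, config = cfg)
    expect_false(is.null(fit))
    expect_equal(fit$G, cs$G, tolerance = 1e-9)
    expect_lt(max(abs(fit$resid)), 1e-9)
  }
})

test_that("uniform translation gives an exactly zero gradient", {
  mesh <- grid_mesh(7, 7, spacing = 1, z = c(100 + rnorm(49, 0, 0.5)))
  flow <- scene_flow(matrix(rep(c(3, -2, 7), each = 49), 49, 3))
  fit <- estimate_gradient_vwls(mesh, flow, vertex = 25L)
  expect_lt(max(abs(fit$G)), 1e-12)
  expect_lt(max(abs(fit$resid)), 1e-12)
})

test_that("degenerate neighborhoods are reported as undetermined", {
  # collinear points: less than two directions of spread
  X <- cbind(seq_len(8), 0, 0)
  mesh <- star_mesh(X)
  flow <- scene_flow(matrix(rnorm(24), 8, 3))
  expect_null(estimate_gradient_vwls(mesh, flow, vertex = 1L,
                                     config = filter_config(min_neighbors = 3)))
  # too few usable neighbors
  cs <- random_affine_case(1, n = 5L)
  expect_null(estimate_gradient_vwls(star_mesh(cs$X), scene_flow(cs$Y), 1L,
                                     config = filter_config(min_neighbors = 6)))
})

test_that("strain tensor is the symmetric gradient with analytic eigenvalues", {
  z <- strain_from_gradient(matrix(0, 3, 3))
  expect_equal(z$eps_max, 0)
  # pure shear du/dy = 0.2
  G <- matrix(0, 3, 3); G[1, 2] <- 0.2
  st <- strain_from_gradient(G)
  expect_equal(st$epsilon[1, 2], 0.1)
  expect_equal(st$epsilon[2, 1], 0.1)
  expect_equal(st$principal, c(0.1, 0, -0.1), tolerance = 1e-12)
  expect_equal(st$eps_max, 0.1)
  expect_error(strain_from_gradient(matrix(NA_real_, 3, 3)), "finite")
  # random symmetric tensors vs characteristic polynomial oracle
  for (s in 1:25) {
    set.seed(s)
    S <- matrix(rnorm(9), 3, 3); S <- (S + t(S)) / 2
    st <- strain_from_gradient(S)
    expect_equal(st$principal, oracle_sym_eigen(S), tolerance = 1e-10)
  }
})

test_that("strain is invariant to the antisymmetric (rotation) part", {
  for (s in 1:20) {
    set.seed(s)
    G <- matrix(rnorm(9, 0, 0.3), 3, 3)
    W <- matrix(rnorm(9), 3, 3); W <- (W - t(W)) / 2  # pure rotation generator
    a <- strain_from_gradient(G)
    b <- strain_from_gradient(G + W)
    expect_equal(a$epsilon, b$epsilon, tolerance = 1e-12)
    expect_equal(a$eps_max, b$eps_max, tolerance = 1e-12)
  }
})

test_that("smooth fields pass the filter untouched", {
  mesh <- grid_mesh(12, 12, spacing = 1, z = 100)
  # gentle smooth displacement, eps well under the threshold
  xy <- mesh$vertices[, 1:2]
  vec <- cbind(0.02 * xy[, 1], 0, 0.3 * exp(-rowSums(xy^2) / 50))
  filt <- filter_scene_flow(mesh, scene_flow(vec))
  rep <- attr(filt, "report")
  determined <- !rep$undetermined
  expect_true(all(filt$status[determined] == "valid"))
  expect_true(all(rep$score[determined] < 1))
})

test_that("a gross spike is flagged as strain outlier at eps_t = 1", {
  mesh <- grid_mesh(12, 12, spacing = 1, z = 100)
  vec <- matrix(0, 144, 3)
  mid <- 6 * 12 + 6
  vec[mid, ] <- c(0, 0, 8)  # 8 mm spike on a 1 mm grid
  filt <- filter_scene_flow(mesh, scene_flow(vec))
  expect_equal(filt$status[mid], "strain_outlier")
  # vectors preserved
  expect_equal(filt$vectors, vec, ignore_attr = TRUE)
  # neighbors not dragged into the outlier set by the spike
  nb <- neighborhoods(mesh, 1)[[mid]]
  expect_true(all(filt$status[nb] == "valid"))
})

test_that("instrument mask takes precedence over strain analysis", {
  mesh <- grid_mesh(10, 10, spacing = 1, z = 100)
  filt <- filter_scene_flow(mesh, scene_flow(matrix(0, 100, 3)),
                            instrument = c(5L, 6L, 7L))
  expect_true(all(filt$status[5:7] == "instrument"))
})

test_that("filtering is idempotent", {
  sq <- default_sequence()
  fr <- sq$frames[[1]]
  f1 <- filter_scene_flow(sq$mesh0, fr$flow, instrument = fr$instrument)
  f2 <- filter_scene_flow(sq$mesh0, f1, instrument = fr$instrument)
  expect_identical(f1$status, f2$status)
})

test_that("filter operating characteristics hold on the default scenario", {
  sq <- default_sequence()
  fr <- sq$frames[[1]]
  filt <- filter_scene_flow(sq$mesh0, fr$flow, instrument = fr$instrument)
  truth_out <- sq$corruption[[1]]$outliers
  flagged <- which(filt$status == "strain_outlier")
  candidates <- which(!filt$status %in% c("vacant", "instrument"))
  clean <- setdiff(candidates, truth_out)
  expect_gte(mean(truth_out %in% flagged), 0.95)
  expect_lte(mean(clean %in% flagged), 0.05)
})

test_that("filter report writes a CSV with scores per vertex", {
  mesh <- grid_mesh(6, 6)
  filt <- filter_scene_flow(mesh, scene_flow(matrix(0, 36, 3)))
  p <- withr::local_tempfile(fileext = ".csv")
  write_filter_report(attr(filt, "report"), p)
  df <- read.csv(p)
  expect_equal(nrow(df), 36)
  expect_true(all(c("vertex", "status", "eps_max", "score") %in% names(df)))
})
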