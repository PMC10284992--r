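# Evaluation metrics: three-point plane-projection surface distance with
# per-axis decomposition, 95th-percentile Hausdorff distance, Cauchy edge
# strain, and rigid ICP registration.

# k nearest rows of `ref` for each row of `query` (chunked brute force);
# returns an nq x k index matrix ordered by increasing distance.
knn_index <- function(query, ref, k, chunk = 1024L) {
  nq <- nrow(query)
  k <- min(k, nrow(ref))
  out <- matrix(0L, nq, k)
  r2 <- rowSums(ref^2)
  for (s in seq(1L, nq, by = chunk)) {
    e <- min(nq, s + chunk - 1L)
    Q <- query[s:e, , drop = FALSE]
    D <- outer(rowSums(Q^2), r2, "+") - 2 * Q %*% t(ref)
    out[s:e, ] <- t(apply(D, 1L, function(d) order(d)[seq_len(k)]))
  }
  out
}

# distance to the single nearest row of ref, per row of query; the candidate
# is located with the fast inner-product expansion, then the distance is
# recomputed directly so cancellation noise does not enter the result
nn_dist <- function(query, ref, chunk = 2048L) {
  idx <- nearest_neighbor_index(query, ref, chunk = chunk)
  sqrt(rowSums((query - ref[idx, , drop = FALSE])^2))
}

#' Surface distance between a mesh and a reference point cloud
#'
#' For each mesh vertex, the three closest reference points define a plane;
#' the vertex is projected onto that plane and the projection offset is the
#' surface distance, decomposed into its x/y/z components (x and y parallel to
#' the image plane, z along the optical axis). Collinear nearest-point triples
#' fall back to the next nearest point until a non-degenerate plane is found.
#'
#' @param mesh a `triangle_mesh` (or N x 3 coordinate matrix).
#' @param reference_points M x 3 matrix of reference points (mm), M >= 3.
#' @param max_fallback how many additional neighbors may be tried when the
#'   nearest triple is collinear (default 7).
#' @return object of class `surface_distance_report`: a tibble with one row
#'   per vertex (`vertex`, `dx`, `dy`, `dz`, `distance`, `fallback`).
#' @export
surface_distance <- function(mesh, reference_points, max_fallback = 7L) {
  V <- if (inherits(mesh, "triangle_mesh")) mesh$vertices else
    as_coord_matrix(mesh)
  R <- as_coord_matrix(reference_points, "reference_points")
  if (nrow(R) < 3L) stop("need at least 3 reference points")
  k <- min(3L + max_fallback, nrow(R))
  nn <- knn_index(V, R, k)
  n <- nrow(V)
  comp <- matrix(NA_real_, n, 3L)
  fallback <- integer(n)
  for (i in seq_len(n)) {
    sel <- c(1L, 2L, 3L)
    repeat {
      A <- R[nn[i, sel[1L]], ]; B <- R[nn[i, sel[2L]], ]; C <- R[nn[i, sel[3L]], ]
      nrm <- cross3(B - A, C - A)
      nn2 <- sqrt(sum(nrm^2))
      if (nn2 > 1e-9 * (sqrt(sum((B - A)^2)) * sqrt(sum((C - A)^2)) + 1e-300)) {
        nrm <- nrm / nn2
        comp[i, ] <- sum((V[i, ] - A) * nrm) * nrm
        break
      }
      if (sel[3L] >= k) {
        stop("could not find a non-collinear reference triple for vertex ", i)
      }
      sel[3L] <- sel[3L] + 1L
      fallback[i] <- fallback[i] + 1L
    }
  }
  tab <- tibble::tibble(
    vertex = seq_len(n),
    dx = comp[, 1L], dy = comp[, 2L], dz = comp[, 3L],
    distance = sqrt(rowSums(comp^2)),
    fallback = fallback
  )
  structure(tab, class = c("surface_distance_report", class(tab)))
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Summarize a surface distance report
#'
#' One row per axis (absolute component of the projection offset) plus an
#' overall row (offset norm), each with max / mean / sd in mm.
#'
#' @param x a `surface_distance_report`.
#' @param ... unused.
#' @export
glance.surface_distance_report <- function(x, ...) {
  vals <- list(x = abs(x$dx), y = abs(x$dy), z = abs(x$dz),
               overall = x$distance)
  tibble::tibble(
    axis = names(vals),
    max = unname(vapply(vals, max, 0)),
    mean = unname(vapply(vals, mean, 0)),
    sd = unname(vapply(vals, stats::sd, 0))
  )
}

#' @export
tidy.surface_distance_report <- function(x, ...) tibble::as_tibble(x)

#' Histogram of per-vertex surface distances
#' @param object a `surface_distance_report`.
#' @param ... unused.
#' @export
autoplot.surface_distance_report <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(x = distance)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::labs(x = "surface distance (mm)", y = "vertices")
}

#' 95th-percentile Hausdorff distance between two point sets
#'
#' The 95th percentile (linear interpolation) of directed nearest-neighbor
#' distances; by default the symmetric value, i.e. the larger of the two
#' directed percentiles, which makes the metric invariant to argument order.
#'
#' @param points_a,points_b non-empty N x 3 matrices (mm); `triangle_mesh`
#'   objects are accepted and contribute their vertices.
#' @param directed if TRUE, only the a -> b directed percentile is returned.
#' @param probs percentile (default 0.95).
#' @return distance in mm.
#' @export
hd95 <- function(points_a, points_b, directed = FALSE, probs = 0.95) {
  A <- if (inherits(points_a, "triangle_mesh")) points_a$vertices else
    as_coord_matrix(points_a, "points_a")
  B <- if (inherits(points_b, "triangle_mesh")) points_b$vertices else
    as_coord_matrix(points_b, "points_b")
  if (nrow(A) == 0L || nrow(B) == 0L) stop("point sets must be non-empty")
  dab <- stats::quantile(nn_dist(A, B), probs, names = FALSE, type = 7)
  if (directed) return(dab)
  dba <- stats::quantile(nn_dist(B, A), probs, names = FALSE, type = 7)
  max(dab, dba)
}

#' Cauchy strain per mesh edge
#'
#' Relative edge-length change against the initial mesh,
#' `(L - L0) / L0`, computed over the shared connectivity. Because edge
#' lengths are invariant to rigid motion, the map separates deformation from
#' rigid displacement.
#'
#' @param mesh_t current-frame `triangle_mesh`.
#' @param mesh_0 initial `triangle_mesh` with identical connectivity.
#' @return tibble with one row per edge: `edge`, `v1`, `v2`, `L0`, `L`,
#'   `strain`.
#' @export
cauchy_edge_strain <- function(mesh_t, mesh_0) {
  stopifnot(inherits(mesh_t, "triangle_mesh"), inherits(mesh_0, "triangle_mesh"))
  if (!identical(mesh_t$edges, mesh_0$edges)) {
    stop("meshes must share identical connectivity")
  }
  e <- mesh_0$edges
  L0 <- sqrt(rowSums((mesh_0$vertices[e[, 1L], , drop = FALSE] -
                        mesh_0$vertices[e[, 2L], , drop = FALSE])^2))
  if (any(L0 == 0)) stop("zero-length edge in the initial mesh")
  L <- sqrt(rowSums((mesh_t$vertices[e[, 1L], , drop = FALSE] -
                       mesh_t$vertices[e[, 2L], , drop = FALSE])^2))
  tibble::tibble(edge = seq_len(nrow(e)), v1 = e[, 1L], v2 = e[, 2L],
                 L0 = L0, L = L, strain = (L - L0) / L0)
}

#' Rigid ICP registration
#'
#' Point-to-point iterative closest point: alternates nearest-neighbor
#' correspondence with the closed-form (SVD/Kabsch) rigid fit until the RMS
#' residual stabilizes. Used to register reference scans into camera
#' coordinates.
#'
#' @param moving,fixed N x 3 / M x 3 point matrices (mm).
#' @param init initial 4 x 4 homogeneous transform (default identity).
#' @param max_iter maximum iterations (default 50).
#' @param tol stop when the RMS improvement falls below this (mm,
#'   default 1e-10).
#' @param diverged_rms residual above which the `diverged` flag is set
#'   (default 10 mm).
#' @return list with `transform` (4 x 4), `R`, `t`, `rms` (mm), `iterations`,
#'   `diverged`.
#' @export
register_icp <- function(moving, fixed, init = diag(4), max_iter = 50L,
                         tol = 1e-10, diverged_rms = 10) {
  P <- as_coord_matrix(moving, "moving")
  Q <- as_coord_matrix(fixed, "fixed")
  Tr <- init
  rms_prev <- Inf
  it <- 0L
  repeat {
    it <- it + 1L
    Pm <- sweep(P %*% t(Tr[1:3, 1:3]), 2L, -Tr[1:3, 4L])
    idx <- nearest_neighbor_index(Pm, Q)
    fit <- kabsch(Pm, Q[idx, , drop = FALSE])
    Tr <- rbind(cbind(fit$R %*% Tr[1:3, 1:3],
                      fit$R %*% Tr[1:3, 4L] + fit$t), c(0, 0, 0, 1))
    rms <- fit$rms
    if (abs(rms_prev - rms) < tol || it >= max_iter) break
    rms_prev <- rms
  }
  diverged <- rms > diverged_rms
  if (diverged) warning("ICP residual ", signif(rms, 4),
                        " mm exceeds divergence threshold")
  list(transform = Tr, R = Tr[1:3, 1:3], t = Tr[1:3, 4L], rms = rms,
       iterations = it, diverged = diverged)
}

# closed-form rigid fit R p + t ~ q
kabsch <- function(P, Q) {
  pc <- colMeans(P); qc <- colMeans(Q)
  H <- t(sweep(P, 2L, pc)) %*% sweep(Q, 2L, qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- qc - as.numeric(R %*% pc)
  res <- sweep(P %*% t(R), 2L, -t) - Q
  list(R = R, t = t, rms = sqrt(mean(rowSums(res^2))))
}

#' Apply a rigid transform to points or a mesh
#'
#' @param x N x 3 matrix or `triangle_mesh`.
#' @param transform 4 x 4 homogeneous matrix.
#' @export
transform_points <- function(x, transform) {
  if (inherits(x, "triangle_mesh")) {
    x$vertices <- transform_points(x$vertices, transform)
    return(x)
  }
  x <- as_coord_matrix(x)
  sweep(x %*% t(transform[1:3, 1:3]), 2L, -transform[1:3, 4L])
}
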