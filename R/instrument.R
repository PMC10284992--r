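# Instrument mask tracking, occluded-vertex detection, and the per-vertex
# depth bounds that feed the constrained least-squares solve.

#' Propagate an instrument mask along an optical flow field
#'
#' Forward-warps each mask pixel to its flow endpoint (rounded to the nearest
#' pixel; endpoints outside the frame are dropped) and closes small holes with
#' one pass of 3x3 morphological closing.
#'
#' @param mask logical height x width matrix (TRUE = instrument).
#' @param flow_uv height x width x 2 flow array (px), as in
#'   [frame_observation()].
#' @return logical matrix of the same size.
#' @export
propagate_mask <- function(mask, flow_uv) {
  mask <- mask > 0
  if (length(dim(flow_uv)) != 3L || !identical(dim(flow_uv)[1:2], dim(mask))) {
    stop("mask and flow dimensions differ")
  }
  h <- nrow(mask); w <- ncol(mask)
  src <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, h, w)
  if (nrow(src) > 0L) {
    # 0-based pixel coords: u = col - 1, v = row - 1
    u1 <- round((src[, 2L] - 1L) + flow_uv[cbind(src[, 1L], src[, 2L], 1L)])
    v1 <- round((src[, 1L] - 1L) + flow_uv[cbind(src[, 1L], src[, 2L], 2L)])
    keep <- is.finite(u1) & is.finite(v1) & u1 >= 0 & u1 < w & v1 >= 0 & v1 < h
    out[cbind(v1[keep] + 1L, u1[keep] + 1L)] <- TRUE
  }
  morph_close(out)
}

# 3x3 binary dilation / erosion / closing on logical matrices
morph_dilate <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (dv in -1:1) for (du in -1:1) {
    # shift without wrap: only in-range contributions
    r_ok <- seq_len(h) + dv >= 1L & seq_len(h) + dv <= h
    c_ok <- seq_len(w) + du >= 1L & seq_len(w) + du <= w
    out[r_ok, c_ok] <- out[r_ok, c_ok] | m[seq_len(h)[r_ok] + dv,
                                           seq_len(w)[c_ok] + du]
  }
  out
}

morph_erode <- function(m) !morph_dilate(!m)

morph_close <- function(m) morph_erode(morph_dilate(m))

#' Vertices whose projection falls on a mask pixel
#'
#' Projects camera-frame vertex positions into the left image and tests the
#' nearest pixel against the binary mask; vertices projecting off-image are
#' never flagged.
#'
#' @param coords N x 3 vertex positions (mm).
#' @param mask logical height x width matrix.
#' @param calib a [stereo_calibration()].
#' @return integer vector of flagged vertex indices.
#' @export
vertices_on_mask <- function(coords, mask, calib) {
  coords <- as_coord_matrix(coords)
  P <- project_points(coords, calib)
  u <- round(P[, 1L]); v <- round(P[, 2L])
  h <- nrow(mask); w <- ncol(mask)
  inb <- is.finite(u) & is.finite(v) & u >= 0 & u < w & v >= 0 & v < h
  hit <- rep(FALSE, nrow(coords))
  hit[inb] <- mask[cbind(v[inb] + 1L, u[inb] + 1L)]
  which(hit)
}

#' Detect mesh vertices occluded by the instrument
#'
#' @param mesh a `triangle_mesh` in the camera frame.
#' @inheritParams vertices_on_mask
#' @return integer vector of occluded vertex indices.
#' @export
detect_occluded_vertices <- function(mesh, mask, calib) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  vertices_on_mask(mesh$vertices, mask, calib)
}

#' Occlusion constraint set
#'
#' Depth bounds for occluded vertices: the recovered z of an occluded tissue
#' vertex must stay at or below the instrument surface, i.e.
#' `z >= p_z + delta` (z grows with depth; the instrument is nearer the
#' camera).
#'
#' @param occluded integer vector of occluded vertex indices (unique).
#' @param p_z per-occluded-vertex depth bound (mm), same length.
#' @param delta non-negative margin added to every bound (mm, default 0).
#' @return object of class `occlusion_constraints`.
#' @export
occlusion_constraints <- function(occluded = integer(), p_z = numeric(),
                                  delta = 0) {
  occluded <- as.integer(occluded)
  if (anyDuplicated(occluded)) stop("occluded indices must be unique")
  if (length(p_z) != length(occluded)) stop("p_z length mismatch")
  if (length(p_z) && any(!is.finite(p_z))) stop("p_z must be finite")
  if (delta < 0) stop("delta must be non-negative")
  structure(list(occluded = occluded, p_z = as.numeric(p_z), delta = delta),
            class = "occlusion_constraints")
}

#' Depth bounds from the instrument's reconstructed 3D points
#'
#' For each occluded vertex, the bound `p_z` is the z coordinate of the
#' instrument point nearest (3D Euclidean distance) to the vertex's
#' previous-frame position.
#'
#' @param occluded integer vector of occluded vertex indices.
#' @param instrument_points M x 3 matrix of instrument 3D points (mm).
#' @param coords N x 3 previous-frame vertex positions (mm).
#' @param delta margin (mm, default 0).
#' @return an [occlusion_constraints()].
#' @export
compute_depth_bounds <- function(occluded, instrument_points, coords,
                                 delta = 0) {
  occluded <- as.integer(occluded)
  if (length(occluded) == 0L) return(occlusion_constraints(delta = delta))
  instrument_points <- as_coord_matrix(instrument_points, "instrument_points")
  if (nrow(instrument_points) == 0L) {
    stop("occluded vertices present but instrument point set is empty")
  }
  coords <- as_coord_matrix(coords)
  nn <- nearest_neighbor_index(coords[occluded, , drop = FALSE],
                               instrument_points)
  occlusion_constraints(occluded, instrument_points[nn, 3L], delta = delta)
}

# index of nearest row of `ref` for each row of `query` (chunked brute force)
nearest_neighbor_index <- function(query, ref, chunk = 2048L) {
  nq <- nrow(query)
  out <- integer(nq)
  r2 <- rowSums(ref^2)
  for (s in seq(1L, nq, by = chunk)) {
    e <- min(nq, s + chunk - 1L)
    Q <- query[s:e, , drop = FALSE]
    D <- outer(rowSums(Q^2), r2, "+") - 2 * Q %*% t(ref)
    out[s:e] <- max.col(-D, ties.method = "first")
  }
  out
}

#' @export
print.occlusion_constraints <- function(x, ...) {
  cat("occlusion_constraints:", length(x$occluded), "occluded vertices, delta =",
      x$delta, "mm\n")
  invisible(x)
}

#' Tidy an occlusion constraint set
#' @param x an `occlusion_constraints`.
#' @param ... unused.
#' @export
tidy.occlusion_constraints <- function(x, ...) {
  tibble::tibble(vertex = x$occluded, p_z = x$p_z, delta = x$delta)
}

#' Write occlusion constraints as CSV
#' @param constraints an `occlusion_constraints`.
#' @param path CSV path.
#' @export
write_constraints_csv <- function(constraints, path) {
  utils::write.csv(as.data.frame(tidy.occlusion_constraints(constraints)),
                   path, row.names = FALSE)
  invisible(path)
}
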