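# Scene flow: stereo triangulation, projection, per-vertex 3D flow fields,
# and composition of flow from disparity + optical-flow observations.

#' Vertex status levels of a scene flow field
#'
#' `"valid"` vectors drive the dynamic term; `"vacant"` marks vertices with no
#' usable observation (off-image projection, invalid disparity/flow sample, or
#' non-finite vector); `"instrument"` marks vertices whose projection falls on
#' the tracked instrument mask; `"strain_outlier"` marks vectors rejected by
#' the strain filter.
#' @export
flow_statuses <- function() c("valid", "vacant", "instrument", "strain_outlier")

#' Rectified stereo calibration
#'
#' @param f focal length (px), shared by the rectified pair.
#' @param cx,cy principal point (px), 0-based image coordinates.
#' @param b baseline between the rectified cameras (mm).
#' @param width,height optional image size in px, used for bounds checks.
#' @return object of class `stereo_calibration`.
#' @export
stereo_calibration <- function(f, cx, cy, b, width = NA_integer_,
                               height = NA_integer_) {
  stopifnot(is.numeric(f), f > 0, is.numeric(b), b > 0)
  structure(list(f = f, cx = cx, cy = cy, b = b,
                 width = as.integer(width), height = as.integer(height)),
            class = "stereo_calibration")
}

#' Read / write stereo calibration as YAML
#'
#' The file stores `f`, `cx`, `cy`, `b` and optionally `width`, `height`.
#' @param path YAML file path.
#' @export
read_calibration <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("f", "cx", "cy", "b")
  miss <- setdiff(need, names(y))
  if (length(miss)) stop("calibration file missing key(s): ",
                         paste(miss, collapse = ", "))
  stereo_calibration(y$f, y$cx, y$cy, y$b,
                     width = y$width %||% NA_integer_,
                     height = y$height %||% NA_integer_)
}

#' @rdname read_calibration
#' @param calib a `stereo_calibration`.
#' @export
write_calibration <- function(calib, path) {
  yaml::write_yaml(unclass(calib), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Triangulate rectified-stereo pixels to 3D points
#'
#' Standard rectified geometry: `z = f * b / d`, `x = (u - cx) * z / f`,
#' `y = (v - cy) * z / f`, all in mm. Non-positive disparities give NA rows.
#'
#' @param uv N x 2 matrix of left-image pixel coordinates (0-based; u =
#'   column, v = row).
#' @param d disparity values (px), length N.
#' @param calib a `stereo_calibration`.
#' @return N x 3 matrix of points (mm).
#' @export
triangulate_stereo <- function(uv, d, calib) {
  uv <- as.matrix(uv)
  stopifnot(ncol(uv) == 2L, length(d) == nrow(uv))
  z <- ifelse(is.finite(d) & d > 0, calib$f * calib$b / d, NA_real_)
  cbind((uv[, 1L] - calib$cx) * z / calib$f,
        (uv[, 2L] - calib$cy) * z / calib$f,
        z)
}

#' Project camera-frame points to left-image pixels
#'
#' Inverse of [triangulate_stereo()]: `u = f * x / z + cx`,
#' `v = f * y / z + cy`; the implied disparity `f * b / z` is returned as a
#' third column.
#'
#' @param points N x 3 matrix (mm).
#' @inheritParams triangulate_stereo
#' @return N x 3 matrix of (u, v, disparity).
#' @export
project_points <- function(points, calib) {
  points <- as_coord_matrix(points)
  z <- points[, 3L]
  cbind(calib$f * points[, 1L] / z + calib$cx,
        calib$f * points[, 2L] / z + calib$cy,
        calib$f * calib$b / z)
}

#' Scene flow field
#'
#' Validated container for per-vertex 3D displacement vectors between two
#' frames, with a per-vertex status (see [flow_statuses()]). Vectors that are
#' not finite are forced to `"vacant"`.
#'
#' @param vectors N x 3 matrix of displacement vectors (mm).
#' @param status character vector of length N with values in
#'   [flow_statuses()]; defaults to all `"valid"`.
#' @return object of class `scene_flow`.
#' @export
scene_flow <- function(vectors, status = NULL) {
  vectors <- as_coord_matrix(vectors, "vectors")
  n <- nrow(vectors)
  if (is.null(status)) status <- rep("valid", n)
  if (length(status) != n) {
    stop("status length (", length(status), ") does not match vector count (",
         n, ")")
  }
  status <- as.character(status)
  bad <- !status %in% flow_statuses()
  if (any(bad)) stop("unknown status value(s): ",
                     paste(unique(status[bad]), collapse = ", "))
  status[!is.finite(rowSums(vectors))] <- "vacant"
  structure(list(vectors = vectors, status = status), class = "scene_flow")
}

#' @export
print.scene_flow <- function(x, ...) {
  tab <- table(factor(x$status, levels = flow_statuses()))
  cat("scene_flow:", nrow(x$vectors), "vertices (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Indices of valid vertices of a scene flow field
#' @param flow a `scene_flow`.
#' @export
valid_vertices <- function(flow) which(flow$status == "valid")

#' Per-frame stereo observation
#'
#' Bundles the image-grid fields needed to compose scene flow between frames
#' t and t+1: disparity maps at both frames, left-image optical flow from t to
#' t+1, and optional binary instrument masks. All fields are matrices (or
#' height x width x 2 array for flow) with rows = image rows.
#'
#' @param disparity_t,disparity_t1 disparity maps (px); invalid pixels NA or
#'   <= 0.
#' @param flow_uv height x width x 2 array; `[ , , 1]` = u (column)
#'   displacement, `[ , , 2]` = v (row) displacement, in px.
#' @param mask_t,mask_t1 optional logical matrices marking instrument pixels.
#' @return object of class `frame_observation`.
#' @export
frame_observation <- function(disparity_t, disparity_t1, flow_uv,
                              mask_t = NULL, mask_t1 = NULL) {
  if (is.null(disparity_t) || is.null(disparity_t1) || is.null(flow_uv)) {
    stop("frame_observation requires disparity_t, disparity_t1 and flow_uv")
  }
  dm <- dim(disparity_t)
  if (!identical(dim(disparity_t1), dm)) {
    stop("disparity maps differ in size")
  }
  if (length(dim(flow_uv)) != 3L || dim(flow_uv)[3L] != 2L ||
      !identical(dim(flow_uv)[1:2], dm)) {
    stop("flow_uv must be a height x width x 2 array matching the disparity maps")
  }
  for (m in list(mask_t, mask_t1)) {
    if (!is.null(m) && !identical(dim(m), dm)) stop("mask size mismatch")
  }
  structure(list(disparity_t = disparity_t, disparity_t1 = disparity_t1,
                 flow_uv = flow_uv, mask_t = mask_t, mask_t1 = mask_t1),
            class = "frame_observation")
}

#' Bilinear sampling of an image-grid field
#'
#' Samples at 0-based pixel coordinates (u = column, v = row, pixel centers
#' at integers) with the conservative "all four neighbors valid" rule:
#' returns NA where any of the four surrounding pixels is invalid (NA) or the
#' sample point falls outside the image, so values never smear across
#' occlusion boundaries.
#'
#' @param img numeric matrix (rows = image rows).
#' @param u,v sample coordinates (px), vectorized.
#' @return numeric vector of sampled values with NA where invalid.
#' @export
bilinear_sample <- function(img, u, v) {
  h <- nrow(img); w <- ncol(img)
  u0 <- floor(u); v0 <- floor(v)
  fu <- u - u0; fv <- v - v0
  inb <- is.finite(u) & is.finite(v) & u0 >= 0 & v0 >= 0 &
    (u0 + 1) <= (w - 1) & (v0 + 1) <= (h - 1)
  # clamp exact right/bottom edge samples
  edge_u <- is.finite(u) & u0 == w - 1 & fu == 0 & v0 >= 0 & v0 <= h - 1
  edge_v <- is.finite(v) & v0 == h - 1 & fv == 0 & u0 >= 0 & u0 <= w - 1
  u0[edge_u] <- u0[edge_u] - 1; fu[edge_u] <- 1
  v0[edge_v] <- v0[edge_v] - 1; fv[edge_v] <- 1
  inb <- inb | ((edge_u | edge_v) & u0 >= 0 & v0 >= 0 &
                  (u0 + 1) <= (w - 1) & (v0 + 1) <= (h - 1))
  out <- rep(NA_real_, length(u))
  if (!any(inb)) return(out)
  i0 <- v0[inb] + 1L; j0 <- u0[inb] + 1L
  a <- img[cbind(i0, j0)]; b <- img[cbind(i0, j0 + 1L)]
  c_ <- img[cbind(i0 + 1L, j0)]; d <- img[cbind(i0 + 1L, j0 + 1L)]
  val <- (1 - fv[inb]) * ((1 - fu[inb]) * a + fu[inb] * b) +
    fv[inb] * ((1 - fu[inb]) * c_ + fu[inb] * d)
  val[!is.finite(a) | !is.finite(b) | !is.finite(c_) | !is.finite(d)] <- NA_real_
  out[inb] <- val
  out
}

valid_disparity <- function(d) ifelse(is.finite(d) & d > 0, d, NA_real_)

#' Compose per-vertex scene flow from disparity and optical flow
#'
#' The two-step composition: each previous-frame vertex is projected into the
#' left image at frame t; the disparity there gives its reconstructed 3D
#' position `X_t`; the optical flow carries the projection to frame t+1 where
#' the second disparity map gives `X_{t+1}`; the scene flow vector is
#' `X_{t+1} - X_t`. A vertex is `"vacant"` if its projection or flow endpoint
#' leaves the image or any sampled field is invalid at that location
#' (bilinear sampling requires all four neighboring pixels valid).
#'
#' @param mesh_prev `triangle_mesh` with previous-frame vertex positions
#'   (camera frame).
#' @param obs a [frame_observation()].
#' @param calib a [stereo_calibration()].
#' @return a [scene_flow()] with statuses `"valid"` / `"vacant"`.
#' @export
compose_scene_flow <- function(mesh_prev, obs, calib) {
  stopifnot(inherits(mesh_prev, "triangle_mesh"),
            inherits(obs, "frame_observation"))
  P <- project_points(mesh_prev$vertices, calib)
  u <- P[, 1L]; v <- P[, 2L]
  d_t <- bilinear_sample(valid_disparity(obs$disparity_t), u, v)
  fu <- bilinear_sample(obs$flow_uv[, , 1L], u, v)
  fv <- bilinear_sample(obs$flow_uv[, , 2L], u, v)
  u1 <- u + fu; v1 <- v + fv
  d_t1 <- bilinear_sample(valid_disparity(obs$disparity_t1), u1, v1)
  X_t <- triangulate_stereo(cbind(u, v), d_t, calib)
  X_t1 <- triangulate_stereo(cbind(u1, v1), d_t1, calib)
  vec <- X_t1 - X_t
  ok <- is.finite(rowSums(vec))
  vec[!ok, ] <- 0
  scene_flow(vec, ifelse(ok, "valid", "vacant"))
}

#' Tidy a scene flow field
#'
#' @param x a `scene_flow`.
#' @param ... unused.
#' @return a tibble with one row per vertex: `vertex`, `fx`, `fy`, `fz`,
#'   `magnitude`, `status`.
#' @export
tidy.scene_flow <- function(x, ...) {
  tibble::tibble(
    vertex = seq_len(nrow(x$vectors)),
    fx = x$vectors[, 1L], fy = x$vectors[, 2L], fz = x$vectors[, 3L],
    magnitude = sqrt(rowSums(x$vectors^2)),
    status = x$status
  )
}

#' Write / read a scene flow field as CSV
#'
#' Columns `vertex, fx, fy, fz, status`.
#' @param flow a `scene_flow`.
#' @param path CSV path.
#' @export
write_scene_flow_csv <- function(flow, path) {
  df <- tidy.scene_flow(flow)[, c("vertex", "fx", "fy", "fz", "status")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scene_flow_csv
#' @export
read_scene_flow_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("vertex", "fx", "fy", "fz", "status")
  if (!all(need %in% names(df))) stop("scene flow CSV missing columns")
  df <- df[order(df$vertex), ]
  scene_flow(as.matrix(df[, c("fx", "fy", "fz")]), df$status)
}
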