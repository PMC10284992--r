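# Synthetic phantom simulator: a ground-truthed deforming grid surface with
# noisy scene flow observations, gross outliers, vacancies, and a rod-shaped
# instrument occluder strictly nearer the camera than the tissue.

#' Synthetic deformation scenario
#'
#' Defines the study conditions of the synthetic benchmark: a rectangular
#' grid surface at depth `z0` indented by a Gaussian-profile press (emulating
#' forceps pushing the tissue away from the camera), observed through noisy
#' per-vertex scene flow with a configurable fraction of gross outliers, a
#' vacancy margin, and a rod occluder above the surface whose motion
#' contaminates the observed flow underneath it.
#'
#' @param nx,ny grid size in vertices (default 60 x 60).
#' @param spacing vertex spacing (mm, default 1).
#' @param z0 base surface depth (mm, default 100).
#' @param indent_center x/y center of the indentation (mm, default c(0, 0)).
#' @param sigma Gaussian indentation width (mm, default 8).
#' @param max_depth total indentation depth reached at the last frame (mm,
#'   default 5).
#' @param n_frames number of flow steps (default 10).
#' @param sigma_n isotropic Gaussian noise sd on observed flow vectors (mm,
#'   default 0.1).
#' @param p_out fraction of vertices replaced by gross outlier vectors per
#'   frame (default 0.1).
#' @param m_out magnitude of outlier vectors (mm, default 10).
#' @param occluder_width width of the rod occluder strip in x (mm, default 6,
#'   about 10% of the default grid); `0` disables the occluder.
#' @param occluder_x x position of the rod center (mm, default 0, over the
#'   indentation).
#' @param occluder_clearance depth gap between rod and base surface (mm,
#'   default 10; the rod sits at `z0 - occluder_clearance`).
#' @param occluder_motion per-frame rigid motion of the rod (mm,
#'   default c(0.3, 0, 0.1)).
#' @param vacancy_margin width of the border band whose vertices report no
#'   observation (mm, default 1, the outermost vertex ring).
#' @param calib a [stereo_calibration()] used to render masks and image-mode
#'   observations.
#' @return a list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(nx = 60L, ny = 60L, spacing = 1, z0 = 100,
                               indent_center = c(0, 0), sigma = 8,
                               max_depth = 5, n_frames = 10L, sigma_n = 0.1,
                               p_out = 0.1, m_out = 10,
                               occluder_width = 6, occluder_x = 0,
                               occluder_clearance = 10,
                               occluder_motion = c(0.3, 0, 0.1),
                               vacancy_margin = 1,
                               calib = stereo_calibration(500, 200, 200, 5.2,
                                                          width = 400L,
                                                          height = 400L)) {
  if (sigma <= 0) stop("sigma must be positive")
  if (spacing <= 0) stop("spacing must be positive")
  if (p_out < 0 || p_out > 1) stop("p_out must be in [0, 1]")
  structure(list(nx = as.integer(nx), ny = as.integer(ny), spacing = spacing,
                 z0 = z0, indent_center = indent_center, sigma = sigma,
                 max_depth = max_depth, n_frames = as.integer(n_frames),
                 sigma_n = sigma_n, p_out = p_out, m_out = m_out,
                 occluder_width = occluder_width, occluder_x = occluder_x,
                 occluder_clearance = occluder_clearance,
                 occluder_motion = occluder_motion,
                 vacancy_margin = vacancy_margin, calib = calib),
            class = "synthetic_scenario")
}

# indentation profile at material (x, y), per unit depth
indent_profile <- function(scn, xy) {
  d2 <- (xy[, 1L] - scn$indent_center[1L])^2 +
    (xy[, 2L] - scn$indent_center[2L])^2
  exp(-d2 / (2 * scn$sigma^2))
}

# cumulative indentation depth at frame t (0..n_frames), linear schedule
indent_depth <- function(scn, t) scn$max_depth * t / scn$n_frames

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Generate a ground-truthed synthetic sequence
#'
#' Produces, for every frame, the true deformed mesh, the observed per-vertex
#' scene flow (true step displacement + Gaussian noise, with a seeded
#' fraction of vertices replaced by gross outlier vectors, occluded vertices
#' carrying copies of the rod's motion, and border vertices vacant), the
#' rod's pixel mask and reconstructed 3D point set, and bookkeeping of which
#' vertices were truly corrupted. Generation is bit-reproducible for a fixed
#' seed.
#'
#' @param scenario a [synthetic_scenario()].
#' @param seed integer RNG seed (default 1).
#' @return a list of class `synthetic_sequence` with elements `mesh0`,
#'   `truth` (list of meshes, frame 0 first), `frames` (per-frame input list
#'   suitable for [run_sequence()]), `calib`, `scenario`, and per-frame truth
#'   bookkeeping in `corruption`.
#' @export
generate_sequence <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  scn <- scenario
  with_seed(seed, {
    mesh0 <- grid_mesh(scn$nx, scn$ny, scn$spacing, z = scn$z0)
    xy <- mesh0$vertices[, 1:2, drop = FALSE]
    prof <- indent_profile(scn, xy)
    n <- nrow(mesh0$vertices)

    # vacancy band at the grid border
    ext_x <- range(xy[, 1L]); ext_y <- range(xy[, 2L])
    vacant <- xy[, 1L] < ext_x[1L] + scn$vacancy_margin |
      xy[, 1L] > ext_x[2L] - scn$vacancy_margin |
      xy[, 2L] < ext_y[1L] + scn$vacancy_margin |
      xy[, 2L] > ext_y[2L] - scn$vacancy_margin

    truth <- vector("list", scn$n_frames + 1L)
    truth[[1L]] <- mesh0
    frames <- vector("list", scn$n_frames)
    corruption <- vector("list", scn$n_frames)

    for (t in seq_len(scn$n_frames)) {
      step_depth <- indent_depth(scn, t) - indent_depth(scn, t - 1L)
      true_step <- cbind(0, 0, step_depth * prof)
      mesh_t <- truth[[t]]
      mesh_t$vertices <- truth[[t]]$vertices + true_step
      truth[[t + 1L]] <- mesh_t

      obs <- true_step + matrix(stats::rnorm(3L * n, 0, scn$sigma_n), n, 3L)

      out_idx <- which(stats::runif(n) < scn$p_out)
      if (length(out_idx)) {
        dir <- matrix(stats::rnorm(3L * length(out_idx)), ncol = 3L)
        dir <- dir / pmax(sqrt(rowSums(dir^2)), 1e-12)
        obs[out_idx, ] <- scn$m_out * dir
      }

      occ <- occluder_state(scn, t)
      occ_idx <- integer()
      mask <- NULL
      inst_pts <- NULL
      if (scn$occluder_width > 0) {
        mask <- occluder_mask(scn, occ)
        occ_idx <- vertices_on_mask(truth[[t + 1L]]$vertices, mask, scn$calib)
        obs[occ_idx, ] <- matrix(scn$occluder_motion, length(occ_idx), 3L,
                                 byrow = TRUE)
        inst_pts <- occluder_points(scn, occ)
      }

      status <- rep("valid", n)
      status[vacant] <- "vacant"
      obs[vacant, ] <- 0

      frames[[t]] <- list(
        flow = scene_flow(obs, status),
        instrument = if (is.null(mask)) NULL else
          list(mask = mask, calib = scn$calib),
        instrument_points = inst_pts
      )
      corruption[[t]] <- list(outliers = setdiff(out_idx, c(occ_idx, which(vacant))),
                              occluded = setdiff(occ_idx, which(vacant)),
                              vacant = which(vacant))
    }
    structure(list(mesh0 = mesh0, truth = truth, frames = frames,
                   calib = scn$calib, scenario = scn, corruption = corruption,
                   seed = seed),
              class = "synthetic_sequence")
  })
}

# rod state at frame index t (0-based): x center and depth
occluder_state <- function(scn, t) {
  list(x = scn$occluder_x + t * scn$occluder_motion[1L],
       y_shift = t * scn$occluder_motion[2L],
       z = scn$z0 - scn$occluder_clearance + t * scn$occluder_motion[3L])
}

# pixel footprint of the rod: vertical strip spanning the image rows covered
# by the grid, at the rod's projected column range
occluder_mask <- function(scn, occ) {
  calib <- scn$calib
  w <- calib$width; h <- calib$height
  if (is.na(w) || is.na(h)) stop("scenario calib needs width/height for masks")
  mask <- matrix(FALSE, h, w)
  u_lo <- calib$f * (occ$x - scn$occluder_width / 2) / occ$z + calib$cx
  u_hi <- calib$f * (occ$x + scn$occluder_width / 2) / occ$z + calib$cx
  cols <- seq(max(0L, floor(u_lo)), min(w - 1L, ceiling(u_hi)))
  if (length(cols)) mask[, cols + 1L] <- TRUE
  mask
}

# reconstructed 3D point set of the rod (regular sampling of its surface)
occluder_points <- function(scn, occ, spacing = 1) {
  half_y <- (scn$ny - 1) * scn$spacing / 2
  xs <- seq(occ$x - scn$occluder_width / 2, occ$x + scn$occluder_width / 2,
            by = spacing / 2)
  ys <- seq(-half_y, half_y, by = spacing)
  cbind(rep(xs, length(ys)), rep(ys, each = length(xs)), occ$z)
}

#' Render image-grid observations for a synthetic frame pair
#'
#' Produces the disparity maps at frames `t` and `t + 1`, the left-image
#' optical flow between them, and the instrument mask, all on the pixel grid
#' of the scenario's calibration — the inputs [compose_scene_flow()] expects.
#' Depth is converted to disparity `d = f b / z` and quantized to
#' `1 / quant_steps` px to emulate finite stereo matching precision.
#'
#' @param scenario a [synthetic_scenario()].
#' @param t frame index (0-based; the pair is t -> t + 1).
#' @param quant_steps disparity/flow quantization steps per px (default 16;
#'   `Inf` disables quantization).
#' @return a [frame_observation()].
#' @export
render_observations <- function(scenario, t = 0L, quant_steps = 16) {
  scn <- scenario
  calib <- scn$calib
  w <- calib$width; h <- calib$height
  if (is.na(w) || is.na(h)) stop("scenario calib needs width/height")
  half_x <- (scn$nx - 1) * scn$spacing / 2
  half_y <- (scn$ny - 1) * scn$spacing / 2
  if (calib$f * half_x / scn$z0 + calib$cx > w ||
      calib$f * half_y / scn$z0 + calib$cy > h ||
      calib$cx - calib$f * half_x / scn$z0 < 0 ||
      calib$cy - calib$f * half_y / scn$z0 < 0) {
    stop("surface extends outside the image frustum")
  }
  q <- function(x) if (is.finite(quant_steps)) round(x * quant_steps) / quant_steps else x

  z_at <- function(xy, depth) {
    scn$z0 + depth * indent_profile(scn, xy)
  }
  # invert pixel -> surface (x, y) by fixed-point iteration on depth
  pixel_surface <- function(depth) {
    uu <- rep(0:(w - 1L), each = h)
    vv <- rep(0:(h - 1L), w)
    z <- rep(scn$z0, length(uu))
    for (k in 1:3) {
      x <- (uu - calib$cx) * z / calib$f
      y <- (vv - calib$cy) * z / calib$f
      z <- z_at(cbind(x, y), depth)
    }
    x <- (uu - calib$cx) * z / calib$f
    y <- (vv - calib$cy) * z / calib$f
    on_surf <- abs(x) <= half_x & abs(y) <= half_y
    list(x = x, y = y, z = z, on = on_surf, u = uu, v = vv)
  }

  d_t <- indent_depth(scn, t)
  d_t1 <- indent_depth(scn, t + 1L)
  s_t <- pixel_surface(d_t)
  s_t1 <- pixel_surface(d_t1)

  to_mat <- function(vals, on) {
    vals[!on] <- NA_real_
    matrix(vals, h, w)  # filled column-major: v fastest, matches (row=v+1)
  }
  disparity_t <- to_mat(q(calib$f * calib$b / s_t$z), s_t$on)
  disparity_t1 <- to_mat(q(calib$f * calib$b / s_t1$z), s_t1$on)

  # material point under each pixel at frame t moves vertically; its new
  # projection gives the optical flow
  z_new <- z_at(cbind(s_t$x, s_t$y), d_t1)
  u_new <- calib$f * s_t$x / z_new + calib$cx
  v_new <- calib$f * s_t$y / z_new + calib$cy
  flow_uv <- array(0, c(h, w, 2L))
  flow_uv[, , 1L] <- to_mat(q(u_new - s_t$u), s_t$on)
  flow_uv[, , 2L] <- to_mat(q(v_new - s_t$v), s_t$on)

  mask_t <- mask_t1 <- NULL
  if (scn$occluder_width > 0) {
    mask_t <- occluder_mask(scn, occluder_state(scn, t))
    mask_t1 <- occluder_mask(scn, occluder_state(scn, t + 1L))
  }
  frame_observation(disparity_t, disparity_t1, flow_uv,
                    mask_t = mask_t, mask_t1 = mask_t1)
}

#' Mean per-vertex position error between two meshes
#'
#' @param mesh,reference `triangle_mesh` objects with identical vertex count.
#' @param subset optional vertex indices to restrict to.
#' @return mean Euclidean vertex error (mm).
#' @export
mean_vertex_error <- function(mesh, reference, subset = NULL) {
  stopifnot(nrow(mesh$vertices) == nrow(reference$vertices))
  d <- sqrt(rowSums((mesh$vertices - reference$vertices)^2))
  if (!is.null(subset)) d <- d[subset]
  mean(d)
}
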