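# Per-frame mesh optimization: dynamic term + differential-edge (or
# Laplacian) smoothness term, solved as constrained least squares with
# instrument depth bounds on occluded vertices.

#' Smoothness system of a mesh
#'
#' Builds the fixed part of the optimization model from the initial mesh: the
#' smoothness operator (differential edge matrix by default, graph Laplacian
#' as the denser baseline), its target delta coordinates computed from the
#' initial vertex positions, and the weight `alpha`. These stay identical for
#' the whole sequence.
#'
#' @param mesh0 the initial `triangle_mesh`.
#' @param alpha smoothness weight (default 1.5).
#' @param smoothness `"edge"` (differential edge matrix) or `"laplacian"`.
#' @return object of class `smoothness_system` with `S`, `delta`, `alpha`,
#'   `smoothness`, `components`.
#' @export
smoothness_system <- function(mesh0, alpha = 1.5,
                              smoothness = c("edge", "laplacian")) {
  stopifnot(inherits(mesh0, "triangle_mesh"), alpha > 0)
  smoothness <- match.arg(smoothness)
  S <- if (smoothness == "edge") {
    differential_edge_matrix(mesh0)
  } else {
    laplacian_matrix(mesh0)
  }
  structure(list(S = S, delta = as.matrix(S %*% mesh0$vertices),
                 alpha = alpha, smoothness = smoothness,
                 components = mesh_components(mesh0)),
            class = "smoothness_system")
}

#' Dynamic term of the mesh optimization model
#'
#' Selector and targets anchoring validly tracked vertices to their scene-flow
#' updated positions: row r of the selector picks valid vertex i(r) and the
#' target is `C_p[i(r), ] + F_s[i(r), ]`. Rows are ordered by ascending vertex
#' index.
#'
#' @param coords_prev N x 3 previous-frame vertex positions (mm).
#' @param flow a `scene_flow` with final (filtered) statuses.
#' @return list with `I_tilde` (sparse `N_valid` x N), `C_star`
#'   (`N_valid` x 3), `valid` (indices).
#' @export
build_dynamic_term <- function(coords_prev, flow) {
  coords_prev <- as_coord_matrix(coords_prev)
  stopifnot(inherits(flow, "scene_flow"),
            nrow(flow$vectors) == nrow(coords_prev))
  valid <- valid_vertices(flow)
  if (length(valid) == 0L) {
    stop("no valid vertices: the dynamic term is empty and the system is rank-deficient")
  }
  n <- nrow(coords_prev)
  I_tilde <- Matrix::sparseMatrix(i = seq_along(valid), j = valid, x = 1,
                                  dims = c(length(valid), n))
  C_star <- coords_prev[valid, , drop = FALSE] +
    flow$vectors[valid, , drop = FALSE]
  list(I_tilde = I_tilde, C_star = C_star, valid = valid)
}

#' Solve one frame of the mesh optimization model
#'
#' Minimizes `||I_tilde C - C_star||^2 + alpha^2 ||S C - delta||^2` column by
#' column. The x and y columns are unconstrained sparse least squares; the z
#' column additionally satisfies `z_i >= p_z_i + delta` for every occluded
#' vertex (the instrument constraint: occluded tissue must stay at or below
#' the instrument's depth), solved by an active-set method on the bound
#' constraints. Connected components of the mesh graph that contain no valid
#' vertex are frozen at their previous positions rather than solved, since
#' their sub-system is rank-deficient (translation-invariant).
#'
#' @param dyn dynamic term from [build_dynamic_term()].
#' @param esys a [smoothness_system()].
#' @param coords_prev N x 3 previous-frame positions (mm).
#' @param constraints an [occlusion_constraints()] or `NULL`.
#' @param tol feasibility/optimality tolerance of the active-set solve (mm).
#' @return N x 3 matrix of recovered vertex positions; attributes
#'   `residual_dynamic` and `residual_smooth` carry the per-term residual
#'   norms, `frozen` the frozen vertex indices.
#' @export
solve_frame <- function(dyn, esys, coords_prev, constraints = NULL,
                        tol = 1e-9) {
  coords_prev <- as_coord_matrix(coords_prev)
  n <- ncol(dyn$I_tilde)
  stopifnot(nrow(coords_prev) == n, ncol(esys$S) == n)
  comp <- esys$components
  valid_comp <- unique(comp[dyn$valid])
  frozen <- which(!comp %in% valid_comp)
  free <- setdiff(seq_len(n), frozen)

  A <- rbind(dyn$I_tilde, esys$alpha * esys$S)
  b <- rbind(dyn$C_star, esys$alpha * esys$delta)
  M <- Matrix::crossprod(A)
  Atb <- as.matrix(Matrix::crossprod(A, b))

  C <- coords_prev
  if (length(free) == 0L) return(finish_solution(C, A, b, dyn, esys, frozen))

  fixed_rhs <- function(fixed_idx, fixed_val, col) {
    rhs <- Atb[free, col]
    fx <- c(frozen, fixed_idx)
    fv <- c(coords_prev[frozen, col], fixed_val)
    if (length(fx)) {
      rhs <- rhs - as.numeric(M[free, fx, drop = FALSE] %*% fv)
    }
    rhs
  }

  # x and y: unconstrained
  for (col in 1:2) {
    Mff <- M[free, free, drop = FALSE]
    C[free, col] <- as.numeric(Matrix::solve(Mff, fixed_rhs(integer(), numeric(), col)))
  }

  # z: lower bounds on occluded free vertices
  lb_idx <- integer(); lb <- numeric()
  if (!is.null(constraints) && length(constraints$occluded)) {
    keep <- constraints$occluded %in% free
    lb_idx <- constraints$occluded[keep]
    lb <- constraints$p_z[keep] + constraints$delta
  }
  C[, 3L] <- solve_bounded_column(M, Atb[, 3L], free, frozen,
                                  coords_prev[, 3L], lb_idx, lb, tol)
  finish_solution(C, A, b, dyn, esys, frozen)
}

# active-set solve of min ||A x - b||^2 with x[lb_idx] >= lb, x[frozen] fixed
solve_bounded_column <- function(M, Atb, free, frozen, prev_col, lb_idx, lb,
                                 tol) {
  n <- length(prev_col)
  x <- prev_col
  active <- rep(FALSE, length(lb_idx))
  max_iter <- 10L + 2L * length(lb_idx)
  for (iter in seq_len(max_iter)) {
    clamp_idx <- lb_idx[active]
    clamp_val <- lb[active]
    solve_free <- setdiff(free, clamp_idx)
    fixed_idx <- c(frozen, clamp_idx)
    fixed_val <- c(prev_col[frozen], clamp_val)
    rhs <- Atb[solve_free]
    if (length(fixed_idx)) {
      rhs <- rhs - as.numeric(M[solve_free, fixed_idx, drop = FALSE] %*% fixed_val)
    }
    x[solve_free] <- as.numeric(Matrix::solve(M[solve_free, solve_free,
                                                drop = FALSE], rhs))
    x[clamp_idx] <- clamp_val
    if (length(lb_idx) == 0L) break
    viol <- !active & x[lb_idx] < lb - tol
    if (any(viol)) {
      active[viol] <- TRUE
      next
    }
    # KKT: at an active lower bound the objective gradient must be >= 0
    g <- 2 * (as.numeric(M[lb_idx[active], , drop = FALSE] %*% x) -
                Atb[lb_idx[active]])
    release <- which(active)[g < -tol]
    if (length(release) == 0L) break
    active[release[which.min(g[g < -tol])]] <- FALSE
  }
  x
}

finish_solution <- function(C, A, b, dyn, esys, frozen) {
  R <- as.matrix(A %*% C - b)
  nd <- nrow(dyn$C_star)
  attr(C, "residual_dynamic") <- sqrt(sum(R[seq_len(nd), ]^2))
  attr(C, "residual_smooth") <- sqrt(sum(R[-seq_len(nd), ]^2)) / esys$alpha
  attr(C, "frozen") <- frozen
  C
}

#' Recovery configuration
#'
#' @param alpha smoothness weight (default 1.5).
#' @param smoothness `"edge"` or `"laplacian"`.
#' @param filter apply the strain filter (default TRUE); `FALSE` reproduces
#'   the raw-flow failure mode for comparison.
#' @param constraint apply the instrument depth constraint (default TRUE).
#' @param raw_update if TRUE, bypass the optimization entirely and move each
#'   observed vertex by its raw scene flow vector (the naive baseline).
#' @param delta constraint margin (mm, default 0).
#' @param filter_config a [filter_config()].
#' @export
recover_config <- function(alpha = 1.5, smoothness = c("edge", "laplacian"),
                           filter = TRUE, constraint = TRUE,
                           raw_update = FALSE, delta = 0,
                           filter_config = meshdeform::filter_config()) {
  structure(list(alpha = alpha, smoothness = match.arg(smoothness),
                 filter = filter, constraint = constraint,
                 raw_update = raw_update, delta = delta,
                 filter_config = filter_config),
            class = "recover_config")
}

#' Recover a deforming surface over a sequence of frames
#'
#' Runs the full per-frame pipeline: obtain scene flow (given per-vertex or
#' composed from disparity + optical flow), filter it (instrument mask, then
#' strain analysis), derive occlusion depth bounds, and solve the mesh
#' optimization model. Frame 0 is the initial mesh; the smoothness system is
#' built once from it and reused for every frame, while the dynamic term
#' follows the running estimate. A frame whose solve fails is skipped with a
#' warning and the previous mesh carried forward.
#'
#' @param mesh0 initial `triangle_mesh`.
#' @param frames list of per-frame inputs. Each element is a list with either
#'   `flow` (a [scene_flow()]) or `obs` (a [frame_observation()]), plus
#'   optionally `instrument` (vertex indices or `list(mask =, calib =)`) and
#'   `instrument_points` (M x 3 matrix for depth bounds).
#' @param config a [recover_config()].
#' @param calib a [stereo_calibration()]; required in image mode or when
#'   instrument masks are given without their own calib.
#' @return object of class `deform_recovery`: `meshes` (list of
#'   `triangle_mesh`, element 1 = initial mesh), `log` (per-frame tibble),
#'   `config`.
#' @export
run_sequence <- function(mesh0, frames, config = recover_config(),
                         calib = NULL) {
  stopifnot(inherits(mesh0, "triangle_mesh"))
  esys <- smoothness_system(mesh0, alpha = config$alpha,
                            smoothness = config$smoothness)
  rings <- neighborhoods(mesh0, config$filter_config$ring)
  meshes <- vector("list", length(frames) + 1L)
  meshes[[1L]] <- mesh0
  C_p <- mesh0$vertices
  logs <- vector("list", length(frames))
  for (t in seq_along(frames)) {
    fr <- frames[[t]]
    mesh_prev <- meshes[[t]]
    step <- tryCatch(
      recover_one_frame(mesh_prev, fr, esys, rings, config, calib),
      error = function(e) e
    )
    if (inherits(step, "error")) {
      warning("frame ", t, " skipped (", conditionMessage(step),
              "); carrying previous mesh forward", call. = FALSE)
      meshes[[t + 1L]] <- mesh_prev
      logs[[t]] <- tibble::tibble(
        frame = t, skipped = TRUE, n_valid = NA_integer_,
        n_occluded = NA_integer_, residual_dynamic = NA_real_,
        residual_smooth = NA_real_
      )
      next
    }
    meshes[[t + 1L]] <- step$mesh
    logs[[t]] <- step$log
  }
  structure(list(meshes = meshes, log = do.call(rbind, logs), config = config),
            class = "deform_recovery")
}

recover_one_frame <- function(mesh_prev, fr, esys, rings, config, calib) {
  flow <- if (!is.null(fr$flow)) {
    fr$flow
  } else if (!is.null(fr$obs)) {
    if (is.null(calib)) stop("image-mode frame requires a calib")
    compose_scene_flow(mesh_prev, fr$obs, calib)
  } else {
    stop("frame has neither 'flow' nor 'obs'")
  }
  if (nrow(flow$vectors) != nrow(mesh_prev$vertices)) {
    stop("flow size does not match mesh")
  }

  if (config$raw_update) {
    C <- mesh_prev$vertices
    obs <- flow$status != "vacant"
    C[obs, ] <- C[obs, ] + flow$vectors[obs, ]
    mesh <- mesh_prev
    mesh$vertices <- C
    return(list(mesh = mesh,
                log = tibble::tibble(frame = NA_integer_, skipped = FALSE,
                                     n_valid = sum(obs), n_occluded = 0L,
                                     residual_dynamic = 0,
                                     residual_smooth = NA_real_)))
  }

  instrument <- fr$instrument
  if (is.list(instrument) && !is.null(instrument$mask) &&
      is.null(instrument$calib)) {
    instrument$calib <- calib
  }
  if (config$filter) {
    flow <- filter_scene_flow(mesh_prev, flow, config$filter_config,
                              instrument = instrument, rings = rings)
  } else if (!is.null(instrument)) {
    # even unfiltered, instrument vertices carry tool motion, not tissue
    status <- flow$status
    status[resolve_instrument_vertices(mesh_prev, instrument)] <- "instrument"
    flow <- scene_flow(flow$vectors, status)
  }

  constraints <- NULL
  if (config$constraint && !is.null(fr$instrument_points)) {
    occ <- resolve_instrument_vertices(mesh_prev, instrument)
    if (length(occ)) {
      constraints <- compute_depth_bounds(occ, fr$instrument_points,
                                          mesh_prev$vertices,
                                          delta = config$delta)
    }
  }

  dyn <- build_dynamic_term(mesh_prev$vertices, flow)
  C <- solve_frame(dyn, esys, mesh_prev$vertices, constraints)
  mesh <- mesh_prev
  mesh$vertices <- as_coord_matrix(C)
  list(mesh = mesh,
       log = tibble::tibble(
         frame = NA_integer_, skipped = FALSE,
         n_valid = length(dyn$valid),
         n_occluded = if (is.null(constraints)) 0L else length(constraints$occluded),
         residual_dynamic = attr(C, "residual_dynamic"),
         residual_smooth = attr(C, "residual_smooth")
       ))
}

#' @export
print.deform_recovery <- function(x, ...) {
  cat("deform_recovery:", length(x$meshes) - 1L, "frames,",
      nrow(x$meshes[[1L]]$vertices), "vertices,",
      "smoothness =", x$config$smoothness,
      "(alpha =", paste0(x$config$alpha, ")"), "\n")
  invisible(x)
}

#' Tidy a deformation recovery run
#'
#' @param x a `deform_recovery`.
#' @param ... unused.
#' @return the per-frame log tibble with `frame` filled in.
#' @export
tidy.deform_recovery <- function(x, ...) {
  lg <- x$log
  lg$frame <- seq_len(nrow(lg))
  lg
}

#' @export
glance.deform_recovery <- function(x, ...) {
  lg <- tidy.deform_recovery(x)
  tibble::tibble(
    n_frames = nrow(lg),
    n_skipped = sum(lg$skipped),
    mean_valid = mean(lg$n_valid, na.rm = TRUE),
    mean_residual_dynamic = mean(lg$residual_dynamic, na.rm = TRUE),
    mean_residual_smooth = mean(lg$residual_smooth, na.rm = TRUE)
  )
}

#' Plot per-frame residuals of a recovery run
#'
#' @param object a `deform_recovery`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.deform_recovery <- function(object, ...) {
  lg <- tidy.deform_recovery(object)
  df <- rbind(
    data.frame(frame = lg$frame, residual = lg$residual_dynamic,
               term = "dynamic"),
    data.frame(frame = lg$frame, residual = lg$residual_smooth,
               term = "smoothness")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = frame, y = residual, colour = term)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "frame", y = "residual norm (mm)", colour = NULL)
}
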