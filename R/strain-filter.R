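# Vertex-wise least-squares (VWLS) estimation of displacement gradients,
# infinitesimal strain analysis, and strain-based scene flow filtering.

#' Strain filter configuration
#'
#' @param eps_t strain threshold above which a vertex's flow is an outlier
#'   (dimensionless; default 1, i.e. 100% strain).
#' @param ring neighborhood ring order k for the local fit (default 2).
#' @param min_neighbors minimum usable neighbors for a determined fit
#'   (default 6).
#' @param rcond_drop relative singular-value cutoff: neighborhood directions
#'   with spread below this fraction of the largest are truncated, so fits on
#'   (near-)coplanar surface patches reduce to tangent-plane surface-strain
#'   fits instead of amplifying noise along the unresolved normal
#'   (default 0.05).
#' @param robust_iter robust reweighting iterations (Tukey bisquare) of the
#'   local fit; 0 gives plain OLS (default 3).
#' @param tukey_c bisquare cutoff as a multiple of the robust residual scale
#'   (default 6).
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(eps_t = 1, ring = 2L, min_neighbors = 6L,
                          rcond_drop = 0.05, robust_iter = 3L, tukey_c = 6) {
  stopifnot(eps_t > 0, ring >= 1L, min_neighbors >= 3L,
            rcond_drop >= 0, robust_iter >= 0L, tukey_c > 0)
  structure(list(eps_t = eps_t, ring = as.integer(ring),
                 min_neighbors = as.integer(min_neighbors),
                 rcond_drop = rcond_drop, robust_iter = as.integer(robust_iter),
                 tukey_c = tukey_c),
            class = "filter_config")
}

#' k-ring vertex neighborhoods of a mesh
#'
#' @param mesh a `triangle_mesh`.
#' @param order ring order k (graph distance).
#' @return list of integer vectors, one per vertex, of the neighbors within
#'   `order` hops (self excluded).
#' @export
neighborhoods <- function(mesh, order = 2L) {
  n <- nrow(mesh$vertices)
  g <- igraph::graph_from_edgelist(mesh$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  lapply(igraph::ego(g, order = order, mindist = 1L), as.integer)
}

# Robust local affine fit of the displacement field around one vertex.
# Returns list(G, resid, ok, reason). coords are previous-frame positions.
vwls_fit <- function(i, nbrs, coords, vectors, usable, config) {
  nb <- nbrs[usable[nbrs]]
  if (length(nb) < config$min_neighbors) {
    return(list(ok = FALSE, reason = "too_few_neighbors"))
  }
  idx <- c(i, nb)
  X <- coords[idx, , drop = FALSE]
  Y <- vectors[idx, , drop = FALSE]
  Xc <- sweep(X, 2L, colMeans(X))
  sv <- svd(Xc)
  keep <- sv$d >= config$rcond_drop * sv$d[1L] & sv$d > 1e-12
  if (sum(keep) < 2L) {
    return(list(ok = FALSE, reason = "degenerate_neighborhood"))
  }
  Vr <- sv$v[, keep, drop = FALSE]
  Tm <- Xc %*% Vr
  Z <- cbind(1, Tm)
  m <- nrow(Z)
  p <- ncol(Z)
  w <- rep(1, m)
  beta <- NULL
  for (it in 0:config$robust_iter) {
    sw <- sqrt(w)
    fit <- .lm.fit(Z * sw, Y * sw)
    beta <- matrix(0, p, 3L)
    beta[fit$pivot, ] <- fit$coefficients
    if (it == config$robust_iter) break
    R <- Y - Z %*% beta
    rn <- sqrt(rowSums(R^2))
    s <- stats::median(rn)
    if (!is.finite(s) || s < 1e-10 * (1 + max(abs(Y)))) break
    u <- rn / (config$tukey_c * s)
    w <- numeric(m)
    lo <- u < 1
    w[lo] <- (1 - u[lo]^2)^2
    if (sum(w > 0) < config$min_neighbors) break
  }
  if (any(!is.finite(beta))) return(list(ok = FALSE, reason = "singular_fit"))
  # gradient rows: d(component)/d(x,y,z) mapped back from the reduced basis
  G <- t(Vr %*% beta[-1L, , drop = FALSE])
  pred_i <- beta[1L, ] + Tm[1L, , drop = FALSE] %*% beta[-1L, , drop = FALSE]
  list(ok = TRUE, G = G, resid = as.numeric(Y[1L, ] - pred_i))
}

#' Estimate the displacement gradient at one vertex (VWLS)
#'
#' Fits, for each displacement component, an affine model over the vertex and
#' its k-ring neighbors (positions taken from `coords`, normally the
#' previous-frame mesh) by iteratively reweighted least squares with Tukey
#' bisquare weights; the gradient rows are the fitted spatial slopes.
#' Directions in which the neighborhood has (nearly) no spread are truncated
#' (see [filter_config()]), so on a locally planar patch the fit estimates the
#' in-surface gradient and sets the out-of-plane derivative to zero. Returns
#' `NULL` (undetermined) when fewer than `min_neighbors` usable neighbors
#' remain or the surviving spread is less than two-dimensional (e.g.
#' collinear neighborhoods).
#'
#' @param mesh a `triangle_mesh` (previous-frame positions).
#' @param flow a `scene_flow` on the mesh vertices.
#' @param vertex vertex index (1-based).
#' @param config a [filter_config()].
#' @param rings optional precomputed [neighborhoods()].
#' @return list with `G` (3 x 3 gradient, rows = d(u,v,w)), `resid` (the
#'   vertex's own 3-vector residual from the local fit, mm), or `NULL` if
#'   undetermined.
#' @export
estimate_gradient_vwls <- function(mesh, flow, vertex, config = filter_config(),
                                   rings = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(flow, "scene_flow"))
  if (is.null(rings)) rings <- neighborhoods(mesh, config$ring)
  usable <- !flow$status %in% c("vacant", "instrument")
  fit <- vwls_fit(vertex, rings[[vertex]], mesh$vertices, flow$vectors,
                  usable, config)
  if (!fit$ok) return(NULL)
  fit[c("G", "resid")]
}

#' Infinitesimal strain from a displacement gradient
#'
#' The infinitesimal strain tensor is the symmetric part of the displacement
#' gradient, `eps = (G + t(G)) / 2`; the principal strains are its
#' eigenvalues and the maximal local strain is the largest eigenvalue in
#' absolute value. The antisymmetric part of `G` (infinitesimal rotation)
#' does not contribute.
#'
#' @param G 3 x 3 displacement gradient, rows = d(u,v,w)/d(x,y,z).
#' @return list with `epsilon` (symmetric 3 x 3), `principal` (eigenvalues,
#'   descending), `eps_max`.
#' @export
strain_from_gradient <- function(G) {
  G <- as.matrix(G)
  if (!identical(dim(G), c(3L, 3L)) || any(!is.finite(G))) {
    stop("G must be a finite 3 x 3 matrix")
  }
  eps <- (G + t(G)) / 2
  ev <- sort(eigen(eps, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  list(epsilon = eps, principal = ev, eps_max = max(abs(ev)))
}

#' Per-vertex strain field of a scene flow
#'
#' Runs the VWLS gradient estimate at every vertex that carries a usable flow
#' vector and derives the strain outlier score: the maximal absolute principal
#' strain of the fitted gradient, combined with the vertex's own fit residual
#' normalized by the local mean edge length (a gross spike at a vertex
#' produces a large normalized residual even when it barely tilts the local
#' affine fit).
#'
#' @inheritParams estimate_gradient_vwls
#' @return object of class `strain_field`: tibble-backed with per-vertex
#'   `eps_max`, `resid_strain`, `score`, `undetermined`, plus the list of
#'   gradients in `attr(, "gradients")`.
#' @export
strain_field <- function(mesh, flow, config = filter_config(), rings = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(flow, "scene_flow"))
  n <- nrow(mesh$vertices)
  if (nrow(flow$vectors) != n) stop("flow/mesh size mismatch")
  if (is.null(rings)) rings <- neighborhoods(mesh, config$ring)
  usable <- !flow$status %in% c("vacant", "instrument")
  h <- local_edge_length(mesh)
  eps_max <- rep(NA_real_, n)
  resid_strain <- rep(NA_real_, n)
  undet <- rep(FALSE, n)
  grads <- vector("list", n)
  coords <- mesh$vertices
  vecs <- flow$vectors
  for (i in which(usable)) {
    fit <- vwls_fit(i, rings[[i]], coords, vecs, usable, config)
    if (!fit$ok) {
      undet[i] <- TRUE
      next
    }
    grads[[i]] <- fit$G
    st <- strain_from_gradient(fit$G)
    eps_max[i] <- st$eps_max
    resid_strain[i] <- sqrt(sum(fit$resid^2)) / h[i]
  }
  tab <- tibble::tibble(
    vertex = seq_len(n),
    eps_max = eps_max,
    resid_strain = resid_strain,
    score = pmax(eps_max, resid_strain),
    undetermined = undet,
    status = flow$status
  )
  structure(tab, class = c("strain_field", class(tab)), gradients = grads)
}

# mean distance from each vertex to its 1-ring neighbors (mm)
local_edge_length <- function(mesh) {
  e <- mesh$edges
  d <- sqrt(rowSums((mesh$vertices[e[, 1L], , drop = FALSE] -
                       mesh$vertices[e[, 2L], , drop = FALSE])^2))
  n <- nrow(mesh$vertices)
  s <- rep(0, n); k <- rep(0L, n)
  for (c in 1:2) {
    t1 <- tapply(d, e[, c], sum)
    s[as.integer(names(t1))] <- s[as.integer(names(t1))] + t1
    t2 <- tapply(d, e[, c], length)
    k[as.integer(names(t2))] <- k[as.integer(names(t2))] + t2
  }
  out <- ifelse(k > 0, s / pmax(k, 1L), NA_real_)
  out[!is.finite(out) | out <= 0] <- mean(d)
  out
}

#' Filter a scene flow field by instrument mask and strain analysis
#'
#' Applies the two filtering rules in order: (1) vertices whose projection
#' falls inside the instrument mask are marked `"instrument"` (mask takes
#' precedence over strain); (2) among the remaining non-vacant vertices, those
#' whose strain outlier score exceeds `eps_t` — or whose local gradient is
#' undetermined — are marked `"strain_outlier"`. Vectors are preserved; only
#' statuses change, so the filter is idempotent.
#'
#' @param mesh `triangle_mesh` with previous-frame positions.
#' @param flow a `scene_flow`.
#' @param config a [filter_config()].
#' @param instrument either `NULL`, an integer vector of instrument vertex
#'   indices, or a list `list(mask =, calib =)` with a logical pixel mask and
#'   a [stereo_calibration()]; vertices projecting onto mask pixels are
#'   flagged.
#' @param rings optional precomputed [neighborhoods()].
#' @return a `scene_flow` with updated statuses; the per-vertex
#'   [strain_field()] report is attached as `attr(, "report")`.
#' @export
filter_scene_flow <- function(mesh, flow, config = filter_config(),
                              instrument = NULL, rings = NULL) {
  stopifnot(inherits(flow, "scene_flow"))
  status <- flow$status
  inst_idx <- resolve_instrument_vertices(mesh, instrument)
  status[inst_idx] <- "instrument"
  work <- scene_flow(flow$vectors, status)
  sf <- strain_field(mesh, work, config, rings = rings)
  candidate <- !status %in% c("vacant", "instrument")
  bad <- candidate & (sf$undetermined | (!is.na(sf$score) & sf$score > config$eps_t))
  status[bad] <- "strain_outlier"
  status[candidate & !bad] <- "valid"
  out <- scene_flow(flow$vectors, status)
  attr(out, "report") <- sf
  out
}

resolve_instrument_vertices <- function(mesh, instrument) {
  if (is.null(instrument)) return(integer())
  if (is.numeric(instrument)) return(as.integer(instrument))
  if (is.list(instrument) && !is.null(instrument$mask)) {
    if (is.null(instrument$calib)) stop("instrument mask requires a calib")
    return(vertices_on_mask(mesh$vertices, instrument$mask, instrument$calib))
  }
  stop("instrument must be NULL, vertex indices, or list(mask=, calib=)")
}

#' Write a strain filter report as CSV
#'
#' Columns: vertex id, status, eps_max, resid_strain, score.
#' @param report a `strain_field` (e.g. `attr(filtered, "report")`).
#' @param path CSV path.
#' @export
write_filter_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

#' @export
tidy.strain_field <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.strain_field <- function(x, ...) {
  tibble::tibble(
    n_vertex = nrow(x),
    n_undetermined = sum(x$undetermined),
    mean_eps_max = mean(x$eps_max, na.rm = TRUE),
    max_score = suppressWarnings(max(x$score, na.rm = TRUE))
  )
}
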