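# Mesh data structure, connectivity, and the differential edge system.

#' Triangle surface mesh
#'
#' Constructs a triangle mesh in left-camera coordinates (mm; x right, y down,
#' z along the optical axis, increasing with depth). Vertex indices are 1-based
#' internally, following R convention; file readers and writers convert from
#' the 0-based (PLY) or 1-based (OBJ) on-disk conventions.
#'
#' @param vertices numeric N x 3 matrix of vertex coordinates (mm).
#' @param faces integer M x 3 matrix of vertex indices (1-based).
#' @return an object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, and `edges` (unique undirected edges, each row `(j, k)` with
#'   `j < k`, lexicographically sorted).
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as_coord_matrix(vertices, "vertices")
  faces <- as_face_matrix(faces)
  n <- nrow(vertices)
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > n) {
      stop("face indices out of range [1, ", n, "]")
    }
  }
  edges <- build_edges(faces)
  mesh <- structure(
    list(vertices = vertices, faces = faces, edges = edges),
    class = "triangle_mesh"
  )
  if (nrow(faces) > 0L) {
    ncomp <- n_mesh_components(mesh)
    if (ncomp > 1L) {
      message("triangle_mesh: edge graph has ", ncomp, " connected components")
    }
  }
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("triangle_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "faces,", nrow(x$edges), "edges\n")
  invisible(x)
}

as_coord_matrix <- function(x, what = "points") {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop(what, " must be an N x 3 matrix")
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

as_face_matrix <- function(faces) {
  faces <- as.matrix(faces)
  if (length(faces) == 0L) return(matrix(integer(), 0L, 3L))
  if (ncol(faces) != 3L) stop("faces must be an M x 3 matrix of vertex indices")
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  degen <- faces[, 1L] == faces[, 2L] | faces[, 1L] == faces[, 3L] |
    faces[, 2L] == faces[, 3L]
  if (any(degen)) {
    stop("degenerate face(s) with repeated vertex indices at row(s): ",
         paste(utils::head(which(degen), 5L), collapse = ", "))
  }
  faces
}

#' Extract unique undirected edges from a face list
#'
#' Each undirected edge appears exactly once as `(j, k)` with `j < k`; rows are
#' sorted lexicographically, so the result is invariant to face ordering.
#'
#' @param faces M x 3 integer matrix of 1-based vertex indices, or a
#'   `triangle_mesh`.
#' @return integer `n_edge` x 2 matrix.
#' @export
build_edges <- function(faces) {
  if (inherits(faces, "triangle_mesh")) return(faces$edges)
  faces <- as_face_matrix(faces)
  if (nrow(faces) == 0L) return(matrix(integer(), 0L, 2L))
  a <- rbind(faces[, c(1L, 2L), drop = FALSE],
             faces[, c(2L, 3L), drop = FALSE],
             faces[, c(1L, 3L), drop = FALSE])
  e <- cbind(pmin(a[, 1L], a[, 2L]), pmax(a[, 1L], a[, 2L]))
  e <- unique(e)
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}

#' Differential edge matrix
#'
#' Sparse signed edge-incidence matrix E: row i for edge `(j, k)` (with
#' `j < k`) carries +1 in column j and -1 in column k. The product `E %*% C`
#' gives the per-edge difference vectors (delta coordinates) of vertex
#' coordinates `C`, and `crossprod(E)` equals the combinatorial graph
#' Laplacian. Each row sums exactly to zero, so rigid translations lie in the
#' null space.
#'
#' @param edges `n_edge` x 2 integer matrix as from [build_edges()], or a
#'   `triangle_mesh`.
#' @param n number of vertices (columns). Defaults to the mesh vertex count
#'   when a mesh is supplied.
#' @return a `dgCMatrix` of dimension `n_edge` x `n`.
#' @export
differential_edge_matrix <- function(edges, n = NULL) {
  ed <- resolve_edges(edges, n)
  Matrix::sparseMatrix(
    i = rep(seq_len(nrow(ed$edges)), 2L),
    j = c(ed$edges[, 1L], ed$edges[, 2L]),
    x = rep(c(1, -1), each = nrow(ed$edges)),
    dims = c(nrow(ed$edges), ed$n)
  )
}

#' Combinatorial graph Laplacian
#'
#' Uniform-weight Laplacian `L = D - A` of the mesh edge graph; identical to
#' `crossprod(differential_edge_matrix(...))`. Provided as the denser
#' smoothness operator that the differential edge matrix replaces.
#'
#' @inheritParams differential_edge_matrix
#' @return a sparse symmetric `n` x `n` matrix.
#' @export
laplacian_matrix <- function(edges, n = NULL) {
  ed <- resolve_edges(edges, n)
  e <- ed$edges
  A <- Matrix::sparseMatrix(
    i = c(e[, 1L], e[, 2L]), j = c(e[, 2L], e[, 1L]),
    x = 1, dims = c(ed$n, ed$n)
  )
  deg <- Matrix::rowSums(A)
  Matrix::Diagonal(ed$n, deg) - A
}

resolve_edges <- function(edges, n) {
  if (inherits(edges, "triangle_mesh")) {
    if (is.null(n)) n <- nrow(edges$vertices)
    edges <- edges$edges
  }
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(integer(), 0L, 2L)
  if (ncol(edges) != 2L) stop("edges must be an n_edge x 2 matrix")
  storage.mode(edges) <- "integer"
  if (is.null(n)) stop("number of vertices 'n' required")
  if (nrow(edges) > 0L && (min(edges) < 1L || max(edges) > n)) {
    stop("edge indices out of range [1, ", n, "]")
  }
  list(edges = edges, n = as.integer(n))
}

#' Delta coordinates of a mesh
#'
#' Computes `delta_E = E %*% C0`, the per-edge difference vectors of the
#' initial mesh. These targets stay fixed over the whole sequence: the
#' smoothness term pulls every recovered frame's edge vectors back toward the
#' initial configuration.
#'
#' @param E differential edge matrix (`n_edge` x N).
#' @param coords N x 3 vertex coordinates of the initial mesh (mm).
#' @return dense `n_edge` x 3 matrix.
#' @export
delta_coordinates <- function(E, coords) {
  coords <- as_coord_matrix(coords)
  if (ncol(E) != nrow(coords)) {
    stop("dimension mismatch: E has ", ncol(E), " columns but coords has ",
         nrow(coords), " rows")
  }
  as.matrix(E %*% coords)
}

#' Connected components of the mesh edge graph
#'
#' @param mesh a `triangle_mesh`.
#' @return integer vector of length N giving each vertex's component id.
#' @export
mesh_components <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  n <- nrow(mesh$vertices)
  g <- igraph::graph_from_edgelist(mesh$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  as.integer(igraph::components(g)$membership)
}

n_mesh_components <- function(mesh) {
  if (nrow(mesh$vertices) == 0L) return(0L)
  max(mesh_components(mesh))
}

#' Mean edge length of a mesh (mm)
#'
#' @param mesh a `triangle_mesh`.
#' @param coords optional alternative vertex coordinates (defaults to the
#'   mesh's own).
#' @export
mean_edge_length <- function(mesh, coords = mesh$vertices) {
  e <- mesh$edges
  if (nrow(e) == 0L) return(NA_real_)
  d <- coords[e[, 1L], , drop = FALSE] - coords[e[, 2L], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' Initialize a surface mesh from a 3D point cloud
#'
#' Builds the initial tissue surface mesh from reconstructed 3D points by
#' camera-view height-field gridding: points are binned on a regular grid in
#' the x-y (image-aligned) plane, each occupied cell receives the median depth
#' of its points, sparsely populated cells are dropped, and the occupied cells
#' are triangulated. An optional uniform Laplacian smoothing pass regularizes
#' the depth field. The approach assumes the surface is a depth field as seen
#' from the camera, which holds for endoscopic tissue surfaces.
#'
#' @param points N x 3 matrix of reconstructed points (mm, camera frame).
#' @param spacing grid cell size in mm (default 1).
#' @param margin bounding-box expansion in mm applied before gridding
#'   (default 0).
#' @param min_points minimum points per cell for the cell to be kept
#'   (default 1).
#' @param smooth_iter uniform Laplacian smoothing iterations on cell depths
#'   (default 1).
#' @param min_total minimum number of input points (default 100).
#' @return a `triangle_mesh`.
#' @export
mesh_from_points <- function(points, spacing = 1, margin = 0,
                             min_points = 1L, smooth_iter = 1L,
                             min_total = 100L) {
  points <- as_coord_matrix(points)
  if (nrow(points) < min_total) {
    stop("mesh_from_points: need at least ", min_total, " points, got ",
         nrow(points))
  }
  if (spacing <= 0) stop("spacing must be positive")
  x0 <- min(points[, 1L]) - margin
  y0 <- min(points[, 2L]) - margin
  nx <- max(2L, ceiling((max(points[, 1L]) + margin - x0) / spacing) + 1L)
  ny <- max(2L, ceiling((max(points[, 2L]) + margin - y0) / spacing) + 1L)
  ix <- pmin(nx, pmax(1L, as.integer(round((points[, 1L] - x0) / spacing)) + 1L))
  iy <- pmin(ny, pmax(1L, as.integer(round((points[, 2L] - y0) / spacing)) + 1L))
  cell <- (iy - 1L) * nx + ix
  cnt <- tabulate(cell, nbins = nx * ny)
  zmed <- rep(NA_real_, nx * ny)
  med <- tapply(points[, 3L], cell, stats::median)
  zmed[as.integer(names(med))] <- med
  keep <- cnt >= min_points & !is.na(zmed)
  if (sum(keep) < 4L) stop("mesh_from_points: too few occupied grid cells")

  Z <- matrix(zmed, nx, ny)
  K <- matrix(keep, nx, ny)
  for (it in seq_len(smooth_iter)) {
    Z <- smooth_heightfield_once(Z, K)
  }

  # vertex per kept cell
  vid <- matrix(0L, nx, ny)
  vid[K] <- seq_len(sum(K))
  gx <- (row(Z)[K] - 1L) * spacing + x0
  gy <- (col(Z)[K] - 1L) * spacing + y0
  verts <- cbind(gx, gy, Z[K])

  faces <- grid_cell_faces(vid, nx, ny)
  if (nrow(faces) == 0L) stop("mesh_from_points: no complete cells to triangulate")
  triangle_mesh(verts, faces)
}

smooth_heightfield_once <- function(Z, K) {
  nx <- nrow(Z); ny <- ncol(Z)
  acc <- matrix(0, nx, ny); wt <- matrix(0, nx, ny)
  shift <- function(M, dx, dy) {
    out <- matrix(NA_real_, nx, ny)
    xs <- seq_len(nx) - dx; ys <- seq_len(ny) - dy
    ok_x <- xs >= 1 & xs <= nx; ok_y <- ys >= 1 & ys <= ny
    out[ok_x, ok_y] <- M[xs[ok_x], ys[ok_y]]
    out
  }
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    Zn <- shift(Z, d[1], d[2]); Kn <- shift(K * 1, d[1], d[2])
    use <- !is.na(Zn) & !is.na(Kn) & Kn > 0
    acc[use] <- acc[use] + Zn[use]
    wt[use] <- wt[use] + 1
  }
  upd <- K & wt > 0
  Z[upd] <- 0.5 * Z[upd] + 0.5 * acc[upd] / wt[upd]
  Z
}

grid_cell_faces <- function(vid, nx, ny) {
  # two triangles per 2x2 block of kept cells, diagonal from (i,j) to (i+1,j+1)
  i <- rep(seq_len(nx - 1L), ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  v00 <- vid[cbind(i, j)]; v10 <- vid[cbind(i + 1L, j)]
  v01 <- vid[cbind(i, j + 1L)]; v11 <- vid[cbind(i + 1L, j + 1L)]
  ok <- v00 > 0L & v10 > 0L & v01 > 0L & v11 > 0L
  rbind(
    cbind(v00[ok], v10[ok], v11[ok]),
    cbind(v00[ok], v11[ok], v01[ok])
  )
}

#' Regular grid mesh
#'
#' Convenience constructor for a rectangular grid surface mesh of
#' `nx` x `ny` vertices with given spacing, lying at constant depth `z`.
#' Used as the synthetic phantom base surface.
#'
#' @param nx,ny number of vertices along x and y.
#' @param spacing vertex spacing (mm).
#' @param z depth of the plane (mm), or a length-`nx*ny` vector.
#' @param center x/y center of the grid (mm), length-2.
#' @return a `triangle_mesh`.
#' @export
grid_mesh <- function(nx, ny, spacing = 1, z = 100, center = c(0, 0)) {
  stopifnot(nx >= 2L, ny >= 2L, spacing > 0)
  xs <- (seq_len(nx) - (nx + 1) / 2) * spacing + center[1L]
  ys <- (seq_len(ny) - (ny + 1) / 2) * spacing + center[2L]
  verts <- cbind(rep(xs, ny), rep(ys, each = nx), z)
  vid <- matrix(seq_len(nx * ny), nx, ny)
  triangle_mesh(verts, grid_cell_faces(vid, nx, ny))
}
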