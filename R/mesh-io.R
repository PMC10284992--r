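# Mesh file I/O: PLY (ascii and binary little-endian) and Wavefront OBJ.
# Indices are 0-based in PLY and 1-based in OBJ on disk; both map to the
# package's 1-based internal convention.

#' Read a mesh from PLY or OBJ
#'
#' @param path file path; format chosen by extension (`.ply` / `.obj`).
#' @return a `triangle_mesh`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = read_ply(path),
    obj = read_obj(path),
    stop("unsupported mesh format: .", ext)
  )
}

#' Write a mesh to PLY or OBJ
#'
#' @param mesh a `triangle_mesh`.
#' @param path output path; format chosen by extension.
#' @param binary for PLY, write `binary_little_endian` (default) or ascii.
#' @export
write_mesh <- function(mesh, path, binary = TRUE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = write_ply(mesh, path, binary = binary),
    obj = write_obj(mesh, path),
    stop("unsupported mesh format: .", ext)
  )
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (length(magic) == 0L || magic != "ply") {
    stop("malformed PLY: missing 'ply' magic line in ", path)
  }
  fmt <- NULL; nvert <- NULL; nface <- NULL
  vprops <- character(); in_elem <- ""
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("malformed PLY: header ended before 'end_header'")
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(tok) == 0L) next
    if (tok[1L] == "comment") next
    if (tok[1L] == "format") {
      fmt <- tok[2L]
      if (!fmt %in% c("ascii", "binary_little_endian")) {
        stop("unsupported PLY format: ", fmt)
      }
    } else if (tok[1L] == "element") {
      in_elem <- tok[2L]
      if (tok[2L] == "vertex") nvert <- as.integer(tok[3L])
      if (tok[2L] == "face") nface <- as.integer(tok[3L])
    } else if (tok[1L] == "property") {
      if (in_elem == "vertex") {
        if (tok[2L] == "list") stop("malformed PLY: list property on vertex element")
        if (!tok[2L] %in% c("float", "float32", "double", "float64")) {
          stop("unsupported PLY vertex property type: ", tok[2L])
        }
        vprops <- c(vprops, tok[3L])
      }
    } else if (tok[1L] == "end_header") break
  }
  if (is.null(fmt)) stop("malformed PLY: no format line")
  if (is.null(nvert)) stop("malformed PLY: no vertex element")
  if (!all(c("x", "y", "z") %in% vprops)) {
    stop("malformed PLY: vertex element lacks x/y/z properties")
  }
  if (is.null(nface)) nface <- 0L
  np <- length(vprops)
  if (fmt == "ascii") {
    txt <- readLines(con)
    if (length(txt) < nvert + nface) stop("malformed PLY: truncated body")
    vdat <- scan(text = txt[seq_len(nvert)], quiet = TRUE)
    if (length(vdat) != nvert * np) stop("malformed PLY: vertex data size mismatch")
    V <- matrix(vdat, nvert, np, byrow = TRUE)
    faces <- matrix(integer(), 0L, 3L)
    if (nface > 0L) {
      fdat <- lapply(txt[nvert + seq_len(nface)], function(s) {
        v <- scan(text = s, quiet = TRUE)
        if (length(v) < 1L || v[1L] != 3L) {
          stop("malformed PLY: only triangular faces supported")
        }
        v[2:4]
      })
      faces <- do.call(rbind, fdat)
    }
  } else {
    vals <- readBin(con, "double", n = nvert * np, size = 4L, endian = "little")
    if (length(vals) != nvert * np) stop("malformed PLY: truncated vertex data")
    V <- matrix(vals, nvert, np, byrow = TRUE)
    faces <- matrix(integer(), 0L, 3L)
    if (nface > 0L) {
      faces <- matrix(0L, nface, 3L)
      for (i in seq_len(nface)) {
        k <- readBin(con, "integer", n = 1L, size = 1L, signed = FALSE)
        if (length(k) == 0L || k != 3L) {
          stop("malformed PLY: only triangular faces supported (face ", i, ")")
        }
        idx <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
        if (length(idx) != 3L) stop("malformed PLY: truncated face data")
        faces[i, ] <- idx
      }
    }
  }
  cols <- match(c("x", "y", "z"), vprops)
  triangle_mesh(V[, cols, drop = FALSE], faces + 1L)
}

write_ply <- function(mesh, path, binary = TRUE) {
  V <- mesh$vertices; Fc <- mesh$faces
  hdr <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    paste("element vertex", nrow(V)),
    "property float x", "property float y", "property float z",
    paste("element face", nrow(Fc)),
    "property list uchar int vertex_indices",
    "end_header"
  )
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(as.numeric(t(V)), con, size = 4L, endian = "little")
    if (nrow(Fc) > 0L) {
      for (i in seq_len(nrow(Fc))) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(Fc[i, ] - 1L), con, size = 4L, endian = "little")
      }
    }
  } else {
    vl <- apply(V, 1L, function(r) paste(format(r, digits = 9L, trim = TRUE),
                                         collapse = " "))
    fl <- if (nrow(Fc) > 0L) {
      apply(Fc - 1L, 1L, function(r) paste(c(3L, r), collapse = " "))
    } else character()
    writeLines(c(hdr, vl, fl), path)
  }
  invisible(path)
}

read_obj <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  vln <- ln[startsWith(ln, "v ")]
  fln <- ln[startsWith(ln, "f ")]
  if (length(vln) == 0L) stop("malformed OBJ: no vertex ('v') lines in ", path)
  V <- t(vapply(strsplit(sub("^v\\s+", "", vln), "\\s+"), function(x) {
    v <- suppressWarnings(as.numeric(x[1:3]))
    if (any(is.na(v))) stop("malformed OBJ: bad vertex line")
    v
  }, numeric(3L)))
  faces <- matrix(integer(), 0L, 3L)
  if (length(fln) > 0L) {
    faces <- t(vapply(strsplit(sub("^f\\s+", "", fln), "\\s+"), function(x) {
      if (length(x) != 3L) stop("malformed OBJ: only triangular faces supported")
      idx <- suppressWarnings(as.integer(sub("/.*$", "", x)))
      if (any(is.na(idx))) stop("malformed OBJ: bad face line")
      idx
    }, integer(3L)))
  }
  triangle_mesh(V, faces)  # OBJ indices already 1-based
}

write_obj <- function(mesh, path) {
  V <- mesh$vertices; Fc <- mesh$faces
  vl <- apply(V, 1L, function(r) paste("v", paste(format(r, digits = 9L,
                                                         trim = TRUE),
                                                  collapse = " ")))
  fl <- if (nrow(Fc) > 0L) {
    apply(Fc, 1L, function(r) paste("f", paste(r, collapse = " ")))
  } else character()
  writeLines(c(vl, fl), path)
  invisible(path)
}
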