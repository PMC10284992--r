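# Image-grid field I/O: Middlebury .flo optical flow, PFM disparity,
# PNG binary masks. All fields are R matrices with rows = image rows
# (height x width), matching the 0-based (u = column, v = row) sampling
# convention used elsewhere.

FLO_MAGIC <- 202021.25

#' Read / write Middlebury .flo optical flow files
#'
#' @param path file path.
#' @return for `read_flo`, a height x width x 2 array (`[ , , 1]` = u,
#'   `[ , , 2]` = v displacement in px).
#' @export
read_flo <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "double", n = 1L, size = 4L, endian = "little")
  if (length(magic) != 1L || abs(magic - FLO_MAGIC) > 1e-3) {
    stop("not a .flo file (bad magic): ", path)
  }
  w <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  h <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(w) != 1L || length(h) != 1L || w <= 0L || h <= 0L) {
    stop("malformed .flo header: ", path)
  }
  dat <- readBin(con, "double", n = 2L * w * h, size = 4L, endian = "little")
  if (length(dat) != 2L * w * h) stop("truncated .flo data: ", path)
  # interleaved (u, v) per pixel, row-major
  m <- matrix(dat, nrow = 2L)
  out <- array(NA_real_, c(h, w, 2L))
  out[, , 1L] <- matrix(m[1L, ], h, w, byrow = TRUE)
  out[, , 2L] <- matrix(m[2L, ], h, w, byrow = TRUE)
  out
}

#' @rdname read_flo
#' @param flow_uv height x width x 2 array.
#' @export
write_flo <- function(flow_uv, path) {
  stopifnot(length(dim(flow_uv)) == 3L, dim(flow_uv)[3L] == 2L)
  h <- dim(flow_uv)[1L]; w <- dim(flow_uv)[2L]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(FLO_MAGIC, con, size = 4L, endian = "little")
  writeBin(c(as.integer(w), as.integer(h)), con, size = 4L, endian = "little")
  inter <- rbind(as.vector(t(flow_uv[, , 1L])), as.vector(t(flow_uv[, , 2L])))
  writeBin(as.numeric(inter), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read / write PFM (portable float map) images
#'
#' Grayscale (`Pf`) maps only, as used for disparity. Rows are stored
#' bottom-to-top in the file, per the format, and flipped on read/write so the
#' in-memory matrix has row 1 at the image top.
#'
#' @param path file path.
#' @return for `read_pfm`, a height x width numeric matrix.
#' @export
read_pfm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readLines(con, n = 3L)
  if (length(hdr) < 3L || !hdr[1L] %in% c("Pf", "PF")) {
    stop("not a PFM file: ", path)
  }
  if (hdr[1L] == "PF") stop("color PFM not supported: ", path)
  dims <- as.integer(strsplit(trimws(hdr[2L]), "\\s+")[[1L]])
  if (length(dims) != 2L || any(is.na(dims)) || any(dims <= 0L)) {
    stop("malformed PFM dimensions: ", path)
  }
  scale <- as.numeric(hdr[3L])
  if (is.na(scale) || scale == 0) stop("malformed PFM scale: ", path)
  endian <- if (scale < 0) "little" else "big"
  w <- dims[1L]; h <- dims[2L]
  dat <- readBin(con, "double", n = w * h, size = 4L, endian = endian)
  if (length(dat) != w * h) stop("truncated PFM data: ", path)
  m <- matrix(dat, h, w, byrow = TRUE)
  m[h:1, , drop = FALSE]  # bottom-to-top on disk
}

#' @rdname read_pfm
#' @param img height x width numeric matrix.
#' @export
write_pfm <- function(img, path) {
  img <- as.matrix(img)
  h <- nrow(img); w <- ncol(img)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("Pf", paste(w, h), "-1.0"), con, sep = "\n")
  writeBin(as.numeric(t(img[h:1, , drop = FALSE])), con, size = 4L,
           endian = "little")
  invisible(path)
}

#' Read / write binary instrument masks as PNG
#'
#' Masks are logical matrices (TRUE = instrument pixel), stored as 0/255
#' grayscale PNG.
#'
#' @param path file path.
#' @return for `read_mask`, a logical height x width matrix.
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img > 0.5
}

#' @rdname read_mask
#' @param mask logical matrix.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
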