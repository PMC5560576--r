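#' Read an STL file
#'
#' Reads either dialect of the STL interchange format. The dialect is
#' auto-detected: a file is binary when its size equals the binary layout
#' (80-byte header + uint32 facet count + 50 bytes per facet, little-endian);
#' otherwise it must parse as ASCII (`solid ... facet normal ... endsolid`).
#' STL stores a facet soup, so coincident vertices are welded within
#' `merge_tol` to recover shared topology for adjacency and nearest-triangle
#' queries. Coordinates are interpreted as millimetres.
#'
#' @param path file path.
#' @param merge_tol welding tolerance in mm; vertices closer than this (per
#'   coordinate, via grid quantization) become one vertex. Default 1e-6 mm.
#' @param drop_degenerate drop zero-area facets (after welding) with a
#'   warning instead of erroring.
#' @return a [trimesh()]. Triangle count equals the facet count of the file
#'   minus any dropped degenerate facets.
#' @export
read_stl <- function(path, merge_tol = 1e-6, drop_degenerate = TRUE) {
  if (!file.exists(path)) stop(sprintf("STL file not found: %s", path), call. = FALSE)
  size <- file.info(path)$size
  if (size < 15) stop(sprintf("not an STL file (only %d bytes): %s", size, path),
                      call. = FALSE)
  tri <- if (is_binary_stl(path, size)) read_stl_binary(path, size) else read_stl_ascii(path)
  soup_to_trimesh(tri, merge_tol, drop_degenerate)
}

is_binary_stl <- function(path, size) {
  if (size < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  head5 <- readBin(con, "raw", n = 5L)
  seek(con, 80L)
  n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (!is.na(n) && n >= 0 && size == 84 + 50 * as.double(n)) return(TRUE)
  # size mismatch: trust the ASCII keyword if present, else call it binary
  !identical(rawToChar(head5), "solid")
}

read_stl_binary <- function(path, size) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (is.na(n) || n < 0) stop("binary STL: bad facet count at byte offset 80", call. = FALSE)
  body <- readBin(con, "raw", n = 50L * n)
  if (length(body) < 50L * n) {
    stop(sprintf("binary STL truncated: expected %d body bytes, got %d (file %s, offset %d)",
                 50L * n, length(body), path, 84L + length(body)), call. = FALSE)
  }
  if (n == 0L) return(matrix(numeric(0), ncol = 9L))
  # each 50-byte facet: 12 float32 (normal + 3 vertices) + uint16 attribute
  float_idx <- as.vector(outer(1:48, (0:(n - 1L)) * 50L, `+`))
  floats <- readBin(body[float_idx], "double", n = 12L * n, size = 4L, endian = "little")
  fm <- matrix(floats, ncol = 12L, byrow = TRUE)
  fm[, 4:12, drop = FALSE]  # drop stored normals; they are recomputed
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vidx <- grep("^\\s*vertex\\s", lines)
  fidx <- grep("^\\s*facet\\s+normal", lines)
  if (length(vidx) %% 3L != 0L || length(vidx) != 3L * length(fidx)) {
    stop(sprintf("ASCII STL malformed: %d 'facet normal' lines but %d 'vertex' lines (file %s, near line %d)",
                 length(fidx), length(vidx),
                 path, if (length(vidx)) vidx[length(vidx)] else 1L), call. = FALSE)
  }
  if (length(fidx) == 0L) return(matrix(numeric(0), ncol = 9L))
  txt <- sub("^\\s*vertex\\s+", "", lines[vidx])
  nums <- suppressWarnings(
    as.numeric(unlist(strsplit(trimws(txt), "\\s+"), use.names = FALSE)))
  if (length(nums) != 3L * length(vidx) || anyNA(nums)) {
    bad <- which(is.na(nums))
    badline <- if (length(bad)) vidx[min(ceiling(bad[1] / 3), length(vidx))] else vidx[1]
    stop(sprintf("ASCII STL malformed vertex record (file %s, near line %d)",
                 path, badline), call. = FALSE)
  }
  vm <- matrix(nums, ncol = 3L, byrow = TRUE)
  matrix(t(vm), ncol = 9L, byrow = TRUE)  # rows: v1x v1y v1z v2x ... v3z
}

# facet soup (m x 9) -> welded trimesh
soup_to_trimesh <- function(tri, merge_tol, drop_degenerate) {
  m <- nrow(tri)
  if (m == 0L) return(trimesh(NULL, NULL))
  pts <- matrix(t(matrix(tri, ncol = 9L)), ncol = 3L, byrow = TRUE)
  key <- if (merge_tol > 0) {
    q <- round(pts / merge_tol)
    paste(q[, 1], q[, 2], q[, 3])
  } else {
    paste(pts[, 1], pts[, 2], pts[, 3])
  }
  first <- !duplicated(key)
  idx <- match(key, key[first])
  verts <- pts[first, , drop = FALSE]
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] | faces[, 1] == faces[, 3]
  if (any(degen)) {
    if (!drop_degenerate) stop(sprintf("%d degenerate facet(s) after welding", sum(degen)),
                               call. = FALSE)
    warning(sprintf("dropped %d degenerate facet(s) on STL import", sum(degen)),
            call. = FALSE)
    faces <- faces[!degen, , drop = FALSE]
  }
  trimesh(verts, faces)
}

#' Write an STL file
#'
#' The binary dialect stores coordinates as little-endian 32-bit floats
#' (80-byte header, uint32 facet count, 50-byte facets, attribute byte count
#' written as 0), so round-trips are bit-exact for values representable in
#' single precision. Facet normals are recomputed from the winding; a
#' degenerate face gets normal (0,0,0), which readers tolerate.
#'
#' @param mesh a valid [trimesh()].
#' @param path output file path.
#' @param dialect `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  validate_trimesh(mesh)
  f <- mesh$faces
  m <- nrow(f)
  n <- if (m > 0L) face_normals(mesh) else matrix(numeric(0), ncol = 3L)
  n[is.na(n)] <- 0
  v1 <- mesh$vertices[f[, 1], , drop = FALSE]
  v2 <- mesh$vertices[f[, 2], , drop = FALSE]
  v3 <- mesh$vertices[f[, 3], , drop = FALSE]
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "plateplanr binary STL"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(m), con, size = 4L, endian = "little")
    if (m > 0L) {
      floats <- as.vector(t(cbind(n, v1, v2, v3)))  # 12 per facet
      fraw <- writeBin(floats, raw(), size = 4L, endian = "little")
      out <- raw(50L * m)
      out[as.vector(outer(1:48, (0:(m - 1L)) * 50L, `+`))] <- fraw
      writeBin(out, con)
    }
  } else {
    fmt <- function(x) sprintf("%.9g", x)
    blocks <- if (m > 0L) {
      paste0("  facet normal ", fmt(n[, 1]), " ", fmt(n[, 2]), " ", fmt(n[, 3]), "\n",
             "    outer loop\n",
             "      vertex ", fmt(v1[, 1]), " ", fmt(v1[, 2]), " ", fmt(v1[, 3]), "\n",
             "      vertex ", fmt(v2[, 1]), " ", fmt(v2[, 2]), " ", fmt(v2[, 3]), "\n",
             "      vertex ", fmt(v3[, 1]), " ", fmt(v3[, 2]), " ", fmt(v3[, 3]), "\n",
             "    endloop\n",
             "  endfacet")
    } else character(0)
    writeLines(c("solid plateplanr", blocks, "endsolid plateplanr"), path)
  }
  invisible(path)
}
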