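#' Indexed triangle mesh
#'
#' The central container of the package: an indexed triangle surface with
#' vertices in millimetres and 0-based-free (R-style, 1-based) face indices.
#' Face winding is counter-clockwise when viewed from the outward-normal side.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z in mm), one row per
#'   vertex. A 3-column data frame is accepted and coerced.
#' @param faces integer matrix with 3 columns of 1-based vertex indices, one
#'   row per triangle. May have zero rows (empty mesh).
#' @param validate check invariants (index range, no repeated index within a
#'   face). Default `TRUE`.
#'
#' @return An object of class `trimesh`: a list with elements `vertices`
#'   (n x 3 double matrix) and `faces` (m x 3 integer matrix).
#' @export
#'
#' @examples
#' m <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
#' face_normal(m, 1)
trimesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as_coord_matrix(vertices, "vertices")
  if (is.null(faces) || length(faces) == 0L) {
    faces <- matrix(integer(0), ncol = 3L)
  }
  faces <- as.matrix(faces)
  if (ncol(faces) != 3L) stop("`faces` must have 3 columns", call. = FALSE)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  m <- structure(list(vertices = vertices, faces = faces), class = "trimesh")
  if (validate) validate_trimesh(m)
  m
}

as_coord_matrix <- function(x, what) {
  if (is.null(x) || length(x) == 0L) {
    return(matrix(numeric(0), ncol = 3L))
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 3L) x <- matrix(x, ncol = 3L)
  if (!is.matrix(x) || ncol(x) != 3L) {
    stop(sprintf("`%s` must be a matrix with 3 columns", what), call. = FALSE)
  }
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' Validate trimesh invariants
#'
#' Checks that every face index lies in `[1, n_vertices]` and that no face
#' repeats a vertex index. Called by [trimesh()] unless `validate = FALSE`.
#'
#' @param mesh a `trimesh`.
#' @return `mesh`, invisibly. Errors on violation.
#' @export
validate_trimesh <- function(mesh) {
  stopifnot(inherits(mesh, "trimesh"))
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  if (nrow(f) > 0L) {
    if (anyNA(f) || min(f) < 1L || max(f) > nv) {
      stop("face indices out of range [1, vertex count]", call. = FALSE)
    }
    if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3])) {
      stop("degenerate face: repeated vertex index within a face", call. = FALSE)
    }
  }
  if (anyNA(mesh$vertices)) stop("vertices contain NA", call. = FALSE)
  invisible(mesh)
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh> %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  if (nrow(x$vertices) > 0L) {
    r <- apply(x$vertices, 2L, range)
    cat(sprintf("  extent [mm]: x %.3f..%.3f  y %.3f..%.3f  z %.3f..%.3f\n",
                r[1, 1], r[2, 1], r[1, 2], r[2, 2], r[1, 3], r[2, 3]))
  }
  invisible(x)
}

#' Per-face normals of a mesh
#'
#' Unit normals from the counter-clockwise winding (cross product of the two
#' edge vectors out of the first vertex). Degenerate faces (area below
#' `eps_area`) yield `NA` rows unless `strict`.
#'
#' @param mesh a `trimesh`.
#' @param strict error on degenerate faces instead of returning `NA`.
#' @param eps_area area threshold (mm^2) below which a face counts as
#'   degenerate.
#' @return m x 3 matrix of unit normals.
#' @export
face_normals <- function(mesh, strict = FALSE, eps_area = 1e-12) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0L) return(matrix(numeric(0), ncol = 3L))
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cross3(e1, e2)
  len <- sqrt(rowSums(n * n))
  bad <- len / 2 <= eps_area
  if (any(bad) && strict) {
    stop(sprintf("degenerate face (area <= %g): face %d", eps_area, which(bad)[1]),
         call. = FALSE)
  }
  n <- n / len
  n[bad, ] <- NA_real_
  n
}

#' Normal of a single face
#'
#' @param mesh a `trimesh`.
#' @param face_index 1-based face index.
#' @param eps_area degeneracy threshold on the face area (mm^2).
#' @return unit 3-vector.
#' @export
face_normal <- function(mesh, face_index, eps_area = 1e-12) {
  stopifnot(length(face_index) == 1L, face_index >= 1L, face_index <= nrow(mesh$faces))
  f <- mesh$faces[face_index, ]
  a <- mesh$vertices[f[1], ]
  b <- mesh$vertices[f[2], ]
  c <- mesh$vertices[f[3], ]
  n <- cross3(rbind(b - a), rbind(c - a))[1, ]
  len <- sqrt(sum(n * n))
  if (len / 2 <= eps_area) {
    stop(sprintf("degenerate face %d (area <= %g)", face_index, eps_area), call. = FALSE)
  }
  n / len
}

#' Concatenate meshes without welding
#'
#' Vertex and face counts of the result are the sums of the inputs' counts;
#' face indices are re-offset. No geometric welding happens across inputs, so
#' every input triangle's vertex positions are preserved exactly.
#'
#' @param meshes a list of `trimesh` objects (at least one).
#' @return a single `trimesh`.
#' @export
merge_meshes <- function(meshes) {
  if (inherits(meshes, "trimesh")) meshes <- list(meshes)
  if (!is.list(meshes) || length(meshes) == 0L) {
    stop("`meshes` must be a non-empty list of trimesh objects", call. = FALSE)
  }
  lapply(meshes, function(m) stopifnot(inherits(m, "trimesh")))
  nvs <- vapply(meshes, function(m) nrow(m$vertices), integer(1))
  offs <- cumsum(c(0L, nvs[-length(nvs)]))
  verts <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  faces <- do.call(rbind, mapply(function(m, o) m$faces + o, meshes, offs,
                                 SIMPLIFY = FALSE))
  trimesh(verts, faces)
}

#' Rigidly transform a mesh or point set
#'
#' @param x a `trimesh` or an n x 3 coordinate matrix.
#' @param transform a [rigid_transform()].
#' @return object of the same type as `x`.
#' @export
apply_transform <- function(x, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(x, "trimesh")) {
    x$vertices <- transform_points(x$vertices, transform)
    return(x)
  }
  transform_points(as_coord_matrix(x, "x"), transform)
}

#' Watertightness check
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces. Used to verify ring-element construction.
#'
#' @param mesh a `trimesh`.
#' @return `TRUE`/`FALSE`.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Signed enclosed volume
#'
#' Divergence-theorem volume (sum of signed tetrahedra against the origin);
#' positive for a closed, consistently outward-wound surface.
#'
#' @param mesh a `trimesh`.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  sum(rowSums(a * cross3(b, c))) / 6
}

#' Total surface area
#' @param mesh a `trimesh`.
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cross3(e1, e2)
  sum(sqrt(rowSums(n * n))) / 2
}

# row-wise cross product of n x 3 matrices (recycled if one has 1 row)
cross3 <- function(a, b) {
  if (is.null(dim(a))) a <- rbind(a)
  if (is.null(dim(b))) b <- rbind(b)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

dot3 <- function(a, b) {
  if (is.null(dim(a))) a <- rbind(a)
  if (is.null(dim(b))) b <- rbind(b)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  rowSums(a * b)
}

vnorm <- function(x) sqrt(sum(x * x))

unitize <- function(x, what = "vector") {
  n <- vnorm(x)
  if (n < 1e-12) stop(sprintf("cannot normalize near-zero %s", what), call. = FALSE)
  x / n
}
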