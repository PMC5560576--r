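#' Ray constructor
#'
#' @param origin 3-vector (mm).
#' @param direction 3-vector; normalized to unit length.
#' @return object of class `ray` with elements `origin`, `direction`.
#' @export
ray <- function(origin, direction) {
  stopifnot(length(origin) == 3L, length(direction) == 3L)
  structure(list(origin = as.numeric(origin),
                 direction = unitize(as.numeric(direction), "ray direction")),
            class = "ray")
}

#' Moeller-Trumbore ray-triangle intersection
#'
#' Solves for the hit record (t, u, v) by the change-of-base method: t is the
#' signed distance along the ray, (u, v) the barycentric coordinates inside
#' the triangle. The triangle's plane equation is never formed. Hits are
#' accepted from either side (no backface culling) when `0 <= u`, `0 <= v`,
#' `u + v <= 1` (within `epsilon`) and `t > epsilon`; otherwise no-hit.
#' Rays parallel to the triangle plane (|determinant| <= epsilon) are no-hits.
#'
#' @param r a [ray()].
#' @param v0,v1,v2 triangle vertices (3-vectors, mm).
#' @param epsilon determinant / self-intersection tolerance (default 1e-9).
#' @return a list `(t, u, v, face_index = NA)` of class `ray_hit`, or `NULL`
#'   for no-hit.
#' @export
intersect_ray_triangle <- function(r, v0, v1, v2, epsilon = 1e-9) {
  e1 <- v1 - v0
  e2 <- v2 - v0
  d <- r$direction
  p <- c(d[2] * e2[3] - d[3] * e2[2],
         d[3] * e2[1] - d[1] * e2[3],
         d[1] * e2[2] - d[2] * e2[1])
  det <- sum(e1 * p)
  if (abs(det) <= epsilon) return(NULL)
  inv <- 1 / det
  s <- r$origin - v0
  u <- sum(s * p) * inv
  if (u < -epsilon || u > 1 + epsilon) return(NULL)
  q <- c(s[2] * e1[3] - s[3] * e1[2],
         s[3] * e1[1] - s[1] * e1[3],
         s[1] * e1[2] - s[2] * e1[1])
  v <- sum(d * q) * inv
  if (v < -epsilon || u + v > 1 + epsilon) return(NULL)
  t <- sum(e2 * q) * inv
  if (t <= epsilon) return(NULL)
  structure(list(t = t, u = u, v = v, face_index = NA_integer_), class = "ray_hit")
}

# vectorized Moeller-Trumbore over all faces of a mesh; returns data.frame of
# accepted forward hits (possibly 0 rows)
mt_all_faces <- function(mesh, origin, direction, epsilon = 1e-9) {
  f <- mesh$faces
  if (nrow(f) == 0L) {
    return(data.frame(t = numeric(0), u = numeric(0), v = numeric(0),
                      face_index = integer(0)))
  }
  vtx <- mesh$vertices
  v0 <- vtx[f[, 1], , drop = FALSE]
  e1 <- vtx[f[, 2], , drop = FALSE] - v0
  e2 <- vtx[f[, 3], , drop = FALSE] - v0
  dmat <- rbind(direction)
  p <- cross3(dmat, e2)
  det <- dot3(e1, p)
  inv <- ifelse(abs(det) > epsilon, 1 / det, NA_real_)
  s <- rbind(origin)[rep(1L, nrow(f)), , drop = FALSE] - v0
  u <- dot3(s, p) * inv
  q <- cross3(s, e1)
  v <- dot3(dmat, q) * inv
  t <- dot3(e2, q) * inv
  ok <- !is.na(inv) & u >= -epsilon & v >= -epsilon & (u + v) <= 1 + epsilon &
    t > epsilon
  ok[is.na(ok)] <- FALSE
  data.frame(t = t[ok], u = u[ok], v = v[ok], face_index = which(ok))
}

#' Cast a ray against a whole mesh
#'
#' Exhaustive scan over all faces: among all triangles intersected with
#' `t > epsilon`, returns the hit with minimal t; ties broken by lowest face
#' index.
#'
#' @param mesh a [trimesh()].
#' @param r a [ray()].
#' @param epsilon see [intersect_ray_triangle()].
#' @return a `ray_hit` (with `face_index` and `point` filled in), or `NULL`.
#' @export
cast_ray <- function(mesh, r, epsilon = 1e-9) {
  hits <- mt_all_faces(mesh, r$origin, r$direction, epsilon)
  if (nrow(hits) == 0L) return(NULL)
  best <- which(hits$t == min(hits$t))[1]  # rows already in face-index order
  h <- hits[best, ]
  structure(list(t = h$t, u = h$u, v = h$v, face_index = h$face_index,
                 point = r$origin + h$t * r$direction),
            class = "ray_hit")
}

#' Closest point, normal and face on a mesh
#'
#' Exact point-to-triangle Euclidean projection over every face; returns the
#' globally closest foot point, the (flat, per-face) normal of its triangle,
#' and the face index. Ties are broken by lowest face index.
#'
#' @param mesh non-empty [trimesh()].
#' @param point 3-vector (mm).
#' @return list with `point` (foot, 3-vector), `normal` (unit 3-vector),
#'   `face_index`, `distance` (mm).
#' @export
closest_surface_frame <- function(mesh, point) {
  if (!inherits(mesh, "trimesh") || nrow(mesh$faces) == 0L) {
    stop("closest_surface_frame needs a non-empty mesh", call. = FALSE)
  }
  cp <- closest_point_all_faces(mesh, as.numeric(point))
  d2 <- rowSums((cp - rbind(as.numeric(point))[rep(1L, nrow(cp)), ])^2)
  i <- which(d2 == min(d2))[1]
  list(point = cp[i, ], normal = face_normal(mesh, i), face_index = i,
       distance = sqrt(d2[i]))
}

# closest point on each face to `p`; vectorized Ericson-style region test
closest_point_all_faces <- function(mesh, p) {
  f <- mesh$faces
  vtx <- mesh$vertices
  a <- vtx[f[, 1], , drop = FALSE]
  b <- vtx[f[, 2], , drop = FALSE]
  c <- vtx[f[, 3], , drop = FALSE]
  m <- nrow(f)
  pm <- rbind(p)[rep(1L, m), , drop = FALSE]
  ab <- b - a; ac <- c - a; ap <- pm - a
  d1 <- dot3(ab, ap); d2 <- dot3(ac, ap)
  bp <- pm - b
  d3 <- dot3(ab, bp); d4 <- dot3(ac, bp)
  cp_ <- pm - c
  d5 <- dot3(ab, cp_); d6 <- dot3(ac, cp_)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2

  out <- matrix(NA_real_, m, 3L)
  done <- rep(FALSE, m)
  set <- function(idx, val) {
    idx <- idx & !done
    out[idx, ] <<- val[idx, , drop = FALSE]
    done <<- done | idx
  }
  # vertex regions
  set(d1 <= 0 & d2 <= 0, a)
  set(d3 >= 0 & d4 <= d3, b)
  set(d6 >= 0 & d5 <= d6, c)
  # edge AB
  vAB <- ifelse(abs(d1 - d3) > 0, d1 / (d1 - d3), 0)
  set(vc <= 0 & d1 >= 0 & d3 <= 0, a + ab * vAB)
  # edge AC
  wAC <- ifelse(abs(d2 - d6) > 0, d2 / (d2 - d6), 0)
  set(vb <= 0 & d2 >= 0 & d6 <= 0, a + ac * wAC)
  # edge BC
  wBC <- ifelse(abs((d4 - d3) + (d5 - d6)) > 0,
                (d4 - d3) / ((d4 - d3) + (d5 - d6)), 0)
  set(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, b + (c - b) * wBC)
  # interior
  denom <- va + vb + vc
  denom <- ifelse(abs(denom) > 0, denom, 1)
  vI <- vb / denom
  wI <- vc / denom
  set(!done, a + ab * vI + ac * wI)
  out
}
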