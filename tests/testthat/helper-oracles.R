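# Independent reference implementations used as oracles. These deliberately
# take the "textbook" route the production code avoids (explicit plane
# equation, per-edge segment projections) so agreement is meaningful.

# ray-triangle intersection via the explicit plane equation + barycentric
# test; returns list(t, u, v) or NULL
oracle_ray_tri <- function(origin, dir, v0, v1, v2, eps = 1e-9) {
  e1 <- v1 - v0
  e2 <- v2 - v0
  n <- c(e1[2] * e2[3] - e1[3] * e2[2],
         e1[3] * e2[1] - e1[1] * e2[3],
         e1[1] * e2[2] - e1[2] * e2[1])
  denom <- sum(n * dir)
  if (abs(denom) <= eps * 1) return(NULL)
  t <- sum(n * (v0 - origin)) / denom
  if (t <= eps) return(NULL)
  p <- origin + t * dir
  # barycentric coordinates from the 2x2 Gram system
  w <- p - v0
  g11 <- sum(e1 * e1); g12 <- sum(e1 * e2); g22 <- sum(e2 * e2)
  det <- g11 * g22 - g12 * g12
  u <- (g22 * sum(w * e1) - g12 * sum(w * e2)) / det
  v <- (g11 * sum(w * e2) - g12 * sum(w * e1)) / det
  if (u < -eps || v < -eps || u + v > 1 + eps) return(NULL)
  list(t = t, u = u, v = v)
}

# closest point on one triangle by plane projection + per-edge clamping
oracle_closest_tri <- function(p, v0, v1, v2) {
  e1 <- v1 - v0
  e2 <- v2 - v0
  n <- c(e1[2] * e2[3] - e1[3] * e2[2],
         e1[3] * e2[1] - e1[1] * e2[3],
         e1[1] * e2[2] - e1[2] * e2[1])
  n <- n / sqrt(sum(n^2))
  q <- p - sum((p - v0) * n) * n
  w <- q - v0
  g11 <- sum(e1 * e1); g12 <- sum(e1 * e2); g22 <- sum(e2 * e2)
  det <- g11 * g22 - g12 * g12
  u <- (g22 * sum(w * e1) - g12 * sum(w * e2)) / det
  v <- (g11 * sum(w * e2) - g12 * sum(w * e1)) / det
  if (u >= 0 && v >= 0 && u + v <= 1) return(q)
  seg <- function(a, b) {
    d <- b - a
    tt <- sum((p - a) * d) / sum(d * d)
    a + min(max(tt, 0), 1) * d
  }
  cand <- rbind(seg(v0, v1), seg(v1, v2), seg(v2, v0))
  cand[which.min(rowSums((cand - rbind(p, p, p))^2)), ]
}

# brute-force nearest hit: scalar kernel looped over all faces
oracle_cast <- function(mesh, origin, dir) {
  best <- NULL
  r <- ray(origin, dir)
  for (i in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[i, ]
    h <- intersect_ray_triangle(r, mesh$vertices[f[1], ], mesh$vertices[f[2], ],
                                mesh$vertices[f[3], ])
    if (!is.null(h) && (is.null(best) || h$t < best$t)) {
      best <- h
      best$face_index <- i
    }
  }
  best
}

xprod <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) v / sqrt(sum(v^2))

rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# a single-triangle mesh
tri_mesh <- function(v0, v1, v2) trimesh(rbind(v0, v1, v2), rbind(c(1L, 2L, 3L)))

expect_vec_equal <- function(actual, expected, tol = 1e-12) {
  expect_lt(max(abs(actual - expected)), tol)
}
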