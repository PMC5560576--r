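#' Rigid transform (proper rotation + translation)
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation 3-vector (mm).
#' @param validate check orthonormality (`R^T R = I` and `det R = 1` within
#'   1e-9).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            validate = TRUE) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (validate) {
    if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
        abs(det(rotation) - 1) > 1e-9) {
      stop("rotation must be proper orthonormal (R'R = I, det = +1)", call. = FALSE)
    }
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation:", paste(signif(x$translation, 6), collapse = " "), "\n")
  invisible(x)
}

#' Apply a rigid transform to points
#' @param points n x 3 matrix or 3-vector.
#' @param transform a [rigid_transform()].
#' @return n x 3 matrix.
#' @export
transform_points <- function(points, transform) {
  p <- as_coord_matrix(points, "points")
  p %*% t(transform$rotation) +
    matrix(transform$translation, nrow(p), 3L, byrow = TRUE)
}

#' Compose two rigid transforms (`a` after `b`)
#' @param a,b [rigid_transform()] objects.
#' @return the transform `x -> a(b(x))`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation,
                  validate = FALSE)
}

#' Minimal rotation mapping one unit vector onto another
#'
#' Rodrigues construction about the axis `a x b`. For anti-parallel inputs
#' (dot < -1 + 1e-9) the rotation is by pi about a deterministic axis
#' perpendicular to `a` (the unit projection of the coordinate axis least
#' aligned with `a`).
#'
#' @param a,b unit 3-vectors.
#' @return a rotation-only [rigid_transform()] with `R a = b`.
#' @export
rotation_between <- function(a, b) {
  if (vnorm(a) < 1e-12 || vnorm(b) < 1e-12) {
    stop("zero vector passed to rotation_between", call. = FALSE)
  }
  a <- a / vnorm(a)
  b <- b / vnorm(b)
  d <- sum(a * b)
  if (d < -1 + 1e-9) {
    # pick the global axis least aligned with a, project to the plane
    # perpendicular to a -> deterministic perpendicular axis
    ax <- diag(3)[, which.min(abs(a))]
    perp <- unitize(ax - sum(ax * a) * a, "anti-parallel fallback axis")
    return(rotation_about_axis(perp, pi))
  }
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  K <- skew3(v)
  R <- diag(3) + K + (K %*% K) / (1 + d)
  rigid_transform(R, c(0, 0, 0), validate = FALSE)
}

#' Right-handed rotation about an axis
#' @param axis unit 3-vector.
#' @param angle rotation angle in radians.
#' @return a rotation-only [rigid_transform()].
#' @export
rotation_about_axis <- function(axis, angle) {
  n <- vnorm(axis)
  if (n < 1e-12) stop("zero axis passed to rotation_about_axis", call. = FALSE)
  axis <- axis / n
  K <- skew3(axis)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  rigid_transform(R, c(0, 0, 0), validate = FALSE)
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3L, 3L)
}
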