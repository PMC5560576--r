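#' Synthetic test surfaces
#'
#' Deterministic fixture surfaces used to exercise and validate the baseline
#' tracer and the implant builder without patient data: a flat plane, a
#' sinusoidal wave, a right-angle step and a hemisphere. All are regular-grid
#' triangulations (diagonal split fixed lower-left to upper-right) with
#' counter-clockwise winding so recomputed normals point up/outward.
#'
#' @param extent_x,extent_y grid extent in mm; the grid covers
#'   `[-extent_x/2, extent_x/2] x [-extent_y/2, extent_y/2]`.
#' @param resolution vertices per axis (>= 2).
#' @name synthetic_surfaces
NULL

grid_mesh <- function(extent_x, extent_y, resolution, zfun,
                      x0 = -extent_x / 2, y0 = -extent_y / 2) {
  if (!is.numeric(resolution) || resolution < 2) {
    stop("`resolution` must be an integer >= 2", call. = FALSE)
  }
  if (extent_x <= 0 || extent_y <= 0) stop("extents must be positive", call. = FALSE)
  n <- as.integer(resolution)
  xs <- x0 + extent_x * (0:(n - 1L)) / (n - 1L)
  ys <- y0 + extent_y * (0:(n - 1L)) / (n - 1L)
  xv <- rep(xs, times = n)
  yv <- rep(ys, each = n)
  verts <- cbind(xv, yv, zfun(xv, yv))
  # cell (i, j): vertices i + (j-1)*n etc.; split lower-left to upper-right.
  i <- rep(1:(n - 1L), times = n - 1L)
  j <- rep(1:(n - 1L), each = n - 1L)
  v00 <- i + (j - 1L) * n
  v10 <- v00 + 1L
  v01 <- v00 + n
  v11 <- v01 + 1L
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  trimesh(verts, faces)
}

#' @describeIn synthetic_surfaces flat plane z = 0; all face normals (0,0,1).
#' @export
make_plane <- function(extent_x = 100, extent_y = 100, resolution = 51) {
  grid_mesh(extent_x, extent_y, resolution, function(x, y) rep(0, length(x)))
}

#' @describeIn synthetic_surfaces sinusoidal wave
#'   `z = amplitude * sin(2 pi x / wavelength)`; vertices satisfy the
#'   analytic equation exactly.
#' @param amplitude wave amplitude in mm.
#' @param wavelength wave period in mm (> 0).
#' @export
make_wave <- function(extent_x = 100, extent_y = 100, resolution = 101,
                      amplitude = 5, wavelength = 40) {
  if (wavelength <= 0) stop("`wavelength` must be positive", call. = FALSE)
  grid_mesh(extent_x, extent_y, resolution,
            function(x, y) amplitude * sin(2 * pi * x / wavelength))
}

#' @describeIn synthetic_surfaces right-angle step: horizontal plane z = 0
#'   for x < 0, vertical face at x = 0 rising to `step_height`, horizontal
#'   plane z = step_height for x > 0. Face normals are (0,0,1) on both
#'   horizontal parts and (-1,0,0) on the vertical face.
#' @param step_height height of the vertical face in mm (>= 0).
#' @export
make_step <- function(extent_x = 100, extent_y = 100, resolution = 51,
                      step_height = 10) {
  if (step_height < 0) stop("`step_height` must be >= 0", call. = FALSE)
  lower <- grid_mesh(extent_x / 2, extent_y, resolution,
                     function(x, y) rep(0, length(x)), x0 = -extent_x / 2)
  upper <- grid_mesh(extent_x / 2, extent_y, resolution,
                     function(x, y) rep(step_height, length(x)), x0 = 0)
  if (step_height == 0) return(merge_meshes(list(lower, upper)))
  # vertical face at x = 0, y-z grid, outward normal (-1,0,0): build in a
  # (u, v) grid with u = y, v = z and map so winding gives -x.
  n <- as.integer(resolution)
  wall <- grid_mesh(extent_y, step_height, resolution,
                    function(u, v) rep(0, length(u)), x0 = -extent_y / 2, y0 = 0)
  wv <- wall$vertices
  # (u, v, 0) with normal +z must become (0, y, z) with normal (-1,0,0);
  # the map (u,v,w) -> (-w, -u, v) is a proper rotation (two sign flips on
  # top of the cyclic permutation), so winding is preserved and +z normals
  # become -x normals; the y range stays symmetric.
  wall$vertices <- cbind(-wv[, 3], -wv[, 1], wv[, 2])
  merge_meshes(list(lower, wall, upper))
}

#' @describeIn synthetic_surfaces upper hemisphere of radius `radius`
#'   centered at the origin (apex vertex at (0,0,radius)); every vertex is at
#'   distance `radius` from the origin up to floating-point rounding.
#' @param radius hemisphere radius in mm (> 0).
#' @export
make_hemisphere <- function(radius = 50, resolution = 100) {
  if (radius <= 0) stop("`radius` must be positive", call. = FALSE)
  if (!is.numeric(resolution) || resolution < 2) {
    stop("`resolution` must be an integer >= 2", call. = FALSE)
  }
  n_az <- as.integer(resolution)          # azimuth samples per ring
  n_el <- as.integer(resolution)          # elevation rings apex..equator
  el <- pi / 2 * (1:n_el) / n_el          # polar angle from +z, apex excluded
  az <- 2 * pi * (0:(n_az - 1L)) / n_az
  ca <- cos(az); sa <- sin(az)
  verts <- matrix(0, 1L + n_el * n_az, 3L)
  verts[1L, ] <- c(0, 0, radius)
  for (k in seq_len(n_el)) {
    rk <- radius * sin(el[k])
    zk <- radius * cos(el[k])
    rows <- 1L + (k - 1L) * n_az + (1:n_az)
    verts[rows, ] <- cbind(rk * ca, rk * sa, rep(zk, n_az))
  }
  ring <- function(k) 1L + (k - 1L) * n_az + (1:n_az)
  nxt <- c(2:n_az, 1L)
  # apex fan: CCW seen from outside (+z above apex)
  r1 <- ring(1L)
  faces <- cbind(rep(1L, n_az), r1, r1[nxt])
  for (k in seq_len(n_el - 1L)) {
    up <- ring(k); lo <- ring(k + 1L)
    faces <- rbind(faces,
                   cbind(up, lo, lo[nxt]),
                   cbind(up, lo[nxt], up[nxt]))
  }
  trimesh(verts, faces)
}
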