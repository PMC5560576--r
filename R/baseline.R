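#' Baseline: ordered surface markers standing in for the implant
#'
#' A baseline is the simplified stand-in for a miniplate during placement: an
#' ordered chain of on-surface markers, each carrying its position, the (flat,
#' per-face) surface normal at the hit triangle, and the tangent direction
#' toward the next marker. Normal and tangent are not necessarily
#' perpendicular on curved surfaces.
#'
#' @param markers data frame with columns `x, y, z, nx, ny, nz, tx, ty, tz`.
#' @param seed the seed point the trace started from (3-vector, mm).
#' @param angle orientation angle (radians).
#' @param spacing marker spacing (mm).
#' @param mode `"cascade"` or `"marching"`.
#' @return object of class `baseline`.
#' @export
baseline <- function(markers, seed, angle, spacing, mode) {
  stopifnot(is.data.frame(markers),
            all(c("x", "y", "z", "nx", "ny", "nz", "tx", "ty", "tz") %in%
                  names(markers)))
  structure(list(markers = markers, seed = as.numeric(seed), angle = angle,
                 spacing = spacing, mode = mode),
            class = "baseline")
}

#' @export
print.baseline <- function(x, ...) {
  cat(sprintf("<baseline> %d markers, mode %s, spacing %.3g mm, arc length %.4f mm\n",
              nrow(x$markers), x$mode, x$spacing, arc_length(x)))
  invisible(x)
}

marker_positions <- function(bl) as.matrix(bl$markers[, c("x", "y", "z")])
marker_normals <- function(bl) as.matrix(bl$markers[, c("nx", "ny", "nz")])
marker_tangents <- function(bl) as.matrix(bl$markers[, c("tx", "ty", "tz")])

#' Extract one marker
#' @param bl a [baseline()].
#' @param i marker index.
#' @return list with `position`, `normal`, `tangent` (3-vectors).
#' @export
baseline_marker <- function(bl, i) {
  m <- bl$markers[i, ]
  list(position = c(m$x, m$y, m$z), normal = c(m$nx, m$ny, m$nz),
       tangent = c(m$tx, m$ty, m$tz))
}

#' Local surface frame at a seed point
#'
#' Projects the seed onto the mesh ([closest_surface_frame()]) and builds the
#' initial trace direction: the reference tangent is the normalized
#' projection of the global +x axis onto the tangent plane (fallback +y when
#' the normal is nearly parallel to +x), rotated by `angle` about the normal.
#'
#' @param mesh non-empty [trimesh()].
#' @param seed 3-vector (mm), on or near the surface.
#' @param angle orientation angle in radians.
#' @return list with `foot` (3-vector), `normal`, `direction` (unit
#'   3-vectors) and `face_index`.
#' @export
seed_frame <- function(mesh, seed, angle = 0) {
  fr <- closest_surface_frame(mesh, seed)
  n <- fr$normal
  ref <- if (abs(sum(n * c(1, 0, 0))) > 0.99) c(0, 1, 0) else c(1, 0, 0)
  d0 <- unitize(ref - sum(ref * n) * n, "reference tangent")
  d <- as.vector(rotation_about_axis(n, angle)$rotation %*% d0)
  list(foot = fr$point, normal = n, direction = d, face_index = fr$face_index)
}

markers_df <- function(pos, nor) {
  k <- nrow(pos)
  tan <- matrix(0, k, 3L)
  if (k >= 2L) {
    d <- pos[-1L, , drop = FALSE] - pos[-k, , drop = FALSE]
    d <- d / sqrt(rowSums(d * d))
    tan[-k, ] <- d
    tan[k, ] <- d[k - 1L, ]
  }
  data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
             nx = nor[, 1], ny = nor[, 2], nz = nor[, 3],
             tx = tan[, 1], ty = tan[, 2], tz = tan[, 3])
}

#' Trace a baseline with a cascade of parallel rays
#'
#' The literal cascade construction: ray origins are lifted `lift` mm above
#' the tangent plane and spaced every `spacing` mm along the fixed direction
#' `D`, from `-length/2` to `+length/2` around the foot point; every ray is
#' cast along the fixed `-N`. Marker positions are the nearest hits, marker
#' normals the hit-face normals, marker tangents point to the successor
#' marker (the last marker copies its predecessor's tangent).
#'
#' @param mesh a [trimesh()] bone surface.
#' @param foot,N,D seed frame as returned by [seed_frame()].
#' @param length requested baseline length (mm, > 0) - normally the plate's
#'   overall length.
#' @param spacing marker spacing (mm, > 0).
#' @param lift ray-origin height above the local tangent plane (mm, > 0);
#'   must exceed the local surface relief.
#' @param on_miss `"skip"` (drop missed rays with a warning) or `"error"`.
#'   More than 50 percent missed rays is always an error.
#' @return a [baseline()].
#' @export
trace_cascade <- function(mesh, foot, N, D, length, spacing = 0.5, lift = 10,
                          on_miss = c("skip", "error")) {
  on_miss <- match.arg(on_miss)
  stopifnot(length > 0, spacing > 0, lift > 0)
  s <- seq(-length / 2, length / 2, by = spacing)
  origins <- rbind(foot)[rep(1L, base::length(s)), ] + outer(s, D) +
    matrix(lift * N, base::length(s), 3L, byrow = TRUE)
  hits <- vector("list", base::length(s))
  for (i in seq_along(s)) {
    hits[[i]] <- cast_ray(mesh, ray(origins[i, ], -N))
  }
  ok <- !vapply(hits, is.null, logical(1))
  if (any(!ok)) {
    if (on_miss == "error") stop(sprintf("%d cascade ray(s) missed the mesh", sum(!ok)),
                                 call. = FALSE)
    warning(sprintf("skipped %d cascade ray(s) that missed the mesh", sum(!ok)),
            call. = FALSE)
  }
  if (sum(ok) < base::length(s) / 2) {
    stop(sprintf("baseline trace failed: %d of %d rays missed the mesh",
                 sum(!ok), base::length(s)), call. = FALSE)
  }
  if (sum(ok) < 2L) stop("baseline trace failed: fewer than 2 markers", call. = FALSE)
  pos <- do.call(rbind, lapply(hits[ok], `[[`, "point"))
  nor <- do.call(rbind, lapply(hits[ok], function(h) face_normal(mesh, h$face_index)))
  baseline(markers_df(pos, nor), foot, NA_real_, spacing, "cascade")
}

# one marching step: cast from cur + spacing*D + lift*N along -N; when the
# hit is absent or farther than 2*spacing (a corner), retry with the frame
# (D, N) rotated +90 deg (concave corner, e.g. the foot of a wall) then
# -90 deg (convex corner, e.g. the top edge) about D x N.
march_step <- function(mesh, cur, D, N, spacing, lift) {
  try_frame <- function(D2, N2) {
    h <- cast_ray(mesh, ray(cur + spacing * D2 + lift * N2, -N2))
    if (!is.null(h) && vnorm(h$point - cur) <= 2 * spacing) list(hit = h, D = D2, N = N2)
    else NULL
  }
  r <- try_frame(D, N)
  if (!is.null(r)) return(r)
  axis <- unitize(cross3(rbind(D), rbind(N))[1, ], "marching frame axis")
  for (ang in c(pi / 2, -pi / 2)) {
    R <- rotation_about_axis(axis, ang)$rotation
    r <- try_frame(as.vector(R %*% D), as.vector(R %*% N))
    if (!is.null(r)) return(r)
  }
  NULL
}

#' Trace a baseline by marching with a locally recomputed frame
#'
#' Grows the baseline symmetrically from the center marker. At each step the
#' local frame is recomputed: the normal is the last hit face's normal and
#' the direction is the previous direction re-projected into the new tangent
#' plane; the next ray origin is `current + spacing * D + lift * N`, cast
#' along `-N`. When a cast misses or lands farther than `2 * spacing` away
#' (a surface corner), the frame is rotated 90 degrees about `D x N`
#' (concave first, then convex) and the cast retried, which lets the
#' baseline follow right-angle steps. Each arm stops when its accumulated
#' arc length reaches `length / 2`.
#'
#' @inheritParams trace_cascade
#' @return a [baseline()].
#' @export
trace_marching <- function(mesh, foot, N, D, length, spacing = 0.5, lift = 10,
                           on_miss = c("skip", "error")) {
  on_miss <- match.arg(on_miss)
  stopifnot(length > 0, spacing > 0, lift > 0)
  h0 <- cast_ray(mesh, ray(foot + lift * N, -N))
  if (is.null(h0)) stop("baseline trace failed: center ray missed the mesh", call. = FALSE)
  N0 <- face_normal(mesh, h0$face_index)
  dproj <- D - sum(D * N0) * N0
  if (vnorm(dproj) < 1e-9) stop("trace failure: direction collapses onto the normal",
                                call. = FALSE)
  D0 <- dproj / vnorm(dproj)

  grow_arm <- function(dir0) {
    cur <- h0$point; Dc <- dir0; Nc <- N0
    arc <- 0
    pos <- NULL; nor <- NULL
    while (arc + spacing <= length / 2 + spacing / 2 + 1e-9) {
      st <- march_step(mesh, cur, Dc, Nc, spacing, lift)
      if (is.null(st)) {
        if (on_miss == "error") stop("marching ray missed the mesh", call. = FALSE)
        warning("marching arm stopped early: ray missed the mesh", call. = FALSE)
        break
      }
      Nn <- face_normal(mesh, st$hit$face_index)
      dp <- st$D - sum(st$D * Nn) * Nn
      if (vnorm(dp) < 1e-9) stop("trace failure: marching frame collapsed", call. = FALSE)
      arc <- arc + vnorm(st$hit$point - cur)
      cur <- st$hit$point
      Dc <- dp / vnorm(dp)
      Nc <- Nn
      pos <- rbind(pos, cur)
      nor <- rbind(nor, Nn)
    }
    list(pos = pos, nor = nor)
  }
  fwd <- grow_arm(D0)
  bwd <- grow_arm(-D0)
  pos <- rbind(if (!is.null(bwd$pos)) bwd$pos[rev(seq_len(nrow(bwd$pos))), , drop = FALSE],
               rbind(h0$point),
               fwd$pos)
  nor <- rbind(if (!is.null(bwd$nor)) bwd$nor[rev(seq_len(nrow(bwd$nor))), , drop = FALSE],
               rbind(N0),
               fwd$nor)
  if (nrow(pos) < 2L) stop("baseline trace failed: fewer than 2 markers", call. = FALSE)
  baseline(markers_df(pos, nor), foot, NA_real_, spacing, "marching")
}

#' Trace a baseline from a seed point
#'
#' Convenience wrapper: [seed_frame()] followed by [trace_cascade()] or
#' [trace_marching()] (the default).
#'
#' @inheritParams trace_cascade
#' @param seed 3-vector (mm).
#' @param angle orientation angle in radians.
#' @param mode `"marching"` (default; adapts to corners) or `"cascade"` (the
#'   literal parallel-ray construction).
#' @return a [baseline()] (with `seed` and `angle` recorded).
#' @export
trace_baseline <- function(mesh, seed, angle = 0, length, spacing = 0.5,
                           lift = 10, mode = c("marching", "cascade"),
                           on_miss = c("skip", "error")) {
  mode <- match.arg(mode)
  fr <- seed_frame(mesh, seed, angle)
  bl <- if (mode == "cascade") {
    trace_cascade(mesh, fr$foot, fr$normal, fr$direction, length, spacing, lift,
                  on_miss)
  } else {
    trace_marching(mesh, fr$foot, fr$normal, fr$direction, length, spacing, lift,
                   on_miss)
  }
  bl$seed <- as.numeric(seed)
  bl$angle <- angle
  bl
}

#' Polyline arc length of a baseline
#' @param bl a [baseline()] with at least one marker.
#' @return total length in mm (0 for a single marker).
#' @export
arc_length <- function(bl) {
  p <- marker_positions(bl)
  if (nrow(p) == 0L) stop("empty baseline", call. = FALSE)
  if (nrow(p) == 1L) return(0)
  d <- p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
  sum(sqrt(rowSums(d * d)))
}

#' Interpolated marker at an arc-length position
#'
#' Position is linearly interpolated along the marker polyline; normal and
#' tangent are taken from the nearer of the two bracketing markers and
#' re-normalized. `s` is measured from the first marker.
#'
#' @param bl a [baseline()].
#' @param s arc-length coordinate, `0 <= s <= arc_length(bl)`.
#' @return list with `position`, `normal`, `tangent`.
#' @export
point_at_arc <- function(bl, s) {
  p <- marker_positions(bl)
  if (nrow(p) < 2L) stop("point_at_arc needs >= 2 markers", call. = FALSE)
  seglen <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[base::length(cum)]
  if (is.na(s) || s < -1e-9 || s > total + 1e-9) {
    stop(sprintf("arc position %.6g outside [0, %.6g]", s, total), call. = FALSE)
  }
  s <- min(max(s, 0), total)
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- min(i, nrow(p) - 1L)
  f <- if (seglen[i] > 0) (s - cum[i]) / seglen[i] else 0
  nearer <- if (f <= 0.5) i else i + 1L
  m <- bl$markers[nearer, ]
  list(position = as.vector(p[i, ] * (1 - f) + p[i + 1L, ] * f),
       normal = unitize(c(m$nx, m$ny, m$nz), "marker normal"),
       tangent = unitize(c(m$tx, m$ty, m$tz), "marker tangent"))
}

#' Serialize a baseline to a plain-text table
#'
#' Tab-separated marker table (`index, x, y, z, nx, ny, nz, tx, ty, tz`) with
#' `#`-prefixed header lines recording seed, angle, spacing and mode, so a
#' trace can be inspected or re-supplied verbatim.
#'
#' @param bl a [baseline()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_baseline <- function(bl, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# seed\t%.17g\t%.17g\t%.17g", bl$seed[1], bl$seed[2], bl$seed[3]),
               sprintf("# angle\t%.17g", bl$angle),
               sprintf("# spacing\t%.17g", bl$spacing),
               sprintf("# mode\t%s", bl$mode),
               paste(c("index", names(bl$markers)), collapse = "\t")), con)
  df <- cbind(index = seq_len(nrow(bl$markers)), bl$markers)
  utils::write.table(format(df, digits = 17, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a baseline written by [write_baseline()]
#' @param path file path.
#' @return a [baseline()].
#' @export
read_baseline <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    l <- grep(paste0("^# ", key, "\\t"), hdr, value = TRUE)[1]
    strsplit(l, "\t")[[1]][-1]
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  baseline(df[, -1, drop = FALSE],
           seed = as.numeric(getv("seed")),
           angle = as.numeric(getv("angle")[1]),
           spacing = as.numeric(getv("spacing")[1]),
           mode = getv("mode")[1])
}
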