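the_catalog <- new.env(parent = emptyenv())

#' Parametric miniplate specification
#'
#' A straight miniplate is `n_end_rings + n_middle_rings` annular ring
#' elements (screw holes) joined by rectangular-cross-section bars. End rings
#' have one flat attachment side, middle rings two opposite ones. The flat
#' side is the chord of the ring circle at which the bar attaches, so the
#' ring's footprint between two attachment sides is
#' `attachment_width = 2 * sqrt(r^2 - (bridge_width/2)^2)` (with
#' `r = ring_outer_diameter / 2`). Bar lengths are the physical face-to-face
#' bridge lengths; consecutive ring centers are spaced by
#' `attachment_width + bar`, and the layout closes on the overall length:
#' `overall_length = ring_outer_diameter + (n-1) * attachment_width +
#' sum(bar_lengths)` (the end rings contribute one radius each beyond the
#' outermost centers).
#'
#' Given the printed overall length (and optionally a printed central bar
#' length), the free bar lengths are solved from this closure rule: all bars
#' equal when no central bar is pinned, otherwise the central bar is fixed
#' and the remaining bars are equal.
#'
#' @param model_id identifier string, e.g. `"M-4138"`.
#' @param n_end_rings number of end rings (must be 2).
#' @param n_middle_rings number of middle rings (>= 0).
#' @param overall_length end-to-end plate length in mm.
#' @param central_bar optional pinned central bar length in mm (requires an
#'   odd number of bars).
#' @param ring_outer_diameter,ring_hole_diameter,plate_thickness,bridge_width,bridge_height
#'   cross-section dimensions in mm.
#' @return object of class `plate_spec` with the fields above plus the solved
#'   `bar_lengths` and the derived `attachment_width`.
#' @export
plate_spec <- function(model_id, n_end_rings = 2L, n_middle_rings = 0L,
                       overall_length, central_bar = NULL,
                       ring_outer_diameter = 4.0, ring_hole_diameter = 2.0,
                       plate_thickness = 1.0, bridge_width = 2.0,
                       bridge_height = 1.0) {
  if (n_end_rings != 2L) stop("a straight plate has exactly 2 end rings", call. = FALSE)
  if (n_middle_rings < 0L) stop("n_middle_rings must be >= 0", call. = FALSE)
  dims <- c(overall_length, ring_outer_diameter, ring_hole_diameter,
            plate_thickness, bridge_width, bridge_height)
  if (any(dims <= 0)) stop("all plate dimensions must be positive", call. = FALSE)
  if (ring_hole_diameter >= ring_outer_diameter) {
    stop("ring_hole_diameter must be smaller than ring_outer_diameter", call. = FALSE)
  }
  if (bridge_width >= ring_outer_diameter) {
    stop("bridge_width must be smaller than ring_outer_diameter", call. = FALSE)
  }
  n <- n_end_rings + n_middle_rings
  nb <- n - 1L
  aw <- 2 * sqrt((ring_outer_diameter / 2)^2 - (bridge_width / 2)^2)
  budget <- overall_length - ring_outer_diameter - nb * aw
  if (is.null(central_bar)) {
    bars <- rep(budget / nb, nb)
  } else {
    if (nb %% 2L == 0L) stop("a pinned central bar needs an odd bar count", call. = FALSE)
    rest <- (budget - central_bar) / (nb - 1L)
    bars <- rep(rest, nb)
    bars[(nb + 1L) / 2L] <- central_bar
  }
  if (any(bars <= 0)) {
    stop(sprintf("model %s: layout closure gives non-positive bar lengths (%s)",
                 model_id, paste(signif(bars, 4), collapse = ", ")), call. = FALSE)
  }
  structure(list(model_id = model_id,
                 n_end_rings = as.integer(n_end_rings),
                 n_middle_rings = as.integer(n_middle_rings),
                 overall_length = overall_length,
                 bar_lengths = bars,
                 ring_outer_diameter = ring_outer_diameter,
                 ring_hole_diameter = ring_hole_diameter,
                 plate_thickness = plate_thickness,
                 bridge_width = bridge_width,
                 bridge_height = bridge_height,
                 attachment_width = aw),
            class = "plate_spec")
}

#' @export
print.plate_spec <- function(x, ...) {
  cat(sprintf("<plate_spec> %s: %d end + %d middle rings, overall %.6g mm\n",
              x$model_id, x$n_end_rings, x$n_middle_rings, x$overall_length))
  cat(sprintf("  bars [mm]: %s\n", paste(signif(x$bar_lengths, 6), collapse = ", ")))
  cat(sprintf("  ring OD %.6g, hole %.6g, thickness %.6g, bridge %.6g x %.6g mm\n",
              x$ring_outer_diameter, x$ring_hole_diameter, x$plate_thickness,
              x$bridge_width, x$bridge_height))
  invisible(x)
}

load_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "plate_catalog.yaml", package = "plateplanr")
  }
  raw <- yaml::read_yaml(path)
  defaults <- raw$defaults
  specs <- lapply(raw$models, function(m) {
    args <- utils::modifyList(defaults, m)
    do.call(plate_spec, args)
  })
  names(specs) <- vapply(specs, `[[`, "", "model_id")
  specs
}

#' Look up a catalog miniplate model
#'
#' The catalog ships as a human-editable YAML file
#' (`system.file("extdata", "plate_catalog.yaml", package = "plateplanr")`);
#' point `catalog_path` at a copy to add models without code changes.
#'
#' @param model_id one of the catalog identifiers (`"M-4138"`, `"M-4320"`,
#'   `"M-4322"` in the shipped catalog).
#' @param catalog_path optional path to an alternative catalog file.
#' @return a [plate_spec()].
#' @export
get_plate_spec <- function(model_id, catalog_path = NULL) {
  specs <- if (is.null(catalog_path)) {
    if (is.null(the_catalog$specs)) the_catalog$specs <- load_catalog()
    the_catalog$specs
  } else {
    load_catalog(catalog_path)
  }
  if (!model_id %in% names(specs)) {
    stop(sprintf("unknown plate model '%s'; available models: %s",
                 model_id, paste(names(specs), collapse = ", ")), call. = FALSE)
  }
  specs[[model_id]]
}

#' Arc-length positions of ring centers along the plate centerline
#'
#' Symmetric about 0 (the plate/baseline midpoint). Consecutive offsets are
#' separated by `attachment_width + bar`; the outermost centers sit at
#' `+/- (overall_length - ring_outer_diameter) / 2`.
#'
#' @param spec a [plate_spec()].
#' @return numeric vector of signed offsets (mm), ordered along the plate.
#' @export
ring_center_offsets <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  spacings <- spec$attachment_width + spec$bar_lengths
  pos <- c(0, cumsum(spacings))
  pos - sum(spacings) / 2
}

#' Kinds of ring element in the order they appear along the plate
#' @param spec a [plate_spec()].
#' @return character vector: `"end"`, then middles, then `"end"`.
#' @export
ring_kinds <- function(spec) {
  c("end", rep("middle", spec$n_middle_rings), "end")
}

# x-coordinate of the flat attachment chord in the canonical ring frame
attachment_x <- function(spec) spec$attachment_width / 2

#' Build the triangle mesh of one ring element
#'
#' A closed (watertight), consistently outward-wound annulus solid in the
#' canonical ring frame: ring-plane normal +z, origin at the ring center,
#' attachment direction +x. End rings have one flat chordal side
#' perpendicular to +x; middle rings have two opposite flat sides (+x and
#' -x). Each flat side exposes the rectangular bridge attachment face
#' (`bridge_width` x `plate_thickness`); the four face corners are mesh
#' vertices. Building twice with the same arguments yields bit-identical
#' meshes.
#'
#' @param spec a [plate_spec()].
#' @param kind `"end"` or `"middle"`.
#' @param angular_resolution number of regular angular samples (>= 8; the
#'   chord corner angles are inserted additionally).
#' @return a [trimesh()].
#' @export
build_ring_mesh <- function(spec, kind = c("end", "middle"),
                            angular_resolution = 64L) {
  kind <- match.arg(kind)
  if (angular_resolution < 8L) stop("angular_resolution must be >= 8", call. = FALSE)
  r_o <- spec$ring_outer_diameter / 2
  r_h <- spec$ring_hole_diameter / 2
  th <- spec$plate_thickness
  xc <- attachment_x(spec)
  half_w <- spec$bridge_width / 2
  theta_c <- atan2(half_w, xc)
  n0 <- as.integer(angular_resolution)
  ang <- 2 * pi * (0:(n0 - 1L)) / n0
  cuts <- c(theta_c, 2 * pi - theta_c)
  if (kind == "middle") cuts <- c(cuts, pi - theta_c, pi + theta_c)
  ang <- sort(unique(round(c(ang, cuts %% (2 * pi)), 12)))
  n <- length(ang)
  ca <- cos(ang); sa <- sin(ang)
  # outer boundary: circle clamped to the chord plane(s)
  fac <- rep(1, n)
  pos <- ca > xc / r_o
  fac[pos] <- xc / (r_o * ca[pos])
  if (kind == "middle") {
    neg <- ca < -xc / r_o
    fac[neg] <- -xc / (r_o * ca[neg])
  }
  ox <- r_o * fac * ca
  oy <- r_o * fac * sa
  ix <- r_h * ca
  iy <- r_h * sa
  zt <- th / 2
  verts <- rbind(cbind(ox, oy, zt),    # OT: 1..n
                 cbind(ox, oy, -zt),   # OB: n+1..2n
                 cbind(ix, iy, zt),    # IT: 2n+1..3n
                 cbind(ix, iy, -zt))   # IB: 3n+1..4n
  OT <- 1:n; OB <- n + 1:n; IT <- 2L * n + 1:n; IB <- 3L * n + 1:n
  nx <- c(2:n, 1L)
  faces <- rbind(
    # top washer (+z): outer edge runs CCW seen from above
    cbind(OT, OT[nx], IT[nx]), cbind(OT, IT[nx], IT),
    # bottom washer (-z): reversed
    cbind(OB[nx], OB, IB), cbind(OB[nx], IB, IB[nx]),
    # outer wall (radially outward)
    cbind(OB, OB[nx], OT[nx]), cbind(OB, OT[nx], OT),
    # hole wall (normals toward the axis)
    cbind(IB[nx], IB, IT), cbind(IB[nx], IT, IT[nx]))
  trimesh(verts, faces)
}

#' Corners of a ring's flat attachment face
#'
#' Computed analytically in the canonical ring frame (center at origin,
#' normal +z, attachment direction +x) from the bridge cross-section - not by
#' mesh search. Corner order is counter-clockwise as seen from outside the
#' requested side, starting at the bottom corner that a bridge cross-section
#' rectangle (see [bridge_cross_rect()]) lists first, so swept bridges attach
#' without twist.
#'
#' @param spec a [plate_spec()].
#' @param kind `"end"` (side `"+x"` only) or `"middle"`.
#' @param side `"+x"` or `"-x"`.
#' @return 4 x 3 matrix of corner coordinates (mm).
#' @export
attachment_corners <- function(spec, kind = c("end", "middle"),
                               side = c("+x", "-x")) {
  kind <- match.arg(kind)
  side <- match.arg(side)
  if (kind == "end" && side == "-x") {
    stop("an end ring has no -x attachment side", call. = FALSE)
  }
  xc <- attachment_x(spec)
  hw <- spec$bridge_width / 2
  hh <- spec$bridge_height / 2
  if (side == "+x") {
    rbind(c(xc, -hw, -hh), c(xc, hw, -hh), c(xc, hw, hh), c(xc, -hw, hh))
  } else {
    rbind(c(-xc, hw, -hh), c(-xc, -hw, -hh), c(-xc, -hw, hh), c(-xc, hw, hh))
  }
}
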