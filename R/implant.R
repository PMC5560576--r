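#' Rigid pose of a ring element at a baseline marker
#'
#' First the canonical ring normal (+z) is rotated onto the marker normal
#' ([rotation_between()]); then a second rotation about the marker normal
#' aligns the mapped canonical attachment direction (+x) with the projection
#' of the marker tangent onto the plane perpendicular to the normal. Only
#' this two-dimensional direction alignment is possible: the marker's normal
#' and tangent need not be perpendicular, while the ring's always are, so
#' the normal is aligned in full 3D and the direction within the tangent
#' plane. The translation moves the ring center to the marker position.
#'
#' @param marker a list with `position`, `normal`, `tangent` (see
#'   [baseline_marker()], [point_at_arc()]).
#' @param canonical_normal,canonical_direction the ring's own frame
#'   (defaults +z, +x).
#' @return a [rigid_transform()].
#' @export
ring_pose <- function(marker, canonical_normal = c(0, 0, 1),
                      canonical_direction = c(1, 0, 0)) {
  n <- unitize(marker$normal, "marker normal")
  tp <- marker$tangent - sum(marker$tangent * n) * n
  if (vnorm(tp) < 1e-6) {
    stop("degenerate marker frame: tangent (near-)parallel to normal", call. = FALSE)
  }
  tp <- tp / vnorm(tp)
  R1 <- rotation_between(canonical_normal, n)$rotation
  d1 <- as.vector(R1 %*% canonical_direction)
  d1 <- d1 - sum(d1 * n) * n
  d1 <- unitize(d1, "mapped canonical direction")
  phi <- atan2(sum(n * cross3(rbind(d1), rbind(tp))[1, ]), sum(d1 * tp))
  R <- rotation_about_axis(n, phi)$rotation %*% R1
  rigid_transform(R, marker$position, validate = FALSE)
}

#' Place all ring elements of a plate along a baseline
#'
#' Ring centers go to the arc positions of [ring_center_offsets()], shifted
#' so offset 0 maps to the baseline's arc midpoint. The outermost rings are
#' end rings (one attachment side, facing inward); the final end ring's
#' tangent is reversed so its single attachment side faces its bridge.
#'
#' @param bl a [baseline()] with arc length at least
#'   `overall_length - spacing`.
#' @param spec a [plate_spec()].
#' @param surface_offset extra lift of each ring center along the marker
#'   normal (mm); 0 keeps the ring mid-plane through the marker.
#' @return list of `list(transform, kind, arc)` per ring, ordered along the
#'   baseline.
#' @export
place_rings <- function(bl, spec, surface_offset = 0) {
  total <- arc_length(bl)
  if (total < spec$overall_length - bl$spacing - 1e-9) {
    stop(sprintf("baseline too short for %s: arc length %.3f mm < plate length %.3f mm (deficit %.3f mm)",
                 spec$model_id, total, spec$overall_length,
                 spec$overall_length - total), call. = FALSE)
  }
  offs <- ring_center_offsets(spec)
  kinds <- ring_kinds(spec)
  mid <- total / 2
  n <- length(offs)
  lapply(seq_len(n), function(i) {
    s <- min(max(mid + offs[i], 0), total)
    mk <- point_at_arc(bl, s)
    if (i == n) mk$tangent <- -mk$tangent  # last end ring faces backward
    tf <- ring_pose(mk)
    if (surface_offset != 0) {
      tf$translation <- tf$translation + surface_offset * mk$normal
    }
    list(transform = tf, kind = kinds[i], arc = s)
  })
}

#' Bridge cross-section rectangle at a marker
#'
#' A `width x height` rectangle centered at the marker position, spanned by
#' the lateral axis `tangent x normal` (width) and the marker normal
#' (height). Corner order matches the attachment-face convention of
#' [attachment_corners()], so consecutive rectangles connect without twist.
#'
#' @param marker list with `position`, `normal`, `tangent`.
#' @param width,height cross-section dimensions (mm).
#' @return 4 x 3 matrix of corners.
#' @export
bridge_cross_rect <- function(marker, width, height) {
  n <- unitize(marker$normal, "marker normal")
  lat <- cross3(rbind(marker$tangent), rbind(n))[1, ]
  if (vnorm(lat) < 1e-9) stop("degenerate marker frame for bridge rectangle",
                              call. = FALSE)
  lat <- lat / vnorm(lat)
  p <- marker$position
  hw <- width / 2
  hh <- height / 2
  rbind(p + hw * lat - hh * n,
        p - hw * lat - hh * n,
        p - hw * lat + hh * n,
        p + hw * lat + hh * n)
}

#' Sweep a triangulated bridge through a sequence of rectangles
#'
#' For each consecutive rectangle pair (one "block") and each of its four
#' side quads, the quad (N1, N2 on the near rectangle; N3, N4 opposite them
#' on the far one) is split into triangles T1 = (N1, N2, N3) and
#' T2 = (N1, N3, N4), giving exactly `8 * (k - 1)` triangles for `k`
#' rectangles. Winding makes the side normals point outward from the bridge
#' axis. The two ends stay open - they abut the ring attachment faces.
#'
#' @param rects list of 4 x 3 corner matrices in consistent corner order
#'   (at least 2).
#' @return a [trimesh()].
#' @export
sweep_bridge <- function(rects) {
  if (!is.list(rects) || length(rects) < 2L) {
    stop("sweep_bridge needs at least 2 rectangles", call. = FALSE)
  }
  if (any(vapply(rects, function(r) !is.matrix(r) || !all(dim(r) == c(4L, 3L)),
                 logical(1)))) {
    stop("every cross-section must be a 4 x 3 corner matrix", call. = FALSE)
  }
  k <- length(rects)
  verts <- do.call(rbind, rects)
  idx <- function(b, j) (b - 1L) * 4L + ((j - 1L) %% 4L) + 1L
  faces <- matrix(0L, 8L * (k - 1L), 3L)
  r <- 0L
  for (b in seq_len(k - 1L)) {
    for (j in 1:4) {
      n1 <- idx(b, j); n2 <- idx(b, j + 1L)
      n3 <- idx(b + 1L, j + 1L); n4 <- idx(b + 1L, j)
      faces[r + 1L, ] <- c(n1, n2, n3)
      faces[r + 2L, ] <- c(n1, n3, n4)
      r <- r + 2L
    }
  }
  trimesh(verts, faces)
}

#' Assemble a miniplate implant along a baseline
#'
#' Rings are placed with [place_rings()]; for every consecutive ring pair the
#' bridge cross-section sequence is: the near ring's transformed attachment
#' face, a [bridge_cross_rect()] at every baseline marker strictly between
#' the two attachment faces, then the far ring's transformed attachment face
#' (corners re-ordered into the marker convention). All parts are merged
#' without welding, so the face count is the exact sum of ring and bridge
#' face counts.
#'
#' @param bone a [trimesh()] (kept as provenance; the geometry comes from the
#'   baseline).
#' @param bl a [baseline()].
#' @param spec a [plate_spec()].
#' @param surface_offset see [place_rings()]; e.g.
#'   `spec$plate_thickness / 2` to keep the plate fully above the surface.
#' @param angular_resolution passed to [build_ring_mesh()].
#' @return object of class `implant_model`: list with `mesh`, `spec_id`,
#'   `spec`, `baseline`, `ring_poses`, `ring_kinds`, `bridge_sizes` (number
#'   of rectangles per bridge).
#' @export
assemble_implant <- function(bone, bl, spec, surface_offset = 0,
                             angular_resolution = 64L) {
  poses <- place_rings(bl, spec, surface_offset)
  templates <- list(end = build_ring_mesh(spec, "end", angular_resolution),
                    middle = build_ring_mesh(spec, "middle", angular_resolution))
  ring_meshes <- lapply(poses, function(p) apply_transform(templates[[p$kind]],
                                                           p$transform))
  xc <- attachment_x(spec)
  n <- length(poses)
  seglen <- {
    p <- marker_positions(bl)
    sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  }
  cum <- c(0, cumsum(seglen))
  # far-face corners (outward direction opposing the travel direction) map to
  # the marker-rectangle corner convention by swapping within each z level
  far_perm <- c(2L, 1L, 4L, 3L)
  bridges <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    near_side <- "+x"                         # rings are oriented along the arc
    far_side <- if (i + 1L < n) "-x" else "+x"  # last end ring is flipped
    near <- transform_points(attachment_corners(spec, poses[[i]]$kind, near_side),
                             poses[[i]]$transform)
    far <- transform_points(attachment_corners(spec, poses[[i + 1L]]$kind, far_side),
                            poses[[i + 1L]]$transform)[far_perm, , drop = FALSE]
    s_lo <- poses[[i]]$arc + xc
    s_hi <- poses[[i + 1L]]$arc - xc
    inner <- which(cum > s_lo + 1e-9 & cum < s_hi - 1e-9)
    rects <- c(list(near),
               lapply(inner, function(j) {
                 mk <- baseline_marker(bl, j)
                 r <- bridge_cross_rect(mk, spec$bridge_width, spec$bridge_height)
                 if (surface_offset != 0) {
                   r <- r + matrix(surface_offset * mk$normal, 4L, 3L, byrow = TRUE)
                 }
                 r
               }),
               list(far))
    bridges[[i]] <- sweep_bridge(rects)
  }
  mesh <- merge_meshes(c(ring_meshes, bridges))
  structure(list(mesh = mesh,
                 spec_id = spec$model_id,
                 spec = spec,
                 baseline = bl,
                 ring_poses = lapply(poses, `[[`, "transform"),
                 ring_kinds = vapply(poses, `[[`, "", "kind"),
                 ring_arcs = vapply(poses, `[[`, 0, "arc"),
                 bridge_sizes = vapply(bridges, function(b) nrow(b$faces) / 8L + 1L,
                                       0)),
            class = "implant_model")
}

#' @export
print.implant_model <- function(x, ...) {
  cat(sprintf("<implant_model> %s: %d rings, %d bridges, %d faces\n",
              x$spec_id, length(x$ring_poses), length(x$bridge_sizes),
              nrow(x$mesh$faces)))
  invisible(x)
}

#' End-to-end extent of an implant along a direction
#' @param implant an `implant_model` (or any `trimesh` via `implant$mesh`).
#' @param direction 3-vector; projections of all mesh vertices onto it are
#'   ranged.
#' @return extent in mm.
#' @export
implant_extent <- function(implant, direction) {
  mesh <- if (inherits(implant, "implant_model")) implant$mesh else implant
  d <- unitize(as.numeric(direction), "direction")
  pr <- mesh$vertices %*% d
  max(pr) - min(pr)
}

#' Minimum signed clearance between an implant and the bone surface
#'
#' Diagnostic only - assembly never blocks on interpenetration. For a sample
#' of implant vertices, the signed distance to the bone along the local bone
#' normal is computed via [closest_surface_frame()]; negative values mean the
#' plate dips below the surface (expected up to half the plate thickness when
#' `surface_offset = 0`).
#'
#' @param implant an `implant_model`.
#' @param bone the bone [trimesh()].
#' @param max_vertices sample size cap (the mesh vertices are subsampled
#'   deterministically, evenly along the vertex order).
#' @return minimum signed clearance in mm.
#' @export
implant_clearance <- function(implant, bone, max_vertices = 200L) {
  v <- implant$mesh$vertices
  if (nrow(v) > max_vertices) {
    v <- v[round(seq(1L, nrow(v), length.out = max_vertices)), , drop = FALSE]
  }
  signed <- apply(v, 1L, function(p) {
    fr <- closest_surface_frame(bone, p)
    sum((p - fr$point) * fr$normal)
  })
  min(signed)
}
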