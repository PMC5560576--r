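flat_marker <- function() list(position = c(0, 0, 0), normal = c(0, 0, 1),
                               tangent = c(1, 0, 0))

test_that("ring_pose aligns the normal fully and the direction in-plane", {
  tf <- ring_pose(flat_marker())
  expect_vec_equal(tf$rotation, diag(3), 1e-12)
  expect_vec_equal(tf$translation, c(0, 0, 0))

  mk <- flat_marker(); mk$tangent <- c(0, 1, 0)
  tf <- ring_pose(mk)
  expect_vec_equal(tf$rotation, rotation_about_axis(c(0, 0, 1), pi / 2)$rotation,
                   1e-12)

  set.seed(21)
  for (i in 1:30) {
    n <- rand_unit()
    t <- rand_unit()
    if (abs(sum(n * t)) > 0.95) next
    mk <- list(position = rnorm(3, sd = 20), normal = n, tangent = t)
    tf <- ring_pose(mk)
    R <- tf$rotation
    # mapped canonical normal coincides with the marker normal
    expect_gte(sum((R %*% c(0, 0, 1)) * n), 1 - 1e-9)
    # mapped direction projects onto the marker tangent's in-plane direction
    d <- as.vector(R %*% c(1, 0, 0))
    tp <- t - sum(t * n) * n
    expect_gt(sum(d * tp) / sqrt(sum(tp^2)), 1 - 1e-9)
    # proper rotation
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
  }

  bad <- list(position = c(0, 0, 0), normal = c(0, 0, 1), tangent = c(0, 0, 1))
  expect_error(ring_pose(bad), "degenerate")
})

test_that("placed rings are isometric copies of the canonical template", {
  spec <- get_plate_spec("M-4138")
  template <- build_ring_mesh(spec, "middle")
  dref <- dist(template$vertices)
  set.seed(33)
  for (i in 1:5) {
    n <- rand_unit(); t <- rand_unit()
    if (abs(sum(n * t)) > 0.9) t <- unit3(t - 0.5 * sum(t * n) * n)
    mk <- list(position = rnorm(3, sd = 30), normal = n, tangent = t)
    moved <- apply_transform(template, ring_pose(mk))
    expect_lt(max(abs(dist(moved$vertices) - dref) / pmax(dref, 1e-12)), 1e-9)
  }
})

test_that("place_rings spaces centers by the catalog offsets along the arc", {
  m <- make_plane(100, 100, 51)
  spec <- get_plate_spec("M-4138")
  bl <- trace_baseline(m, c(0, 0, 0), 0, length = spec$overall_length)
  pr <- place_rings(bl, spec)
  centers <- t(vapply(pr, function(p) p$transform$translation, numeric(3)))
  expect_equal(nrow(centers), 4L)
  # collinear along x, symmetric about the seed
  expect_lt(max(abs(centers[, 2])), 1e-9)
  expect_lt(max(abs(centers[, 3])), 1e-9)
  expect_lt(abs(sum(centers[, 1])), 1e-9)
  expect_equal(max(centers[, 1]) - min(centers[, 1]),
               spec$overall_length - spec$ring_outer_diameter, tolerance = 1e-9)
  expect_equal(vapply(pr, `[[`, "", "kind"), c("end", "middle", "middle", "end"))
  # all ring normals point up on the plane
  for (p in pr) {
    expect_vec_equal(p$transform$rotation %*% c(0, 0, 1), c(0, 0, 1), 1e-9)
  }

  # hemisphere: ring centers stay on the sphere within the facet sag
  h <- make_hemisphere(50, 100)
  blh <- trace_baseline(h, c(0, 0, 60), 0.4, length = spec$overall_length)
  prh <- place_rings(blh, spec)
  ch <- t(vapply(prh, function(p) p$transform$translation, numeric(3)))
  expect_lt(max(abs(sqrt(rowSums(ch^2)) - 50)), 0.05)

  # too-short baseline errors with the deficit
  short <- trace_baseline(m, c(0, 0, 0), 0, length = 10)
  expect_error(place_rings(short, spec), "deficit")
})

test_that("bridge cross-section rectangles span lateral x normal", {
  r <- bridge_cross_rect(flat_marker(), width = 2, height = 1)
  expect_vec_equal(colMeans(r), c(0, 0, 0))
  expect_setequal(round(r[, 2], 9), c(-1, 1))
  expect_setequal(round(r[, 3], 9), c(-0.5, 0.5))
  expect_true(all(r[, 1] == 0))
  d <- as.matrix(dist(r))
  expect_setequal(round(c(d[1, 2], d[2, 3], d[3, 4], d[4, 1]), 9), c(2, 1))

  # coplanarity for a skewed frame (normal and tangent not perpendicular)
  mk <- list(position = c(3, -2, 7), normal = c(0, 0, 1),
             tangent = unit3(c(1, 0, 0.4)))
  r <- bridge_cross_rect(mk, 2, 1)
  expect_vec_equal(colMeans(r), mk$position, 1e-12)
  nrm <- xprod(r[2, ] - r[1, ], r[4, ] - r[1, ])
  expect_lt(abs(sum((r[3, ] - r[1, ]) * nrm)) / sqrt(sum(nrm^2)), 1e-9)
})

test_that("sweep_bridge triangulates 8 (k - 1) faces with prism side area", {
  sq <- function(x0) rbind(c(x0, 0.5, -0.5), c(x0, -0.5, -0.5),
                           c(x0, -0.5, 0.5), c(x0, 0.5, 0.5))
  b2 <- sweep_bridge(list(sq(0), sq(1)))
  expect_equal(nrow(b2$faces), 8L)
  expect_equal(mesh_area(b2), 4, tolerance = 1e-12)
  b3 <- sweep_bridge(list(sq(0), sq(0.5), sq(1)))
  expect_equal(nrow(b3$faces), 16L)

  # straight sweep, w x h cross-section, length L: side area 2 L (w + h)
  w <- 2; h <- 1; L <- 7
  rects <- lapply(seq(0, L, by = 0.5), function(x) {
    mk <- list(position = c(x, 0, 0), normal = c(0, 0, 1), tangent = c(1, 0, 0))
    bridge_cross_rect(mk, w, h)
  })
  swept <- sweep_bridge(rects)
  expect_equal(mesh_area(swept), 2 * L * (w + h), tolerance = 1e-9)
  # outward winding: normals never point toward the sweep axis
  nrm <- face_normals(swept)
  ctr <- (swept$vertices[swept$faces[, 1], ] + swept$vertices[swept$faces[, 2], ] +
            swept$vertices[swept$faces[, 3], ]) / 3
  radial <- ctr - cbind(ctr[, 1], 0, 0)
  expect_true(all(rowSums(nrm * radial) > 0))

  expect_error(sweep_bridge(list(sq(0))), "at least 2")
  expect_error(sweep_bridge(list(sq(0), sq(1)[1:3, ])), "4 x 3")
})

test_that("assembled implants reproduce the catalog lengths on a plane", {
  m <- make_plane(100, 100, 51)
  for (id in c("M-4138", "M-4320", "M-4322")) {
    spec <- get_plate_spec(id)
    bl <- trace_baseline(m, c(0, 0, 0), 0, length = spec$overall_length)
    imp <- assemble_implant(m, bl, spec)
    expect_equal(implant_extent(imp, c(1, 0, 0)), spec$overall_length,
                 tolerance = 0.5 / spec$overall_length)
    # plate stays within the mid-plane bound on the flat surface
    expect_gte(min(imp$mesh$vertices[, 3]), -spec$plate_thickness / 2 - 1e-9)
    expect_lte(max(imp$mesh$vertices[, 3]), spec$plate_thickness / 2 + 1e-9)
    # face bookkeeping: rings + 8 (k - 1) per bridge, exactly
    ring_faces <- vapply(imp$ring_kinds, function(k)
      nrow(build_ring_mesh(spec, k)$faces), 0)
    expect_equal(nrow(imp$mesh$faces),
                 sum(ring_faces) + sum(8 * (imp$bridge_sizes - 1)))
    expect_length(imp$ring_poses, spec$n_end_rings + spec$n_middle_rings)
    # every bridge has at least two blocks (>= 3 rectangles)
    expect_true(all(imp$bridge_sizes >= 3))
  }
})

test_that("surface_offset lifts the plate fully above a flat surface", {
  m <- make_plane(100, 100, 51)
  spec <- get_plate_spec("M-4138")
  bl <- trace_baseline(m, c(0, 0, 0), 0, length = spec$overall_length)
  imp <- assemble_implant(m, bl, spec, surface_offset = spec$plate_thickness / 2)
  expect_gte(min(imp$mesh$vertices[, 3]), -1e-9)
  expect_gte(implant_clearance(imp, m), -1e-9)
})

test_that("bridges conform to curved surfaces: rect centers near the bone", {
  w <- make_wave(100, 100, 101, 5, 40)
  spec <- get_plate_spec("M-4320")
  bl <- trace_baseline(w, c(0, 0, 0), 0, length = spec$overall_length)
  imp <- assemble_implant(w, bl, spec)
  # every baseline marker used for a bridge rectangle is on the surface, so
  # the implant's bridge vertices stay within the cross-section half-diagonal
  # of the wave
  expect_gt(implant_clearance(imp, w), -sqrt(1^2 + 0.5^2) - 0.05)
})

test_that("sessions save immutably and export the merged implants", {
  m <- make_plane(100, 100, 31)
  spec <- get_plate_spec("M-4138")
  bl <- trace_baseline(m, c(0, 0, 0), 0, length = spec$overall_length)
  imp1 <- assemble_implant(m, bl, spec)
  bl2 <- trace_baseline(m, c(0, 20, 0), pi / 2, length = spec$overall_length)
  imp2 <- assemble_implant(m, bl2, spec)

  s <- planning_session()
  expect_error(save_current(s), "no current")
  expect_error(export_session(s, tempfile()), "empty session")

  s <- set_current(s, imp1)
  s <- save_current(s)
  expect_length(s$saved, 1L)
  expect_null(s$current)
  expect_error(save_current(s), "no current")

  s <- set_current(s, imp2)
  f <- tempfile(fileext = ".stl")
  export_session(s, f)  # 1 saved + 1 current
  back <- read_stl(f)
  expect_equal(nrow(back$faces), nrow(imp1$mesh$faces) + nrow(imp2$mesh$faces))

  s <- save_current(s)
  expect_length(s$saved, 2L)
})
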