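test_that("seed_frame yields the surface normal and the rotated tangent", {
  m <- make_plane(100, 100, 21)
  fr <- seed_frame(m, c(0, 0, 0), 0)
  expect_vec_equal(fr$normal, c(0, 0, 1))
  expect_vec_equal(fr$direction, c(1, 0, 0))
  fr90 <- seed_frame(m, c(0, 0, 0), pi / 2)
  expect_vec_equal(fr90$direction, c(0, 1, 0), 1e-12)

  # direction always lies in the tangent plane
  w <- make_wave(60, 60, 41, 4, 30)
  set.seed(3)
  for (i in 1:10) {
    fr <- seed_frame(w, c(runif(2, -20, 20), 10), runif(1, 0, 2 * pi))
    expect_lt(abs(sum(fr$direction * fr$normal)), 1e-9)
    expect_equal(vapply(list(fr$direction, fr$normal),
                        function(v) sqrt(sum(v^2)), 0), c(1, 1),
                 tolerance = 1e-9)
  }
})

test_that("cascade trace on a plane gives the full collinear marker grid", {
  m <- make_plane(100, 100, 21)
  fr <- seed_frame(m, c(0, 0, 0), 0)
  bl <- trace_cascade(m, fr$foot, fr$normal, fr$direction, length = 23,
                      spacing = 0.5, lift = 10)
  expect_equal(nrow(bl$markers), 47L)   # floor(L / spacing) + 1
  expect_true(all(abs(bl$markers$z) < 1e-9))
  expect_true(all(abs(bl$markers$y) < 1e-9))
  expect_equal(arc_length(bl), 23, tolerance = 1e-9)
  # markers ordered monotonically along the trace direction
  expect_true(all(diff(bl$markers$x) > 0))
})

test_that("marker adherence: markers lie on the analytic fixture surfaces", {
  w <- make_wave(100, 100, 101, 5, 40)
  for (mode in c("cascade", "marching")) {
    bl <- trace_baseline(w, c(0, 0, 0), 0, length = 23, mode = mode)
    p <- as.matrix(bl$markers[, 1:3])
    expect_lt(max(abs(p[, 3] - 5 * sin(2 * pi * p[, 1] / 40))), 0.05)
  }

  # hemisphere: markers are on the mesh; their deviation from the analytic
  # sphere is bounded by the facet chord sag
  h <- make_hemisphere(50, 100)
  bl <- trace_baseline(h, c(0, 0, 60), 0, length = 23)
  p <- as.matrix(bl$markers[, 1:3])
  on_mesh <- apply(p, 1, function(q) closest_surface_frame(h, q)$distance)
  expect_lt(max(on_mesh), 1e-9)
  sag <- 50 * (pi / 2 / 100)^2 / 2
  expect_lt(max(abs(sqrt(rowSums(p^2)) - 50)), sag)
})

test_that("marching adapts to a right-angle step, placing markers on the wall", {
  st <- make_step(100, 100, 51, 10)
  bl <- trace_baseline(st, c(-5, 0, 0), 0, length = 23, mode = "marching")
  p <- as.matrix(bl$markers[, 1:3])
  on_lower <- abs(p[, 3]) < 0.05 & p[, 1] < 0.05
  on_wall <- abs(p[, 1]) < 0.05 & p[, 3] > -0.05 & p[, 3] < 10.05
  on_upper <- abs(p[, 3] - 10) < 0.05 & p[, 1] > -0.05
  expect_true(all(on_lower | on_wall | on_upper))
  expect_gt(sum(on_lower), 5)
  expect_gt(sum(on_wall & p[, 3] > 0.05), 5)
  # consecutive markers stay within twice the spacing
  steps <- sqrt(rowSums(diff(p)^2))
  expect_lt(max(steps), 2 * bl$spacing + 1e-9)
  # arc length within one spacing of the request
  expect_lt(abs(arc_length(bl) - 23), 0.5 + 1e-9)
})

test_that("cascade and marching coincide on a flat surface", {
  m <- make_plane(100, 100, 21)
  a <- trace_baseline(m, c(0, 0, 0), 0.3, length = 29, mode = "cascade")
  b <- trace_baseline(m, c(0, 0, 0), 0.3, length = 29, mode = "marching")
  expect_equal(nrow(a$markers), nrow(b$markers))
  expect_lt(max(abs(as.matrix(a$markers[, 1:3]) - as.matrix(b$markers[, 1:3]))),
            1e-9)
})

test_that("tracing with angle theta equals rotating the angle-0 baseline", {
  m <- make_plane(100, 100, 21)
  theta <- 0.7
  a <- trace_baseline(m, c(0, 0, 0), theta, length = 23)
  b <- trace_baseline(m, c(0, 0, 0), 0, length = 23)
  R <- rotation_about_axis(c(0, 0, 1), theta)
  rot <- transform_points(as.matrix(b$markers[, 1:3]), R)
  expect_lt(max(abs(as.matrix(a$markers[, 1:3]) - rot)), 1e-9)
})

test_that("baseline traces are deterministic", {
  w <- make_wave(100, 100, 51, 5, 40)
  a <- trace_baseline(w, c(3, 2, 10), 1.1, length = 29)
  b <- trace_baseline(w, c(3, 2, 10), 1.1, length = 29)
  expect_identical(a, b)
})

test_that("misses are skipped with a warning and excessive misses fail", {
  # small plane: a 40 mm trace overhangs the 20 mm patch
  m <- make_plane(20, 20, 11)
  fr <- seed_frame(m, c(0, 0, 0), 0)
  expect_warning(
    bl <- trace_cascade(m, fr$foot, fr$normal, fr$direction, length = 30,
                        spacing = 0.5, lift = 5),
    "missed")
  expect_true(all(abs(bl$markers$x) <= 10 + 1e-9))
  expect_error(
    suppressWarnings(trace_cascade(m, fr$foot, fr$normal, fr$direction,
                                   length = 200, spacing = 0.5, lift = 5)),
    "missed")
  expect_error(
    trace_cascade(m, fr$foot, fr$normal, fr$direction, length = 30,
                  spacing = 0.5, lift = 5, on_miss = "error"),
    "missed")
})

test_that("arc_length sums marker distances", {
  df <- data.frame(x = c(0, 3), y = c(0, 4), z = c(0, 0),
                   nx = 0, ny = 0, nz = 1, tx = 0.6, ty = 0.8, tz = 0)
  bl <- baseline(df, c(0, 0, 0), 0, 0.5, "cascade")
  expect_equal(arc_length(bl), 5)
  bl1 <- baseline(df[1, ], c(0, 0, 0), 0, 0.5, "cascade")
  expect_equal(arc_length(bl1), 0)

  set.seed(77)
  p <- matrix(cumsum(rnorm(30)), 10, 3)
  df <- data.frame(x = p[, 1], y = p[, 2], z = p[, 3],
                   nx = 0, ny = 0, nz = 1, tx = 1, ty = 0, tz = 0)
  bl <- baseline(df, c(0, 0, 0), 0, 0.5, "cascade")
  expect_equal(arc_length(bl), sum(sqrt(rowSums(diff(p)^2))), tolerance = 1e-12)
})

test_that("point_at_arc interpolates and is 1-Lipschitz in arc length", {
  m <- make_wave(100, 100, 51, 5, 40)
  bl <- trace_baseline(m, c(0, 0, 0), 0, length = 29)
  total <- arc_length(bl)
  expect_vec_equal(point_at_arc(bl, 0)$position,
                   unlist(bl$markers[1, 1:3], use.names = FALSE))
  expect_error(point_at_arc(bl, total + 1), "outside")

  set.seed(5)
  ss <- runif(20, 0, total)
  pts <- t(vapply(ss, function(s) point_at_arc(bl, s)$position, numeric(3)))
  for (i in 1:19) {
    expect_lte(sqrt(sum((pts[i + 1, ] - pts[i, ])^2)),
               abs(ss[i + 1] - ss[i]) + 1e-9)
  }

  # straight baseline: midpoint at half arc
  pl <- make_plane(100, 100, 21)
  blp <- trace_baseline(pl, c(0, 0, 0), 0, length = 23)
  expect_vec_equal(point_at_arc(blp, arc_length(blp) / 2)$position, c(0, 0, 0),
                   1e-9)
})

test_that("baselines round-trip through the plain-text marker table", {
  m <- make_wave(100, 100, 51, 5, 40)
  bl <- trace_baseline(m, c(1, 2, 10), 0.4, length = 23)
  f <- tempfile(fileext = ".tsv")
  write_baseline(bl, f)
  back <- read_baseline(f)
  expect_equal(back$seed, bl$seed)
  expect_equal(back$angle, bl$angle)
  expect_equal(back$mode, bl$mode)
  expect_equal(as.matrix(back$markers), as.matrix(bl$markers), tolerance = 1e-12)
})
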