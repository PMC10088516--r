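test_that("perpendicular and oblique cylinder sections match plane geometry", {
  ch <- cylinder_chain()
  poly <- cross_section_contour(ch$mesh, c(0, 0, 20), c(0, 0, 1))
  m <- contour_metrics(poly, check = FALSE)
  expect_lt(abs(m$area_mm2 / (pi * 4) - 1), 0.02)

  # plane at 60 degrees to the axis: ellipse with axis ratio cos(60) = 0.5
  ang <- 60 * pi / 180
  poly2 <- cross_section_contour(ch$mesh, c(0, 0, 20),
                                 c(sin(ang), 0, cos(ang)))
  m2 <- contour_metrics(poly2, check = FALSE)
  expect_lt(abs(m2$min_max_ratio / 0.5 - 1), 0.03)

  expect_error(cross_section_contour(ch$mesh, c(0, 0, 200), c(0, 0, 1)),
               "does not intersect")
  # plane crosses the mesh but the point is outside the lumen
  expect_error(cross_section_contour(ch$mesh, c(3.2, 0, 20), c(0, 0, 1)),
               "outside the lumen|does not intersect")
  expect_error(cross_section_contour(ch$mesh, c(0, 0, 20), c(0, 0, 0)),
               "nonzero")
})

test_that("contour metrics reproduce closed forms", {
  # regular 360-gon of circumradius 1 is numerically a circle
  ang <- seq(0, 2 * pi, length.out = 361)[-361]
  m <- contour_metrics(cbind(cos(ang), sin(ang)))
  expect_lt(abs(m$area_mm2 - pi), 1e-3)
  expect_lt(abs(m$perimeter_mm - 2 * pi), 1e-3)
  expect_gt(m$circularity, 0.9999)
  expect_lt(abs(m$min_diameter_mm - 2), 1e-3)
  expect_lt(abs(m$max_diameter_mm - 2), 1e-3)

  # unit square
  sq <- contour_metrics(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(sq$area_mm2, 1)
  expect_equal(sq$perimeter_mm, 4)
  expect_equal(sq$circularity, pi / 4)
  expect_equal(sq$min_diameter_mm, 1)
  expect_equal(sq$max_diameter_mm, sqrt(2))

  # 2:1 ellipse against quadrature oracles
  el <- contour_metrics(cbind(2 * cos(ang), sin(ang)))
  expect_lt(abs(el$area_mm2 / (2 * pi) - 1), 0.005)
  expect_lt(abs(el$min_max_ratio / 0.5 - 1), 0.01)
  expect_lt(abs(el$perimeter_mm / ellipse_perimeter(2, 1) - 1), 0.005)

  expect_error(contour_metrics(rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))),
               "self-intersecting")
  expect_error(contour_metrics(rbind(c(0, 0), c(1, 0), c(2, 0))), "area")
  expect_error(contour_metrics(rbind(c(0, 0), c(1, 0))), "3 vertices")
})

test_that("circularity never exceeds 1 on random star-shaped polygons", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    th <- sort(runif(n, 0, 2 * pi))
    r <- runif(n, 0.5, 2)
    m <- contour_metrics(cbind(r * cos(th), r * sin(th)), check = FALSE)
    expect_lte(m$circularity, 1)
    expect_lte(m$min_diameter_mm, m$max_diameter_mm)
    expect_lte(m$area_mm2, pi * m$max_diameter_mm^2 / 4 + 1e-12)
  }
})

test_that("the per-point feature table matches phantom truth", {
  ch <- cylinder_chain()
  pf <- mid_rows(ch$features)
  expect_lt(abs(mean(pf$area_mm2) / (pi * 4) - 1), 0.03)
  expect_gt(mean(pf$circularity), 0.98)
  # 2*misr, min and max diameter each within 5% of the true diameter
  expect_lt(abs(mean(2 * pf$misr_mm) / 4 - 1), 0.05)
  expect_lt(abs(mean(pf$min_diameter_mm) / 4 - 1), 0.05)
  expect_lt(abs(mean(pf$max_diameter_mm) / 4 - 1), 0.05)

  tc <- torus_chain()
  tf <- mid_rows(tc$features)
  expect_lt(abs(mean(tf$curvature_per_mm) / 0.1 - 1), 0.05)
  expect_lt(abs(mean(tf$area_mm2) / (pi * 4) - 1), 0.03)

  expect_true(all(!ch$features$missing))
})

test_that("failed cross-sections are recorded as missing, not dropped", {
  ch <- cylinder_chain()
  # a centerline escaping the lumen at one end: those points fail but the
  # branch survives below the 20% quality threshold
  pts <- cbind(0, 0, seq(4, 36, by = 0.284))
  pts[1:3, 1] <- 5 # outside the radius-2 tube
  cl <- analytic_centerline(pts, misr = 2)
  feats <- point_features(ch$mesh, cl)
  expect_identical(nrow(feats), nrow(pts))
  expect_true(all(feats$missing[1:3]))
  expect_true(all(is.na(feats$area_mm2[1:3])))
  expect_false(any(feats$missing[10:50]))

  # > 20% failures is a branch-level quality error
  bad <- cbind(5, 0, seq(4, 36, by = 0.284))
  expect_error(point_features(ch$mesh, analytic_centerline(bad, misr = 2)),
               "quality")
})

test_that("feature estimates are stable under rigid rotation", {
  set.seed(3)
  vals <- lapply(1:3, function(i) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- runif(1, 0.3, 1.2)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    spec <- tube_spec("cylinder", radius_mm = 2, length_mm = 25,
                      pose = list(rotation = R, translation = c(0, 0, 0)))
    ch <- phantom_chain(spec)
    colMeans(mid_rows(ch$features)[, c("area_mm2", "misr_mm", "max_diameter_mm",
                                       "perimeter_mm")])
  })
  vals <- do.call(rbind, vals)
  spread <- apply(vals, 2, function(x) diff(range(x)) / mean(x))
  expect_true(all(spread < 0.02))
})
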