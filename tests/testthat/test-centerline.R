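test_that("cylinder centerline recovers the axis and the true misr", {
  ch <- cylinder_chain()
  b <- ch$centerline$branches[[1]]
  # misr = 2.0 +- one voxel, everywhere
  expect_true(all(abs(b$misr_mm - 2) < 0.284))
  # RMS deviation from the true axis below half a voxel
  rms <- sqrt(mean(b$points[, 1]^2 + b$points[, 2]^2))
  expect_lt(rms, 0.5 * 0.284)
})

test_that("torus centerline hugs the bend-radius circle", {
  ch <- torus_chain()
  b <- ch$centerline$branches[[1]]
  dev <- sqrt((sqrt(b$points[, 1]^2 + b$points[, 2]^2) - 10)^2 + b$points[, 3]^2)
  expect_lt(max(dev), 0.5 * 0.284)
})

test_that("degenerate and out-of-mask endpoints raise errors", {
  ch <- cylinder_chain()
  p <- c(0, 0, 20)
  expect_error(compute_centerline(ch$mask, list(rbind(p, p))), "degenerate")
  expect_error(compute_centerline(ch$mask, list(rbind(c(50, 50, 50), p))),
               "outside the mask")
})

test_that("bifurcation paths merge into a tree with a shared junction", {
  ph <- make_tube_phantom(
    tube_spec("bifurcation", radius_mm = c(2, 1.5, 1.5), length_mm = 20,
              daughter_length_mm = 15, branch_angle_deg = 35), 0.284)
  tr <- ph$truth
  src <- as.numeric(tr[tr$branch_id == 1, ][1, c("x", "y", "z")]) + c(0, 0, 2)
  tips <- lapply(2:3, function(d) {
    td <- tr[tr$branch_id == d, ]
    tip <- as.numeric(td[nrow(td), c("x", "y", "z")])
    root <- as.numeric(td[1, c("x", "y", "z")])
    tip - 2 * (tip - root) / sqrt(sum((tip - root)^2))
  })
  cl <- compute_centerline(ph$mask, list(rbind(src, tips[[1]]),
                                         rbind(src, tips[[2]])))
  expect_length(cl$branches, 3)
  parents <- vapply(cl$branches, `[[`, 1L, "parent")
  expect_identical(sum(is.na(parents)), 1L)
  root <- cl$branches[[which(is.na(parents))]]
  junction <- root$points[nrow(root$points), ]
  for (i in which(!is.na(parents)))
    expect_equal(cl$branches[[i]]$points[1, ], junction)
})

test_that("resampling yields uniform pitch with exact endpoints", {
  ch <- cylinder_chain()
  b <- ch$centerline$branches[[1]]
  # branch spans 40 - 2*4 = 32 mm; n = round(L/pitch)+1
  L <- max(b$arclength_mm)
  expect_lt(abs(nrow(b$points) - (round(L / 0.284) + 1)), 2)
  # chord lengths of the recentered (not perfectly straight) path: uniform
  # to well under the +-10% contract
  gaps <- sqrt(rowSums(diff(b$points)^2))
  expect_lt(max(abs(gaps / mean(gaps) - 1)), 0.01)
  expect_lt(abs(mean(gaps) - 0.284), 0.284 * 0.005)

  # analytic 40-mm straight branch: 142 +- 1 points, idempotent re-resampling
  pts <- cbind(0, 0, seq(0, 40, length.out = 200))
  cl1 <- resample_centerline(analytic_centerline(pts), 0.284)
  expect_lt(abs(nrow(cl1$branches[[1]]$points) - 141), 1.5)
  cl2 <- resample_centerline(cl1, 0.284)
  expect_lt(max(abs(cl1$branches[[1]]$points - cl2$branches[[1]]$points)), 1e-9)
  expect_equal(cl1$branches[[1]]$points[1, ], pts[1, ])
  expect_equal(cl1$branches[[1]]$points[nrow(cl1$branches[[1]]$points), ],
               pts[nrow(pts), ])

  # branches shorter than 2 * pitch are dropped
  short <- analytic_centerline(cbind(0, 0, seq(0, 0.4, length.out = 5)))
  expect_error(suppressWarnings(resample_centerline(short, 0.284)), "nothing")
  expect_warning(tryCatch(resample_centerline(short, 0.284),
                          error = function(e) NULL), "dropped")
})

test_that("Frenet features match closed forms on analytic curves", {
  # straight line: flagged straight, zero curvature and torsion
  line <- analytic_centerline(cbind(0, 0, seq(0, 40, by = 0.284)))
  fr <- frenet_features(line)
  expect_true(all(fr$curvature_per_mm == 0))
  expect_true(all(fr$torsion_per_mm == 0))
  expect_true(all(fr$straight))

  # circle radius 10: kappa = 0.1 within 1%, |tau| <= 1e-3 mid-branch
  th <- seq(0, pi, length.out = 120)
  circ <- frenet_features(analytic_centerline(cbind(10 * cos(th), 10 * sin(th), 0)))
  mid <- mid_rows(circ, 0.25, 0.75)
  expect_lt(abs(mean(mid$curvature_per_mm) * 10 - 1), 0.01)
  expect_lt(max(abs(mid$torsion_per_mm)), 1e-3)

  # helix a = 5, b = 2: kappa = 5/29, tau = 2/29, each within 2% mid-branch
  t2 <- seq(0, 3 * pi, length.out = 200)
  hel <- frenet_features(analytic_centerline(cbind(5 * cos(t2), 5 * sin(t2), 2 * t2)))
  mid <- mid_rows(hel, 0.25, 0.75)
  expect_lt(abs(mean(mid$curvature_per_mm) / (5 / 29) - 1), 0.02)
  expect_lt(abs(mean(mid$torsion_per_mm) / (2 / 29) - 1), 0.02)

  expect_error(frenet_features(analytic_centerline(cbind(0, 0, 1:3))), ">= 5")
})
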