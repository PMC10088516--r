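test_that("cylinder voxelisation matches the analytic volume and converges", {
  spec <- tube_spec("cylinder", radius_mm = 2, length_mm = 40)
  ph <- make_tube_phantom(spec, 0.284)
  analytic <- pi * 2^2 * 40
  expect_lt(abs(mask_volume(ph$mask) / analytic - 1), 0.02)

  # halving the spacing halves the error (or the error is already at the
  # sub-0.5% convergence floor)
  err <- vapply(c(0.568, 0.284), function(h) {
    abs(mask_volume(make_tube_phantom(spec, h)$mask) / analytic - 1)
  }, 0)
  expect_true(err[2] <= err[1] / 2 || err[2] < 0.005)
})

test_that("ground truth carries the Frenet closed forms exactly", {
  hel <- make_tube_phantom(
    tube_spec("helix", radius_mm = 1.2, coil_radius_mm = 5, pitch_mm = 2,
              turns = 1.5), 0.284)
  expect_equal(unique(hel$truth$curvature_per_mm), 5 / 29)
  expect_equal(unique(hel$truth$torsion_per_mm), 2 / 29)

  tor <- make_tube_phantom(
    tube_spec("torus_arc", radius_mm = 2, bend_radius_mm = 10), 0.284)
  expect_equal(unique(tor$truth$curvature_per_mm), 1 / 10)
  expect_equal(unique(tor$truth$torsion_per_mm), 0)

  cyl <- make_tube_phantom(tube_spec("cylinder", radius_mm = 2), 0.284)
  expect_equal(unique(cyl$truth$curvature_per_mm), 0)
  expect_equal(unique(cyl$truth$circularity), 1)
  expect_equal(unique(cyl$truth$min_diameter_mm), 4)
  expect_equal(unique(cyl$truth$max_diameter_mm), 4)
  # ground truth sampled at <= spacing intervals along the centerline
  expect_lte(max(diff(cyl$truth$arclength_mm)), 0.284 + 1e-9)
})

test_that("bifurcation daughters share exactly one junction point with the parent", {
  ph <- make_tube_phantom(
    tube_spec("bifurcation", radius_mm = c(2, 1.5, 1.5), length_mm = 20,
              daughter_length_mm = 12), 0.284)
  tr <- ph$truth
  parent <- tr[tr$branch_id == 1, ]
  junction <- as.numeric(parent[nrow(parent), c("x", "y", "z")])
  for (d in 2:3) {
    daughter <- as.matrix(tr[tr$branch_id == d, c("x", "y", "z")])
    hits <- rowSums(abs(sweep(daughter, 2, junction, "-"))) < 1e-12
    expect_identical(sum(hits), 1L)
    expect_true(hits[1])
  }
})

test_that("phantom preconditions and contracts are enforced", {
  expect_error(tube_spec("torus_arc", radius_mm = 5, bend_radius_mm = 4),
               "self-intersection")
  expect_error(tube_spec("cylinder", foreground_intensity = 0,
                         background_intensity = 10), "foreground")
  expect_error(tube_spec("cylinder", radius_mm = -1), "positive")
  expect_warning(make_tube_phantom(tube_spec("cylinder", radius_mm = 0.3,
                                             length_mm = 5), 0.284),
                 "sub-resolution")
  # tube exceeding a fixed grid names the offending extent
  expect_error(make_tube_phantom(tube_spec("cylinder", radius_mm = 2,
                                           length_mm = 40), 0.284,
                                 shape = c(30, 30, 30)),
               "exits the volume")
})

test_that("Rician noise is seeded, identity at sigma 0, and matches its moments", {
  vol <- cv_volume(array(100, c(100, 100, 100)), 1)
  expect_identical(add_acquisition_noise(vol, 0)$data, vol$data)
  n1 <- add_acquisition_noise(vol, 5, seed = 9)
  n2 <- add_acquisition_noise(vol, 5, seed = 9)
  expect_identical(n1$data, n2$data)
  n3 <- add_acquisition_noise(vol, 5, seed = 10)
  expect_false(identical(n1$data, n3$data))
  expect_error(add_acquisition_noise(vol, -1), "nonnegative")

  # sample mean at 1e6 voxels vs numerically integrated Rician mean
  expect_lt(abs(mean(n1$data) / rician_mean(100, 5) - 1), 0.01)
})
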