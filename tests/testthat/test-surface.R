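test_that("cylinder surface is watertight with volume within 5% of pi r^2 L", {
  ch <- cylinder_chain()
  expect_true(is_watertight(ch$mesh))
  expect_lt(abs(mesh_volume(ch$mesh) / (pi * 4 * 40) - 1), 0.05)
  # enclosed volume also within 5% of the voxel-count volume
  expect_lt(abs(mesh_volume(ch$mesh) / mask_volume(ch$mask) - 1), 0.05)
})

test_that("small blocks give closed surfaces; sub-minimal masks are rejected", {
  arr <- array(FALSE, c(7, 7, 7))
  arr[3:5, 3:5, 3:5] <- TRUE
  mesh <- extract_surface(cv_mask(arr, 1), smoothing_iterations = 0,
                          presmooth_sigma_vox = 0)
  expect_true(is_watertight(mesh))
  # the 0.5-level surface of a 3-voxel block lies between the inter-centre
  # cube (2^3) and the full voxel support (3^3)
  expect_gt(mesh_volume(mesh), 8)
  expect_lt(mesh_volume(mesh), 27)

  # a single voxel has no fully interior voxel
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  expect_error(extract_surface(cv_mask(one, 1)), "interior")
  expect_error(extract_surface(cv_mask(array(FALSE, c(5, 5, 5)), 1)), "empty")
})

test_that("Taubin smoothing reduces area while preserving volume", {
  # voxelized sphere, radius 8 voxels
  co <- expand.grid(i = 1:21, j = 1:21, k = 1:21)
  arr <- array((co$i - 11)^2 + (co$j - 11)^2 + (co$k - 11)^2 <= 64, c(21, 21, 21))
  mask <- cv_mask(arr, 1)
  m0 <- extract_surface(mask, smoothing_iterations = 0, presmooth_sigma_vox = 0)
  m20 <- extract_surface(mask, smoothing_iterations = 20, presmooth_sigma_vox = 0)
  expect_lt(mesh_area(m20), mesh_area(m0))
  expect_lt(abs(mesh_volume(m20) / mesh_volume(m0) - 1), 0.02)
  expect_true(is_watertight(m20))
})

test_that("boundary-touching masks are padded or rejected", {
  arr <- array(FALSE, c(6, 6, 6))
  arr[1:4, 2:5, 2:5] <- TRUE # touches the i = 1 face
  mask <- cv_mask(arr, 1)
  expect_error(extract_surface(mask, pad = FALSE), "boundary")
  mesh <- extract_surface(mask, pad = TRUE)
  expect_true(is_watertight(mesh))
  expect_gt(mesh_volume(mesh), 0)
})
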