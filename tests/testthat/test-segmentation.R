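test_that("region growing recovers a noiseless phantom exactly and is idempotent", {
  ch <- cylinder_chain()
  ph <- ch$phantom
  mid <- ph$truth[which.min(abs(ph$truth$arclength_mm - 20)), ]
  seedvox <- cvmorph:::world_to_voxel(ph$volume,
                                      matrix(as.numeric(mid[c("x", "y", "z")]), 1))
  grown <- region_grow(ph$volume, seedvox, lower = 50, upper = 200)
  expect_identical(grown$data, ph$mask$data) # Dice 1 against the membership oracle

  # idempotence: re-grow from an arbitrary voxel of the result
  v2 <- which(grown$data, arr.ind = TRUE)[123, , drop = FALSE]
  expect_identical(region_grow(ph$volume, v2, lower = 50, upper = 200)$data,
                   grown$data)
})

test_that("uniform volumes grow to the whole grid; bad seeds are rejected", {
  vol <- cv_volume(array(100, c(8, 9, 10)), 1)
  expect_true(all(region_grow(vol, c(4, 4, 4), 50, 200)$data))
  expect_error(region_grow(vol, c(99, 1, 1), 50, 200), "outside the .* grid")

  vol$data[1, 1, 1] <- 0
  expect_error(region_grow(vol, c(1, 1, 1), 50, 200), "rejected")
})

test_that("largest component keeps the bigger blob with a lexicographic tie-break", {
  arr <- array(FALSE, c(30, 10, 10))
  arr[2:11, 2:6, 2:6] <- TRUE   # 250 voxels
  arr[20:23, 2:3, 2:3] <- TRUE  # 16 voxels
  mask <- cv_mask(arr, 1)
  lcc <- largest_connected_component(mask)
  expect_identical(sum(lcc$data), 250L)
  expect_false(any(lcc$data[20:23, , ]))
  # idempotent on a single component
  expect_identical(largest_connected_component(lcc)$data, lcc$data)

  # equal sizes: keep the component containing the smallest voxel index
  arr2 <- array(FALSE, c(10, 4, 4))
  arr2[1:2, 1:2, 1] <- TRUE
  arr2[8:9, 3:4, 3] <- TRUE
  tie <- largest_connected_component(cv_mask(arr2, 1))
  expect_true(tie$data[1, 1, 1])
  expect_false(any(tie$data[8:9, , ]))

  expect_error(largest_connected_component(cv_mask(array(FALSE, c(3, 3, 3)), 1)),
               "empty")
})

test_that("segmentation of a noisy phantom stays above Dice 0.95", {
  # radius 1.42 mm = 5 voxels; Rician sigma = 5% of the foreground intensity
  ph <- make_tube_phantom(tube_spec("cylinder", radius_mm = 1.42,
                                    length_mm = 20, noise_sigma = 5),
                          0.284, seed = 42)
  thr <- suggest_lower_threshold(ph$volume, c(1, 6, 1, 6, 1, 6))
  mid <- ph$truth[which.min(abs(ph$truth$arclength_mm - 10)), ]
  seedvox <- cvmorph:::world_to_voxel(ph$volume,
                                      matrix(as.numeric(mid[c("x", "y", "z")]), 1))
  m <- largest_connected_component(region_grow(ph$volume, seedvox, lower = thr))
  dice <- 2 * sum(m$data & ph$mask$data) / (sum(m$data) + sum(ph$mask$data))
  expect_gt(dice, 0.95)
})

test_that("background-box threshold follows the documented mean + 2 SD rule", {
  vol <- cv_volume(array(rnorm(8000, 10, 2), c(20, 20, 20)), 1)
  box <- c(1, 10, 1, 10, 1, 10)
  vals <- vol$data[1:10, 1:10, 1:10]
  expect_equal(suggest_lower_threshold(vol, box),
               mean(vals) + 2 * sd(as.numeric(vals)))
  expect_error(suggest_lower_threshold(vol, c(0, 5, 1, 5, 1, 5)), "out of range")
})
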