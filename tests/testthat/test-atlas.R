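test_that("the shipped atlas partitions 74 branches into 19 chunks", {
  atlas <- load_atlas()
  expect_identical(nrow(atlas$chunks), 19L)
  expect_identical(nrow(atlas$branches), 74L)
  expect_false(anyDuplicated(atlas$branches$branch_id) > 0)
  expect_false(anyDuplicated(atlas$branches$branch_name) > 0)
  expect_true(all(atlas$branches$chunk_id %in% atlas$chunks$chunk_id))
  expect_true(all(c("BA", "Lt basal ACA", "Rt pial MCA", "Lt cbll") %in%
                    atlas$chunks$chunk_name))
})

test_that("atlas validation reports structural violations", {
  ok <- data.frame(branch_id = 1:3, branch_name = c("a", "b", "c"),
                   chunk_id = c(1, 1, 2), chunk_name = c("X", "X", "Y"))
  expect_s3_class(load_atlas(write_mini_atlas(ok)), "cv_atlas")

  dup <- ok; dup$branch_id[2] <- 1
  expect_error(load_atlas(write_mini_atlas(dup)), "duplicate branch_id")
  twochunk <- ok; twochunk$chunk_name[2] <- "Z"
  expect_error(load_atlas(write_mini_atlas(twochunk)), "more than one")
  missingcol <- ok[, -2]
  expect_error(load_atlas(write_mini_atlas(missingcol)), "missing required")
  empty <- tempfile(fileext = ".csv"); file.create(empty)
  expect_error(load_atlas(empty))
  expect_error(load_atlas("/nonexistent/atlas.csv"), "not found")
})

test_that("seed labels propagate over the centerline tree", {
  ph <- make_tube_phantom(
    tube_spec("bifurcation", radius_mm = c(2, 1.5, 1.5), length_mm = 20,
              daughter_length_mm = 15, branch_angle_deg = 35), 0.284)
  tr <- ph$truth
  src <- as.numeric(tr[tr$branch_id == 1, ][1, c("x", "y", "z")]) + c(0, 0, 2)
  junction <- as.numeric(tr[tr$branch_id == 1, ][sum(tr$branch_id == 1),
                                                 c("x", "y", "z")])
  tips <- lapply(2:3, function(d) {
    td <- tr[tr$branch_id == d, ]
    tip <- as.numeric(td[nrow(td), c("x", "y", "z")])
    tip - 2 * (tip - junction) / sqrt(sum((tip - junction)^2))
  })
  cl <- resample_centerline(compute_centerline(
    ph$mask, list(rbind(src, tips[[1]]), rbind(src, tips[[2]]))))
  seeds <- data.frame(
    branch_id = c(10L, 20L, 30L),
    x = c(0, (junction[1] + tips[[1]][1]) / 2, (junction[1] + tips[[2]][1]) / 2),
    y = 0,
    z = c(10, (junction[3] + tips[[1]][3]) / 2, (junction[3] + tips[[2]][3]) / 2))
  cla <- assign_branches(cl, seeds)
  labs <- unlist(lapply(cla$branches, `[[`, "label"))
  expect_setequal(unique(labs), c(10L, 20L, 30L))
  expect_true(all(table(labs) > 10))

  # tree-propagation oracle: every point carries the geodesically nearest
  # seed label; on this geometry straight-line distance to the three seed
  # anchors agrees with the geodesic for points away from the junction
  pts <- do.call(rbind, lapply(cla$branches, `[[`, "points"))
  seedm <- as.matrix(seeds[, c("x", "y", "z")])
  d2 <- sapply(seq_len(3), function(s)
    rowSums(sweep(pts, 2, seedm[s, ], "-")^2))
  direct <- seeds$branch_id[apply(d2, 1, which.min)]
  # the straight-line oracle only applies where it is unambiguous: the
  # best seed must beat every other by > 2 mm (points near the junction or
  # the daughters' symmetry plane are governed by the geodesic instead)
  d <- sqrt(d2)
  margin <- apply(d, 1, function(r) sort(r)[2] - min(r))
  clear <- margin > 2
  expect_true(mean(labs[clear] == direct[clear]) > 0.97)

  # single branch, one seed: every point shares the label
  ch <- cylinder_chain()
  one <- assign_branches(ch$centerline,
                         data.frame(branch_id = 5L, x = 0, y = 0, z = 20))
  expect_true(all(unlist(lapply(one$branches, `[[`, "label")) == 5L))

  # far seed: error naming the seed
  expect_error(assign_branches(ch$centerline,
                               data.frame(branch_id = 9L, x = 50, y = 0, z = 20)),
               "9")
})

test_that("chunk means honour exclusions, missingness and permutation", {
  atlas <- load_atlas(write_mini_atlas(data.frame(
    branch_id = 1:3, branch_name = c("a", "b", "c"),
    chunk_id = c(1, 1, 2), chunk_name = c("X", "X", "Y"))))
  feats <- data.frame(
    branch_id = rep(1:3, each = 4),
    area_mm2 = c(rep(3, 4), rep(5, 4), rep(7, 4)),
    misr_mm = 1, min_diameter_mm = 2, max_diameter_mm = 3,
    min_max_ratio = 0.7, curvature_per_mm = 0.1, torsion_per_mm = 0,
    perimeter_mm = 6, circularity = 0.9, missing = FALSE)
  cm <- chunk_means(feats, atlas)
  expect_equal(cm$area_mm2[cm$chunk_id == 1], 4) # equal point counts: (3+5)/2
  expect_equal(cm$point_count, c(8L, 4L))

  # excluding one member branch leaves the other's mean
  cm2 <- chunk_means(feats, atlas, exclusions = 2L)
  expect_equal(cm2$area_mm2[cm2$chunk_id == 1], 3)
  # excluding all members keeps the chunk with missing mean and count 0
  cm3 <- chunk_means(feats, atlas, exclusions = c(1L, 2L))
  expect_true(is.na(cm3$area_mm2[cm3$chunk_id == 1]))
  expect_identical(cm3$point_count[cm3$chunk_id == 1], 0L)
  expect_error(chunk_means(feats, atlas, exclusions = 99L), "not in atlas")

  # permutation invariance and empty-exclusion identity
  perm <- feats[sample(nrow(feats)), ]
  expect_equal(chunk_means(perm, atlas), cm)
  expect_equal(chunk_means(feats, atlas, integer(0)), cm)

  # partition: chunk point counts plus exclusions cover every labelled row
  expect_identical(sum(cm2$point_count) + sum(feats$branch_id %in% 2L),
                   nrow(feats))
  # missing rows are data, not errors
  feats$missing[1:2] <- TRUE
  expect_identical(sum(chunk_means(feats, atlas)$point_count), nrow(feats) - 2L)
})
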