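test_that("lung segmentation recovers the phantom lungs and fills interior structures", {
  ph <- small_phantom()
  lung <- segment_lungs(ph$pre)
  expect_gt(dice(lung, ph$lung_pre), 0.98)
  # tumor and vessels are interior structures and must be inside the mask
  expect_gt(sum(ph$tumor$data & lung$data) / mask_volume(ph$tumor), 0.95)
  expect_gt(sum(ph$vessels_pre$data & lung$data) / mask_volume(ph$vessels_pre), 0.9)
})

test_that("lung segmentation fails loudly without a low-density interior", {
  flat <- image_volume(array(0, c(20, 20, 20)))
  expect_error(segment_lungs(flat), "below the lung threshold|segmentation failure")
})

test_that("tumor segmentation recovers the phantom sphere and rejects bad seeds", {
  # an 8 mm tumor well inside the lung with no adjacent vessel
  ph <- memo("tumor_phantom",
             generate_phantom(small_phantom_spec(tumor_center = c(49, 70, 41),
                                                 tumor_radius = 8,
                                                 resection_offset_mm = NA)))
  lung <- segment_lungs(ph$pre)
  seedvox <- round(world_to_voxel(ph$pre, matrix(ph$spec$tumor_center, 1)))[1, ]
  tm <- segment_tumor(ph$pre, lung, seedvox)
  analytic <- 4 / 3 * pi * ph$spec$tumor_radius^3
  expect_lt(abs(mask_volume(tm) - analytic) / analytic, 0.1)
  expect_gt(dice(tm, ph$tumor), 0.85)

  # a tumor abutting a vessel tube: the vessel stays out of the mask
  ph2 <- memo("tumor_vessel_phantom",
              generate_phantom(small_phantom_spec(tumor_center = c(60, 46, 80),
                                                  tumor_radius = 8,
                                                  resection_offset_mm = NA)))
  lung2 <- segment_lungs(ph2$pre)
  sv2 <- round(world_to_voxel(ph2$pre, matrix(ph2$spec$tumor_center, 1)))[1, ]
  tm2 <- segment_tumor(ph2$pre, lung2, sv2)
  expect_lt(sum(tm2$data & ph2$vessels_pre$data), 0.05 * mask_volume(ph2$vessels_pre))

  # seed in air is rejected (below the HU floor)
  air_seed <- c(3L, 3L, 3L)
  expect_error(segment_tumor(ph$pre, lung, air_seed), "outside the lung|HU")
  # seed inside the lung on aerated tissue is below the floor
  in_lung <- which(ph$lung_pre$data & !ph$tumor$data & !ph$vessels_pre$data,
                   arr.ind = TRUE)[1, ]
  expect_error(segment_tumor(ph$pre, lung, in_lung), "below the .* floor")
})

test_that("vesselness enhances tubes and suppresses blobs and flat regions", {
  dims <- c(48L, 48L, 48L)
  # constant volume: zero Hessian everywhere -> response identically 0
  flatv <- image_volume(array(100, dims))
  lungish <- binary_mask(array(TRUE, dims))
  expect_true(all(vesselness_filter(flatv, lungish)$data == 0))

  # bright tube on dark background
  tube <- array(-900, dims)
  for (z in 1:48) for (y in 1:48) for (x in 1:48)
    if ((y - 24)^2 + (x - 24)^2 <= 9) tube[z, y, x] <- 100
  tv <- image_volume(tube)
  resp <- vesselness_filter(tv, lungish)$data
  on_axis <- resp[10:38, 24, 24]
  off <- resp[10:38, 24, 36]   # 12 mm from the axis
  expect_gt(min(on_axis), max(off))

  # bright sphere: response at its centre is below the tube's on-axis response
  sph <- array(-900, dims)
  for (z in 1:48) for (y in 1:48) for (x in 1:48)
    if ((z - 24)^2 + (y - 24)^2 + (x - 24)^2 <= 100) sph[z, y, x] <- 100
  sresp <- vesselness_filter(image_volume(sph), lungish)$data
  expect_gt(max(on_axis), sresp[24, 24, 24])
})

test_that("vessel-tree segmentation respects the percentile budget and erosion mask", {
  ph <- full_phantom()
  lung <- segment_lungs(ph$pre)
  vess <- segment_vessel_tree(ph$pre, lung)
  # by construction at most ~5% (+1%) of lung voxels pass the 95th percentile
  expect_lte(mask_volume(vess) / mask_volume(lung), 0.06)
  # the output is always inside the 4 mm-eroded lung
  core <- erode_mm(lung, 4)
  expect_true(all(!vess$data | core$data))
  # it covers most ground-truth tube voxels that survive the erosion
  gt_in <- ph$vessels_pre$data & core$data
  expect_gt(sum(vess$data & gt_in) / sum(gt_in), 0.8)
})

test_that("subvascular tree extraction is strict, disjoint and deterministic", {
  # two disjoint solid tubes of ~1000 voxels -> 2 trees
  two <- binary_mask(array(FALSE, c(40, 30, 30)))
  two$data[3:38, 4:8, 4:8] <- TRUE       # 36*25 = 900... keep > 250
  two$data[3:38, 20:24, 20:24] <- TRUE
  trees <- extract_subvascular_trees(two)
  expect_length(trees, 2L)
  expect_true(all(vapply(trees, `[[`, numeric(1), "volume") > 250))

  # a 200-voxel blob is below the strict threshold
  blob <- binary_mask(array(FALSE, c(20, 20, 20)))
  blob$data[5:12, 5:9, 5:9] <- TRUE      # 8*5*5 = 200
  expect_equal(sum(blob$data), 200)
  expect_length(extract_subvascular_trees(blob), 0L)
  # ... and exactly 250 voxels is still excluded (strict >)
  blob250 <- binary_mask(array(FALSE, c(20, 20, 20)))
  blob250$data[5:14, 5:9, 5:9] <- TRUE   # 10*5*5 = 250
  expect_length(extract_subvascular_trees(blob250), 0L)
  blob251 <- blob250
  blob251$data[15, 5, 5] <- TRUE
  expect_length(extract_subvascular_trees(blob251), 1L)

  # the phantom's six ground-truth trees, with deterministic labels
  ph <- small_phantom()
  t1 <- extract_subvascular_trees(ph$vessels_pre)
  t2 <- extract_subvascular_trees(ph$vessels_pre)
  expect_length(t1, ph$spec$n_trees)
  expect_identical(lapply(t1, `[[`, "voxels"), lapply(t2, `[[`, "voxels"))
  vols <- vapply(t1, `[[`, numeric(1), "volume")
  expect_true(all(diff(vols) <= 0))      # labelled by decreasing volume
  # components are pairwise disjoint and contained in the vessel mask
  total <- sum(vols)
  expect_lte(total, mask_volume(ph$vessels_pre))
  # skeleton preserves the component count (one per tree) and is inside it
  for (tr in t1[1:2]) {
    skm <- array(FALSE, tr$dims)
    skm[tr$skeleton_idx] <- TRUE
    trm <- array(FALSE, tr$dims)
    trm[tr$voxels] <- TRUE
    expect_true(all(trm[tr$skeleton_idx]))
    lab <- cpp_label_wrap(skm)
    expect_equal(max(lab), 1L)
  }
})
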