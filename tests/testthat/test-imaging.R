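test_that("volume and mask constructors enforce geometric invariants", {
  expect_error(image_volume(array(0, c(4, 4)), c(1, 1, 1)), "3 dimensions")
  expect_error(image_volume(array(0, c(4, 4, 4)), c(1, -1, 1)), "positive")
  v <- image_volume(array(rnorm(64), c(4, 4, 4)), c(2, 1, 0.5), c(-3, 0, 7))
  expect_s3_class(v, "image_volume")
  # world coordinate convention: origin + (index - 1) * spacing
  w <- voxel_to_world(v, matrix(c(2, 3, 4), 1))
  expect_equal(w[1, ], c(-3 + 2, 0 + 2, 7 + 1.5))
  expect_equal(world_to_voxel(v, w)[1, ], c(2, 3, 4))
})

test_that("isotropic resampling matches the analytic linear-interpolation oracle", {
  # identity resample leaves data untouched
  v <- image_volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)), c(1, 1, 1))
  expect_equal(resample_isotropic(v, 1)$data, v$data)

  # constant volume stays constant at any target
  vc <- image_volume(array(42, c(6, 6, 6)), c(2, 2, 2))
  out <- resample_isotropic(vc, 1.3)
  expect_true(all(abs(out$data - 42) < 1e-12))

  # separable linear ramp along z, spacing 2 -> 1: values follow the ramp
  nz <- 10
  ramp <- image_volume(array(rep((0:(nz - 1)) * 2, 4 * 4), c(nz, 4, 4)), c(2, 1, 1))
  r1 <- resample_isotropic(ramp, 1)
  expect_equal(dim(r1$data)[1], 20L)
  interior <- 1:19   # last output voxel falls beyond the input extent
  expect_equal(r1$data[interior, 2, 2], (interior - 1) * 1, tolerance = 1e-12)

  # idempotence at the target spacing
  r2 <- resample_isotropic(r1, 1)
  expect_equal(r2$data, r1$data)

  expect_error(resample_isotropic(v, 0), "> 0")
  thin <- image_volume(array(0, c(1, 5, 5)), c(1, 1, 1))
  expect_error(resample_isotropic(thin, 0.5, mode = "linear"), ">= 2")
})

test_that("metric ball morphology counts lattice points exactly", {
  # single voxel dilated by 3 mm: brute-force count of x^2+y^2+z^2 <= 9
  g <- expand.grid(z = -4:4, y = -4:4, x = -4:4)
  expected <- sum(g$z^2 + g$y^2 + g$x^2 <= 9)
  expect_equal(expected, 123L)
  m <- binary_mask(array(FALSE, c(11, 11, 11)))
  m$data[6, 6, 6] <- TRUE
  d <- dilate_mm(m, 3)
  expect_equal(mask_volume(d), expected)
  idx <- which(d$data, arr.ind = TRUE)
  expect_true(all(rowSums((idx - 6)^2) <= 9))

  # radius 0 is the identity
  expect_equal(erode_mm(d, 0)$data, d$data)
  expect_equal(dilate_mm(d, 0)$data, d$data)

  # containment: erosion subset of input subset of dilation
  set.seed(11)
  rm_ <- random_mask(c(14, 14, 14), 0.3)
  expect_true(all(!erode_mm(rm_, 2)$data | rm_$data))
  expect_true(all(!rm_$data | dilate_mm(rm_, 2)$data))

  # closing recovers a large solid cube exactly
  cube <- box_mask(c(34, 34, 34), c(8, 8, 8), c(27, 27, 27))
  closed <- erode_mm(dilate_mm(cube, 4), 4)
  expect_equal(closed$data, cube$data)

  # duality on complements away from the grid edge
  comp <- binary_mask(!rm_$data, rm_$spacing)
  er <- erode_mm(rm_, 2)$data
  du <- !dilate_mm(comp, 2)$data
  core <- 4:11
  expect_equal(er[core, core, core], du[core, core, core])

  aniso <- binary_mask(array(TRUE, c(4, 4, 4)), c(2, 1, 1))
  expect_error(erode_mm(aniso, 1), "isotropic")
})

test_that("mask_surface returns exactly the six-connected boundary", {
  cube <- box_mask(c(5, 5, 5), c(2, 2, 2), c(4, 4, 4))
  s <- mask_surface(cube)
  expect_equal(nrow(s), 26L)            # all but the centre voxel
  expect_false(any(s[, 1] == 3 & s[, 2] == 3 & s[, 3] == 3))

  single <- binary_mask(array(FALSE, c(3, 3, 3)))
  single$data[2, 2, 2] <- TRUE
  expect_equal(unname(mask_surface(single)[1, ]), c(2L, 2L, 2L))

  # full grid: the edge counts as background, so the shell is the surface
  full <- binary_mask(array(TRUE, c(4, 4, 4)))
  sf <- mask_surface(full)
  expect_equal(nrow(sf), 4^3 - 2^3)

  # brute-force oracle on a random mask
  set.seed(21)
  rm_ <- random_mask(c(8, 8, 8), 0.4)
  s2 <- mask_surface(rm_)
  bf <- matrix(0L, 0, 3)
  for (z in 1:8) for (y in 1:8) for (x in 1:8) {
    if (!rm_$data[z, y, x]) next
    nb <- rbind(c(z + 1, y, x), c(z - 1, y, x), c(z, y + 1, x),
                c(z, y - 1, x), c(z, y, x + 1), c(z, y, x - 1))
    bg <- apply(nb, 1, function(q) any(q < 1 | q > 8) || !rm_$data[q[1], q[2], q[3]])
    if (any(bg)) bf <- rbind(bf, c(z, y, x))
  }
  expect_equal(nrow(s2), nrow(bf))
  expect_true(all(rm_$data[s2]))

  expect_error(mask_surface(binary_mask(array(FALSE, c(3, 3, 3)))), "empty")
})
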