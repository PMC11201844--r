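test_that("margin distance follows plain Euclidean geometry", {
  dims <- c(12L, 12L, 12L)
  lungish <- binary_mask(array(TRUE, dims))
  warped <- binary_mask(array(FALSE, dims))
  warped$data[1, 1, 1] <- TRUE
  tumor <- binary_mask(array(FALSE, dims))
  tumor$data[4, 5, 1] <- TRUE            # 3-4-5 triangle
  res <- measure_margin(warped, tumor, lungish)
  expect_equal(res$distance, 5)
  expect_equal(unname(res$point_on_resection), c(0, 0, 0))
  expect_equal(unname(res$point_on_tumor), c(3, 4, 0))

  # symmetry: swapping which surface hosts the search gives the same value
  res2 <- measure_margin(tumor, warped, lungish)
  expect_equal(res2$distance, res$distance)
})

test_that("margin for a sphere facing a plane matches the analytic value", {
  dims <- c(64L, 64L, 64L)
  lungish <- binary_mask(array(TRUE, dims))
  warped <- binary_mask(array(FALSE, dims))
  warped$data[1:21, , ] <- TRUE          # boundary plane at z index 21 (z = 20)
  tumor <- binary_mask(array(FALSE, dims))
  for (z in 1:64) for (y in 24:40) for (x in 24:40)
    if ((z - 41)^2 + (y - 33)^2 + (x - 33)^2 <= 64) tumor$data[z, y, x] <- TRUE
  res <- measure_margin(warped, tumor, lungish)
  expect_lt(abs(res$distance - 12), 1)   # (40 - 20) - 8
})

test_that("overlapping masks report a zero margin with the overlap flag", {
  dims <- c(20L, 20L, 20L)
  lungish <- binary_mask(array(TRUE, dims))
  warped <- binary_mask(array(FALSE, dims)); warped$data[5:15, 5:15, 5:15] <- TRUE
  tumor <- binary_mask(array(FALSE, dims)); tumor$data[10:12, 10:12, 10:12] <- TRUE
  res <- measure_margin(warped, tumor, lungish)
  expect_equal(res$distance, 0)
  expect_true(res$overlap)
})

test_that("sub-voxel margins carry the below-resolution sentinel", {
  dims <- c(16L, 16L, 16L)
  lungish <- binary_mask(array(TRUE, dims))
  warped <- binary_mask(array(FALSE, dims)); warped$data[4, 8, 8] <- TRUE
  tumor <- binary_mask(array(FALSE, dims)); tumor$data[5, 8, 8] <- TRUE
  # adjacent voxels: 1.0 mm is not below resolution
  expect_match(measure_margin(warped, tumor, lungish)$display, "^1.00 mm")
  # sub-voxel masks on a finer grid scaled back: emulate with 0.5 mm spacing
  f <- binary_mask(array(FALSE, dims), spacing = rep(0.5, 3))
  g <- binary_mask(array(FALSE, dims), spacing = rep(0.5, 3))
  f$data[4, 8, 8] <- TRUE; g$data[5, 8, 8] <- TRUE
  lung2 <- binary_mask(array(TRUE, dims), spacing = rep(0.5, 3))
  expect_match(measure_margin(g, f, lung2)$display, "0.50 mm")

  empty <- binary_mask(array(FALSE, dims))
  expect_error(measure_margin(warped, empty, lungish), "empty")
  outside <- binary_mask(array(FALSE, dims)); outside$data[1, 1, 1] <- TRUE
  small_lung <- binary_mask(array(FALSE, dims)); small_lung$data[8:12, 8:12, 8:12] <- TRUE
  expect_error(measure_margin(warped, outside, small_lung), "outside")
})

test_that("TRE handles exact fields, compensated offsets and exclusions", {
  dims <- c(20L, 20L, 20L)
  zero <- resectmargin:::displacement_field(array(0, dims), array(0, dims),
                                            array(0, dims), array(TRUE, dims),
                                            c(1, 1, 1), c(0, 0, 0))
  lm <- data.frame(label = c("a", "b"), pre_z = c(5, 9), pre_y = c(5, 12),
                   pre_x = c(5, 7), post_z = c(5, 9), post_y = c(5, 12),
                   post_x = c(5, 7))
  r <- compute_tre(lm, zero)
  expect_equal(r$mean, 0)
  expect_equal(r$max, 0)

  # constant (0,0,5) field exactly compensates a -5 x-offset of the posts
  const <- zero
  const$ux <- array(5, dims)
  lm2 <- lm
  lm2$post_x <- lm2$pre_x - 5
  r2 <- compute_tre(lm2, const)
  expect_lt(r2$max, 1e-9)

  # landmark outside the validity mask is excluded with a warning
  holed <- zero
  holed$valid[1:3, , ] <- FALSE
  lm3 <- rbind(lm, data.frame(label = "out", pre_z = 2, pre_y = 2, pre_x = 2,
                              post_z = 2, post_y = 2, post_x = 2))
  expect_warning(r3 <- compute_tre(lm3, holed), "excluded")
  expect_equal(r3$n_excluded, 1L)
  expect_equal(r3$n, 2L)
  # summary statistics agree with the per-landmark list
  expect_equal(r3$mean, mean(r3$per_landmark$error))
})

test_that("MIP slabs equal the brute-force per-pixel maximum", {
  set.seed(41)
  v <- image_volume(array(rnorm(9 * 8 * 7), c(9, 8, 7)))
  m <- mip_slab(v, "z", 5L, 5L)
  bf <- apply(v$data[3:7, , ], c(2, 3), max)
  expect_equal(m, bf)

  vc <- image_volume(array(3.5, c(9, 8, 7)))
  expect_true(all(mip_slab(vc, "y", 4L) == 3.5))

  vb <- image_volume(array(0, c(9, 8, 7)))
  vb$data[4, 3, 2] <- 99
  expect_equal(mip_slab(vb, "z", 5L)[3, 2], 99)

  expect_error(mip_slab(v, "z", 2L), "outside")
  expect_error(mip_slab(v, "x", 6L), "outside")
})

test_that("paired t test matches the closed-form statistic and edge cases", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(2.1, 2.9, 4.2, 4.8, 6.0)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))   # closed-form paired t
  r <- paired_t_test(a, b)
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$df, 4L)
  expect_equal(r$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  expect_equal(r$stars, "***")

  same <- paired_t_test(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(paired_t_test(a, a + 2), "zero-variance|degenerate")
  expect_error(paired_t_test(a, b[1:3]), "equal-length")
})
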