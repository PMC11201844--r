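test_that("phantom generation is deterministic and self-consistent", {
  s <- small_phantom_spec()
  a <- generate_phantom(s)
  b <- generate_phantom(s)
  expect_identical(a$pre$data, b$pre$data)
  expect_identical(a$post$data, b$post$data)
  expect_identical(a$bifurcations, b$bifurcations)
  phantom_validate(a)
  # different seeds give different volumes
  c_ <- generate_phantom(small_phantom_spec(seed = 8L))
  expect_false(identical(a$pre$data, c_$pre$data))
})

test_that("phantom satisfies downstream preconditions", {
  ph <- small_phantom()
  expect_true(phantom_validate(ph))
  lab <- cpp_label_wrap(ph$vessels_pre$data)
  counts <- tabulate(lab[lab > 0])
  expect_length(counts, ph$spec$n_trees)
  expect_true(all(counts > 250))
  # tumor strictly inside the lung, inside the resected wedge
  expect_false(any(ph$tumor$data & !ph$lung_pre$data))
  expect_false(any(ph$tumor$data & !ph$resection_region$data))
  # post = warp(resect(pre)): the resected wedge is absent from the post lung
  expect_lt(sum(ph$lung_post$data & ph$resection_region$data) /
              mask_volume(ph$resection_region), 0.12)
})

test_that("a null-deformation phantom leaves pre and post equal up to noise", {
  ph0 <- generate_phantom(small_phantom_spec(warp_amplitude_mm = 0,
                                             collapse_amplitude_mm = 0,
                                             resection_offset_mm = NA))
  d <- ph0$post$data - ph0$pre$data
  # two independent noise draws: zero mean, sd ~ sqrt(2) * noise_sd
  expect_lt(abs(mean(d)), 0.5)
  expect_lt(abs(sd(d) - sqrt(2) * ph0$spec$noise_sd), 1)
  expect_equal(ph0$lung_pre$data, ph0$lung_post$data)
})

test_that("the true field reproduces the phantom's landmark mapping", {
  ph <- small_phantom()
  lm <- bifurcation_landmarks(ph, 12)
  tre <- compute_tre(lm, ph$true_field)
  expect_lt(tre$mean, 0.01)      # exact up to trilinear sampling of the grid

  # n = 0 gives an empty frame; oversampling errors out
  expect_equal(nrow(bifurcation_landmarks(ph, 0)), 0L)
  expect_error(bifurcation_landmarks(ph, 10000), "available")

  # 20 landmarks cover at least 3 distinct trees
  lm20 <- bifurcation_landmarks(ph, 20)
  trees_used <- unique(sub("_b.*", "", lm20$label))
  expect_gte(length(trees_used), 3L)
  # landmarks stay clear of the resected wedge
  expect_true(all(!ph$resection_region$data[round(cbind(lm20$pre_z, lm20$pre_y,
                                                        lm20$pre_x)) + 1]))
})

test_that("the ground-truth margin matches the analytic construction", {
  ph <- small_phantom()
  # warping the true post lung back with the true field recovers the
  # pre-operative lung minus the wedge; the margin then equals the offset
  warped <- warp_with_field(ph$lung_post, ph$true_field)
  m <- measure_margin(warped, ph$tumor, ph$lung_pre)
  expect_lt(abs(m$distance - ph$true_margin_mm), 2)
  # round trip recovers the remaining lung region
  remaining <- binary_mask(ph$lung_pre$data & !ph$resection_region$data)
  expect_gt(dice(warped, remaining), 0.95)
})

test_that("stronger collapse displaces landmarks monotonically", {
  dims <- c(120L, 120L, 120L)
  zero_field <- resectmargin:::displacement_field(
    array(0, dims), array(0, dims), array(0, dims), array(TRUE, dims),
    c(1, 1, 1), c(0, 0, 0))
  tre_at <- function(amp) {
    ph <- generate_phantom(small_phantom_spec(collapse_amplitude_mm = amp))
    # use every bifurcation so the collapse zone is represented
    lm <- bifurcation_landmarks(ph, min(40, nrow(ph$bifurcations)))
    compute_tre(lm, zero_field)$mean
  }
  t0 <- tre_at(0); t1 <- tre_at(4); t2 <- tre_at(8)
  expect_lt(t0, t1)
  expect_lt(t1, t2)
})

test_that("cutting through the tumor produces the negative-margin overlap", {
  ph <- generate_phantom(small_phantom_spec(cut_through_tumor = TRUE))
  # part of the tumor survives in the post lung; warping back with the true
  # field makes the warped lung overlap the tumor
  warped <- warp_with_field(ph$lung_post, ph$true_field)
  m <- measure_margin(warped, ph$tumor, ph$lung_pre)
  expect_true(m$overlap)
  expect_equal(m$distance, 0)
})

test_that("phantom specs that violate geometry are rejected", {
  expect_error(generate_phantom(small_phantom_spec(tumor_center = c(60, 5, 110))),
               "inside the lung")
  expect_error(generate_phantom(small_phantom_spec(resection_offset_mm = 60)),
               "misses the lung")
  expect_error(generate_phantom(small_phantom_spec(wedge_halfwidth_mm = 10)),
               "wedge too narrow")
})
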