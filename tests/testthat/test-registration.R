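test_that("candidate radius follows the closed form and is monotone", {
  expect_equal(candidate_radius(100, 100, 3), 200)       # d = dmax -> 2 dmax
  expect_equal(candidate_radius(0, 100, 3), 200 * exp(-3))
  expect_equal(candidate_radius(0, 100, 3), 9.957414, tolerance = 1e-6)
  set.seed(61)
  d <- sort(runif(100, 0, 150))
  r <- candidate_radius(d, dmax = 120)
  expect_true(all(diff(r) > 0))
  expect_true(all(r[d <= 120] <= 2 * 120 + 1e-9))
  expect_error(candidate_radius(10, -5), "dmax")
  expect_error(candidate_radius(-1, 10), ">= 0")
})

test_that("control-point selection picks the displacement regime nearest the voxel", {
  # all candidates share one displacement: a single cluster, all returned
  set.seed(62)
  post <- matrix(runif(60, 0, 30), 20, 3)
  fps1 <- fps_fixture(post, post + matrix(rep(c(1, 0, 2), each = 20), 20, 3))
  # query far from the tumor: the candidate radius covers the whole cloud
  sel <- select_control_points(c(15, 15, 15), c(55, 55, 55), 50, fps1)
  expect_setequal(sel, seq_len(20))

  # two displacement groups separated beyond eps: only the near one returned
  postA <- cbind(runif(15, 0, 10), runif(15, 0, 10), runif(15, 0, 10))
  postB <- cbind(runif(15, 20, 30), runif(15, 20, 30), runif(15, 20, 30))
  dispA <- matrix(rep(c(0, 0, 0), each = 15), 15, 3)
  dispB <- matrix(rep(c(0, 0, 8), each = 15), 15, 3)
  fps2 <- fps_fixture(rbind(postA, postB), rbind(postA + dispA, postB + dispB))
  selA <- select_control_points(c(5, 5, 5), c(15, 15, 15), 40, fps2)
  expect_true(all(selA <= 15))
  selB <- select_control_points(c(25, 25, 25), c(15, 15, 15), 40, fps2)
  expect_true(all(selB > 15))

  # fewer candidates than min_pts: the k-nearest fallback kicks in
  few <- fps_fixture(matrix(c(1, 1, 1, 2, 2, 2, 3, 3, 3, 30, 30, 30,
                              31, 31, 31, 32, 32, 32), 6, 3, byrow = TRUE),
                     matrix(0, 6, 3))
  few$pre_points <- few$post_points
  # query next to the tumor: radius ~6.6 mm captures only 3 < min_pts pairs
  self_sel <- select_control_points(c(1, 1, 1), c(2, 2, 2), 60, few,
                                    field_params(k_fallback = 4))
  expect_length(self_sel, 4L)
  expect_true(all(1:3 %in% self_sel))
  expect_error(select_control_points(c(0, 0, 0), c(1, 1, 1), 10,
                                     fps_fixture(matrix(0, 0, 3), matrix(0, 0, 3))),
               "empty")
})

test_that("TPS interpolates exactly and reproduces affine maps", {
  set.seed(63)
  src <- matrix(runif(30, 0, 80), 10, 3)
  fit <- tps_fit(src, src)
  q <- matrix(runif(300, 0, 80), 100, 3)
  expect_lt(max(abs(tps_predict(fit, q) - q)), 1e-6)

  A <- matrix(c(1.05, 0.02, -0.01, 0.03, 0.97, 0.02, -0.02, 0.01, 1.02), 3, 3)
  tt <- c(4, -2, 1)
  dst <- sweep(src %*% t(A), 2, tt, "+")
  fit2 <- tps_fit(src, dst)
  truth <- sweep(q %*% t(A), 2, tt, "+")
  expect_lt(max(abs(tps_predict(fit2, q) - truth)), 1e-4)

  # the defining interpolation property at every control point
  dst3 <- src + matrix(rnorm(30, 0, 3), 10, 3)
  fit3 <- tps_fit(src, dst3)
  expect_lt(max(abs(tps_predict(fit3, src) - dst3)), 1e-6)

  expect_error(tps_fit(src[1:3, ], src[1:3, ]), "at least 4")
  expect_error(tps_fit(src, src[1:5, ]), "differ")
  plane <- cbind(src[, 1:2], 0)
  expect_warning(tps_fit(plane, plane), "coplanar|degenerate")
})


test_that("a constant displacement is reproduced everywhere", {
  dims <- c(60L, 60L, 60L)
  lungish <- box_mask(dims, c(11, 11, 11), c(50, 50, 50))
  tumor <- binary_mask(array(FALSE, dims)); tumor$data[28:32, 28:32, 28:32] <- TRUE
  set.seed(65)
  post <- cbind(runif(150, 12, 48), runif(150, 12, 48), runif(150, 12, 48))
  fps <- fps_fixture(post, sweep(post, 2, c(0, 0, 5), "+"))
  field <- build_displacement_field(fps, tumor, lungish)
  expect_lt(max(abs(field$ux[field$valid] - 5)), 0.1)
  expect_lt(max(abs(field$uz[field$valid])), 0.1)
  expect_lt(max(abs(field$uy[field$valid])), 0.1)
})

test_that("selective control points create a jump that the all-points TPS cannot", {
  fx <- two_regime_fixture()
  sel <- build_displacement_field(fx$fps, fx$tumor, fx$lung)
  base <- build_displacement_field(fx$fps, fx$tumor, fx$lung,
                                   method = "all_points")
  # each side matches its regime within 1 mm (sampled away from the plane)
  sideA <- cbind(seq(20, 60, by = 5), seq(20, 60, by = 5), 20)
  sideB <- cbind(seq(20, 60, by = 5), seq(20, 60, by = 5), 60)
  uA <- sample_field(sel, sideA); uB <- sample_field(sel, sideB)
  expect_lt(max(abs(uA[, 3] - 0)), 1)
  expect_lt(max(abs(uB[, 3] - fx$jumpsize)), 1)

  # jump across the plane: adjacent nodes straddling x = 39 differ by more
  # than half the regime difference for the selective field only
  probe_lo <- cbind(rep(seq(24, 56, by = 8), each = 5), seq(24, 56, by = 8), 35)
  probe_hi <- probe_lo; probe_hi[, 3] <- 43
  jump_sel <- max(abs(sample_field(sel, probe_hi)[, 3] -
                        sample_field(sel, probe_lo)[, 3]))
  jump_base <- max(abs(sample_field(base, probe_hi)[, 3] -
                         sample_field(base, probe_lo)[, 3]))
  expect_gt(jump_sel, fx$jumpsize / 2)
  expect_lt(jump_base, fx$jumpsize / 2)
})

test_that("with one displacement regime the selective field matches the baseline", {
  dims <- c(60L, 60L, 60L)
  lungish <- box_mask(dims, c(11, 11, 11), c(50, 50, 50))
  tumor <- binary_mask(array(FALSE, dims)); tumor$data[28:32, 28:32, 28:32] <- TRUE
  set.seed(66)
  post <- cbind(runif(250, 12, 48), runif(250, 12, 48), runif(250, 12, 48))
  # one smooth regime
  pre <- post + cbind(2 * sin(post[, 3] / 15), 2 * cos(post[, 1] / 18),
                      2 * sin(post[, 2] / 20))
  fps <- fps_fixture(post, pre)
  sel <- build_displacement_field(fps, tumor, lungish)
  base <- build_displacement_field(fps, tumor, lungish, method = "all_points")
  set.seed(67)
  nodes <- cbind(runif(1000, 14, 46), runif(1000, 14, 46), runif(1000, 14, 46))
  us <- sample_field(sel, nodes); ub <- sample_field(base, nodes)
  expect_lt(stats::quantile(sqrt(rowSums((us - ub)^2)), 0.95), 0.5)
})

test_that("warping with a field moves content as the displacement dictates", {
  dims <- c(30L, 30L, 30L)
  m <- binary_mask(array(FALSE, dims)); m$data[10:20, 10:20, 10:20] <- TRUE
  zero <- resectmargin:::displacement_field(array(0, dims), array(0, dims),
                                            array(0, dims), array(TRUE, dims),
                                            c(1, 1, 1), c(0, 0, 0))
  expect_equal(warp_with_field(m, zero)$data, m$data)

  shift5 <- zero; shift5$uz <- array(5, dims)
  w <- warp_with_field(m, shift5)
  expect_equal(w$data[15:25, 10:20, 10:20], m$data[10:20, 10:20, 10:20])
  expect_equal(mask_volume(w), mask_volume(m))

  v <- image_volume(array(rnorm(prod(dims)), dims))
  expect_equal(warp_with_field(v, zero)$data, v$data)
})

test_that("field construction is deterministic and respects interpolation", {
  fx <- two_regime_fixture()
  f1 <- build_displacement_field(fx$fps, fx$tumor, fx$lung)
  f2 <- build_displacement_field(fx$fps, fx$tumor, fx$lung)
  expect_identical(f1$ux, f2$ux)
  expect_identical(f1$uz, f2$uz)

  # node-level interpolation property: a node whose subset contains a pair
  # reproduces that pair's displacement when evaluated at the pair itself
  fps <- fx$fps
  dmax <- max(sqrt(rowSums(sweep(voxel_to_world(fx$lung, mask_surface(fx$lung)),
                                 2, mask_centroid(fx$tumor))^2)))
  idx <- select_control_points(fps$post_points[3, ], mask_centroid(fx$tumor),
                               dmax, fps)
  expect_true(3 %in% idx)
  fit <- tps_fit(fps$post_points[idx, ], fps$pre_points[idx, ])
  mapped <- tps_predict(fit, fps$post_points[3, , drop = FALSE])
  expect_lt(max(abs(mapped - fps$pre_points[3, , drop = FALSE])), 1e-6)
})
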