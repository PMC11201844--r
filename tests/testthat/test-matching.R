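test_that("skeletonization preserves topology and reduces to centerlines", {
  # a 1-voxel-wide straight line is already thin: unchanged
  line <- binary_mask(array(FALSE, c(30, 7, 7)))
  line$data[3:28, 4, 4] <- TRUE
  sk <- skeletonize(line)
  expect_equal(sk$data, line$data)

  # solid tube radius 4, length 40: a connected curve spanning the ends
  tube <- tube_mask(c(44, 13, 13), c(7, 7), 4, c(3, 42))
  skt <- skeletonize(tube)
  expect_lte(mask_volume(skt), 60)
  expect_equal(max(cpp_label_wrap(skt$data)), 1L)       # stays connected
  idx <- which(skt$data, arr.ind = TRUE)
  expect_lte(min(idx[, 1]), 6)                          # reaches both ends
  expect_gte(max(idx[, 1]), 39)
  expect_true(all(tube$data[idx]))                      # subset of the input

  # two disjoint blobs give two disjoint skeleton components
  blobs <- binary_mask(array(FALSE, c(24, 24, 24)))
  blobs$data[4:10, 4:10, 4:10] <- TRUE
  blobs$data[15:21, 15:21, 15:21] <- TRUE
  skb <- skeletonize(blobs)
  expect_equal(max(cpp_label_wrap(skb$data)), 2L)
})

test_that("Dice agrees with brute-force voxel counting", {
  a <- binary_mask(array(FALSE, c(10, 10, 10))); a$data[1:4, , ] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- binary_mask(array(FALSE, c(10, 10, 10))); b$data[6:9, , ] <- TRUE
  expect_equal(dice(a, b), 0)

  # |a| = 100, |b| = 100, |intersection| = 50 -> 0.5
  a2 <- binary_mask(array(FALSE, c(10, 10, 10))); a2$data[1, 1:10, 1:10] <- TRUE
  b2 <- binary_mask(array(FALSE, c(10, 10, 10)))
  b2$data[1, 1:5, 1:10] <- TRUE; b2$data[2, 1:5, 1:10] <- TRUE
  expect_equal(sum(a2$data), 100); expect_equal(sum(b2$data), 100)
  expect_equal(dice(a2, b2), 0.5)

  # random masks against the brute-force formula
  set.seed(51)
  for (i in 1:20) {
    x <- random_mask(c(20, 20, 20), runif(1, 0.1, 0.5))
    y <- random_mask(c(20, 20, 20), runif(1, 0.1, 0.5))
    bf <- 2 * sum(x$data & y$data) / (sum(x$data) + sum(y$data))
    expect_equal(dice(x, y), bf)
  }

  empty <- binary_mask(array(FALSE, c(10, 10, 10)))
  expect_equal(dice(empty, empty), 0)
  other <- binary_mask(array(FALSE, c(9, 10, 10)))
  expect_error(dice(a, other), "same grid")
})

test_that("penalized Dice divides by the squared volume ratio", {
  # |a| = 400, |b| = 100 with 80 shared: dice = 0.32, DSCP = 0.32 / 16
  a <- binary_mask(array(FALSE, c(12, 12, 12)))
  a$data[1:4, 1:10, 1:10] <- TRUE                        # 400
  b <- binary_mask(array(FALSE, c(12, 12, 12)))
  b$data[4, 1:10, 1:8] <- TRUE                           # 80 shared with a
  b$data[6, 1:10, 1:2] <- TRUE                           # 20 disjoint
  expect_equal(sum(a$data), 400); expect_equal(sum(b$data), 100)
  expect_equal(dice(a, b), 0.32)
  expect_equal(dice_penalized(a, b), 0.02)

  # equal volumes: DSCP equals DSC; and DSCP <= DSC always
  set.seed(52)
  for (i in 1:20) {
    x <- random_mask(c(15, 15, 15), runif(1, 0.2, 0.5))
    y <- random_mask(c(15, 15, 15), runif(1, 0.2, 0.5))
    expect_lte(dice_penalized(x, y), dice(x, y) + 1e-12)
  }
  expect_equal(dice_penalized(a, a), dice(a, a))
  empty <- binary_mask(array(FALSE, c(12, 12, 12)))
  expect_error(dice_penalized(a, empty), "non-empty")
})

test_that("Phase I self-matching is perfect and one-to-one", {
  ph <- intact_phantom()
  trees <- extract_subvascular_trees(ph$vessels_pre)
  res <- phase1_match(trees, trees, ph$vessels_pre, ph$vessels_pre)
  expect_equal(nrow(res$pairs), length(trees))
  expect_true(all(res$pairs$phase == "I"))
  expect_true(all(res$pairs$dsc_target == 1))
  expect_true(all(res$pairs$dsc_surround >= 0.2))
  expect_equal(res$pairs$post_id, res$pairs$pre_id)
  # one-to-one: no id repeated
  expect_false(any(duplicated(res$pairs$post_id)))
  expect_false(any(duplicated(res$pairs$pre_id)))
  expect_length(res$unmatched_post, 0L)
})

test_that("Phase I accepted pairs always satisfy both thresholds", {
  ph <- small_phantom()
  pre_trees <- extract_subvascular_trees(ph$vessels_pre)
  post_trees <- extract_subvascular_trees(ph$vessels_post)
  res <- phase1_match(pre_trees, post_trees, ph$vessels_pre, ph$vessels_post)
  if (nrow(res$pairs) > 0) {
    expect_true(all(res$pairs$dsc_target >= 0.5))
    expect_true(all(res$pairs$dsc_surround >= 0.2))
  }
  s <- summary(res)
  expect_equal(s$matched[1] + s$unmatched[1], s$total[1])
})

test_that("an orphan tree with no counterpart stays unmatched", {
  ph <- intact_phantom()
  trees_pre <- extract_subvascular_trees(ph$vessels_pre)
  # fabricate an extra post component with no pre counterpart
  vess_post <- binary_mask(ph$vessels_pre$data, ph$vessels_pre$spacing)
  er <- erode_mm(ph$lung_pre, 8)
  # place the orphan at the in-lung spot farthest from any real vessel
  D <- array(cpp_label_wrap(ph$vessels_pre$data) * 0, dim(er$data))
  D <- array(resectmargin:::cpp_edt(as.logical(ph$vessels_pre$data),
                                    dim(er$data), c(1, 1, 1)), dim(er$data))
  D[!er$data] <- 0
  spot <- which(D == max(D), arr.ind = TRUE)[1, ]
  expect_gt(max(D), 8)                  # room for a detached component
  vess_post$data[(spot[1]-5):(spot[1]+5), (spot[2]-2):(spot[2]+2),
                 (spot[3]-2):(spot[3]+2)] <- TRUE
  trees_post <- extract_subvascular_trees(vess_post)
  expect_length(trees_post, length(trees_pre) + 1L)
  res <- suppressWarnings(phase1_match(trees_pre, trees_post, ph$vessels_pre, vess_post))
  res <- suppressWarnings(phase2_match(res, trees_pre, trees_post, ph$vessels_pre))
  # the fabricated tree is whichever post id is not matched
  expect_length(res$unmatched_post, 1L)
  orphan <- trees_post[[res$unmatched_post]]
  expect_lt(abs(orphan$centroid[1] - (spot[1] - 1)), 3)
})

test_that("a global residual translation is absorbed by rigid CPD", {
  ph <- intact_phantom()
  trees_pre <- extract_subvascular_trees(ph$vessels_pre)
  shifted <- resectmargin:::shift_mask(ph$vessels_pre, c(2, 3, -3))
  trees_post <- extract_subvascular_trees(shifted)
  res <- phase1_match(trees_pre, trees_post, ph$vessels_pre, shifted)
  expect_gte(nrow(res$pairs) / length(trees_post), 0.8)
})

test_that("Phase II recovers a displaced tree and rejects orphans and bent trees", {
  ph <- intact_phantom()
  trees <- extract_subvascular_trees(ph$vessels_pre)
  # post set: all trees, with the last one's mask translated by 4 mm
  last <- trees[[length(trees)]]
  vess_post <- binary_mask(ph$vessels_pre$data, ph$vessels_pre$spacing)
  lm <- resectmargin:::tree_mask(last)
  vess_post$data[lm$data] <- FALSE
  moved <- resectmargin:::shift_mask(lm, c(0, 4, 0))
  vess_post$data[moved$data] <- TRUE
  trees_post <- extract_subvascular_trees(vess_post)
  res <- phase1_match(trees, trees_post, ph$vessels_pre, vess_post)
  # emulate the displaced tree having failed Phase I: strip its pair (if
  # any) so Phase II must recover it from the matched neighbours
  moved_id <- which.min(vapply(trees_post, function(t)
    sum((t$centroid - (last$centroid + c(0, 4, 0)))^2), numeric(1)))
  k <- which(res$pairs$post_id == moved_id)
  if (length(k)) {
    res$unmatched_post <- sort(c(res$unmatched_post, res$pairs$post_id[k]))
    res$unmatched_pre <- sort(c(res$unmatched_pre, res$pairs$pre_id[k]))
    res$pairs <- res$pairs[-k, , drop = FALSE]
  }
  expect_gte(nrow(res$pairs), 3L)
  res <- phase2_match(res, trees, trees_post, ph$vessels_pre)
  expect_length(res$unmatched_post, 0L)
  ph2_rows <- res$pairs[res$pairs$phase == "II", , drop = FALSE]
  expect_gte(nrow(ph2_rows), 1L)
  expect_true(all(ph2_rows$dscp >= 0.3))

  # severely bent tube versus a straight pre tube: below the 0.3 threshold
  dims <- c(80L, 60L, 60L)
  pre_v <- tube_mask(dims, c(20, 20), 2.2, c(15, 65))
  pre_v$data <- pre_v$data | tube_mask(dims, c(40, 40), 2.2, c(10, 70))$data |
    tube_mask(dims, c(20, 45), 2.2, c(10, 70))$data |
    tube_mask(dims, c(45, 20), 2.2, c(12, 68))$data
  # bent post tube: three segments with two 45-degree kinks
  bent <- binary_mask(array(FALSE, dims))
  for (z in 15:32) for (y in 16:24) for (x in 16:24)
    if ((y - 20)^2 + (x - 20)^2 <= 5) bent$data[z, y, x] <- TRUE
  for (k in 0:17) {
    zz <- 32 + k; yy <- 20 + k
    for (dy in -2:2) for (dx in -2:2)
      if (dy^2 + dx^2 <= 5) bent$data[zz, yy + dy, 20 + dx] <- TRUE
  }
  for (z in 50:65) for (dy in -2:2) for (dx in -2:2)
    if (dy^2 + dx^2 <= 5) bent$data[z, 38 + dy, 20 + dx] <- TRUE
  post_v <- binary_mask(pre_v$data, pre_v$spacing)
  post_v$data[tube_mask(dims, c(20, 20), 2.2, c(15, 65))$data] <- FALSE
  post_v$data[bent$data] <- TRUE
  tp <- extract_subvascular_trees(pre_v)
  tq <- extract_subvascular_trees(post_v)
  r2 <- suppressWarnings(phase1_match(tp, tq, pre_v, post_v))
  r2 <- suppressWarnings(phase2_match(r2, tp, tq, pre_v))
  # the bent tube must not claim the straight pre tube
  expect_gte(length(r2$unmatched_post), 1L)
})

test_that("feature points from identical tree sets coincide", {
  ph <- intact_phantom()
  trees <- extract_subvascular_trees(ph$vessels_pre)
  res <- phase1_match(trees, trees, ph$vessels_pre, ph$vessels_pre)
  fps <- build_feature_points(res, trees, trees)
  offs <- sqrt(rowSums((fps$pre_points - fps$post_points)^2))
  expect_lt(mean(offs), 0.5)
})

test_that("feature points recover a known smooth warp within tolerance", {
  ph <- small_phantom()
  trees_pre <- extract_subvascular_trees(ph$vessels_pre)
  trees_post <- extract_subvascular_trees(ph$vessels_post)
  res <- phase1_match(trees_pre, trees_post, ph$vessels_pre, ph$vessels_post)
  res <- phase2_match(res, trees_pre, trees_post, ph$vessels_pre)
  expect_gte(nrow(res$pairs), 3L)
  fps <- build_feature_points(res, trees_pre, trees_post)
  truth <- fps$post_points +
    resectmargin:::phantom_true_u(ph$spec, fps$post_points)
  err <- sqrt(rowSums((fps$pre_points - truth)^2))
  expect_lt(mean(err), 1.5)
})

test_that("the full-size phantom yields over a thousand feature pairs", {
  ph <- full_phantom()
  trees <- extract_subvascular_trees(ph$vessels_pre)
  expect_length(trees, 6L)
  expect_true(all(vapply(trees, `[[`, numeric(1), "volume") > 250))
  res <- phase1_match(trees, trees, ph$vessels_pre, ph$vessels_pre)
  fps <- build_feature_points(res, trees, trees)
  expect_gte(nrow(fps$post_points), 1000)
})

test_that("matching is deterministic run to run", {
  ph <- intact_phantom()
  trees <- extract_subvascular_trees(ph$vessels_pre)
  r1 <- phase1_match(trees, trees, ph$vessels_pre, ph$vessels_pre)
  r2 <- phase1_match(trees, trees, ph$vessels_pre, ph$vessels_pre)
  expect_identical(r1$pairs, r2$pairs)
})
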