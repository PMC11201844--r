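#' Specification of a synthetic paired CT phantom
#'
#' Defines the study conditions the generator emulates: a thorax-like body
#' (~40 HU) with air background, two ellipsoidal lungs (~-850 HU), six
#' branching vessel trees (~50 HU, radius tapering 3 -> 1.5 mm, three per
#' lung, each confined to its own axial slab so the 26-connected
#' decomposition is unambiguous), a spherical tumor (~0 HU), a planar
#' resection at a configurable offset from the tumor surface, a smooth
#' sinusoidal global warp plus a localized collapse pulling the remaining
#' lung toward the resection plane (confined to within `collapse_extent_mm`
#' of it), and white HU noise.
#'
#' @param seed RNG seed (all randomness in the generator derives from it).
#' @param dims Grid size (z, y, x) voxels.
#' @param spacing Isotropic voxel size (mm).
#' @param n_trees Total tree count (split over the two lungs).
#' @param tree_depth Branching depth (segments double per level).
#' @param segment_len Root segment length in mm (children shrink by 0.72).
#' @param tumor_center Tumor center (z, y, x) mm.
#' @param tumor_radius Tumor radius (mm).
#' @param resection_offset_mm Distance from the tumor surface to the cut
#'   face of the resected wedge (mm); the tumor leaves with the wedge, so
#'   this is the ground-truth margin. `NA` disables the resection.
#' @param wedge_halfwidth_mm Half-width of the resected wedge in y (mm);
#'   must exceed `tumor_radius + resection_offset_mm` is not required, but
#'   the wedge boundary nearest the tumor is always the cut face.
#' @param cut_through_tumor When TRUE the cut face passes through the tumor
#'   centre (negative-margin scenario for overlap tests).
#' @param warp_amplitude_mm Global sinusoidal warp amplitude (mm).
#' @param collapse_amplitude_mm Localized collapse amplitude (mm).
#' @param collapse_extent_mm Extent of the collapse around the plane (mm).
#' @param noise_sd HU noise standard deviation.
#' @param hu HU values of the tissue classes.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(seed = 42L, dims = c(160L, 160L, 160L), spacing = 1,
                         n_trees = 6L, tree_depth = 4L, segment_len = 28,
                         tumor_center = c(80, 52, 116), tumor_radius = 8,
                         resection_offset_mm = 10, wedge_halfwidth_mm = 20,
                         cut_through_tumor = FALSE,
                         warp_amplitude_mm = 3, collapse_amplitude_mm = 5,
                         collapse_extent_mm = 15, noise_sd = 5,
                         hu = list(air = -1000, body = 40, lung = -850,
                                   vessel = 50, tumor = 0, pleura_fill = 30)) {
  spec <- list(seed = as.integer(seed), dims = as.integer(dims), spacing = spacing,
               n_trees = as.integer(n_trees), tree_depth = as.integer(tree_depth),
               segment_len = segment_len,
               tumor_center = tumor_center, tumor_radius = tumor_radius,
               resection_offset_mm = resection_offset_mm,
               wedge_halfwidth_mm = wedge_halfwidth_mm,
               cut_through_tumor = isTRUE(cut_through_tumor),
               warp_amplitude_mm = warp_amplitude_mm,
               collapse_amplitude_mm = collapse_amplitude_mm,
               collapse_extent_mm = collapse_extent_mm,
               noise_sd = noise_sd, hu = hu,
               body_center = as.numeric(dims) / 2 * spacing,
               body_semi = c(0.47, 0.44, 0.46) * as.numeric(dims) * spacing,
               lung_semi = c(0.345, 0.24, 0.19) * as.numeric(dims) * spacing)
  spec$lung_centers <- list(
    left = spec$body_center + c(0, 0, -0.225 * dims[3] * spacing),
    right = spec$body_center + c(0, 0, 0.225 * dims[3] * spacing))
  class(spec) <- "phantom_spec"
  spec
}

ellipsoid_mask <- function(dims, spacing, center, semi) {
  z <- (seq_len(dims[1]) - 1) * spacing - center[1]
  y <- (seq_len(dims[2]) - 1) * spacing - center[2]
  x <- (seq_len(dims[3]) - 1) * spacing - center[3]
  oz <- (z / semi[1])^2
  oy <- (y / semi[2])^2
  ox <- (x / semi[3])^2
  outer(outer(oz, oy, "+"), ox, "+") < 1
}

# keep a point inside the scaled lung ellipsoid
clamp_to_lung <- function(p, center, semi, frac = 0.75) {
  u <- (p - center) / semi
  nu <- sqrt(sum(u^2))
  if (nu > frac) p <- center + u / nu * frac * semi
  p
}

# draw a capsule (cylinder with spherical caps) into a voxel index set
capsule_voxels <- function(dims, spacing, p0, p1, radius, zlim) {
  lo <- pmax(floor(pmin(p0, p1) / spacing - radius / spacing) + 1, 1)
  hi <- pmin(ceiling(pmax(p0, p1) / spacing + radius / spacing) + 1, dims)
  lo[1] <- max(lo[1], floor(zlim[1] / spacing) + 1)
  hi[1] <- min(hi[1], ceiling(zlim[2] / spacing) + 1)
  if (any(hi < lo)) return(NULL)
  g <- as.matrix(expand.grid(z = lo[1]:hi[1], y = lo[2]:hi[2], x = lo[3]:hi[3]))
  w <- (g - 1) * spacing
  v <- p1 - p0
  L2 <- sum(v^2)
  t <- pmin(pmax((sweep(w, 2, p0) %*% v) / max(L2, 1e-12), 0), 1)
  proj <- sweep(t %*% t(v), 2, p0, function(a, b) a + b)
  d2 <- rowSums((w - proj)^2)
  g[d2 <= radius^2, , drop = FALSE]
}

# branching tube tree: a lateral stem with alternating side branches, each
# ending in a twig bifurcation; jittered but structured so the tree fills
# its slab without folding back on itself. Returns voxels + bifurcations.
draw_tree <- function(dims, spacing, root, lateral, radius, lung_center,
                      lung_semi, zlim, n_stations = 6L) {
  vox <- list(); bifs <- list()
  seg <- function(p0, p1, r) {
    p1 <- clamp_to_lung(p1, lung_center, lung_semi)
    p1[1] <- min(max(p1[1], zlim[1] + 1.5), zlim[2] - 1.5)
    vox[[length(vox) + 1L]] <<- capsule_voxels(dims, spacing, p0, p1, r, zlim)
    p1
  }
  # main stem along the lateral (x) direction
  stem_dir <- c(stats::runif(1, -0.12, 0.12), stats::runif(1, -0.2, 0.2), lateral)
  stem_dir <- stem_dir / sqrt(sum(stem_dir^2))
  stem_len <- 1.5 * lung_semi[3]
  p_end <- seg(root, root + stem_dir * stem_len, radius)
  stem_vec <- p_end - root
  for (k in seq_len(n_stations)) {
    t_k <- (k - 0.6) / n_stations
    q0 <- root + stem_vec * t_k
    side <- if (k %% 2L == 0L) 1 else -1
    bifs[[length(bifs) + 1L]] <- q0
    bdir <- c(stats::runif(1, -0.3, 0.3), side * 1,
              lateral * stats::runif(1, 0.1, 0.45))
    bdir <- bdir / sqrt(sum(bdir^2))
    blen <- stats::runif(1, 0.45, 0.8) * lung_semi[2]
    q1 <- seg(q0, q0 + bdir * blen, radius * 0.65)
    bifs[[length(bifs) + 1L]] <- q1
    bvec <- (q1 - q0) / max(sqrt(sum((q1 - q0)^2)), 1e-9)
    for (s in c(-1, 1)) {
      tdir <- bvec + c(s * stats::runif(1, 0.5, 0.8), stats::runif(1, -0.2, 0.2),
                       lateral * stats::runif(1, 0, 0.3))
      seg(q1, q1 + tdir / sqrt(sum(tdir^2)) * stats::runif(1, 8, 13), radius * 0.55)
    }
  }
  list(voxels = unique(do.call(rbind, vox)), bifurcations = do.call(rbind, bifs))
}

# cut-face x position: the wedge containing the tumor is removed and its
# medial face sits `resection_offset_mm` from the tumor surface
phantom_cut_plane <- function(spec) {
  if (spec$cut_through_tumor) return(spec$tumor_center[3])
  spec$tumor_center[3] - spec$tumor_radius - spec$resection_offset_mm
}

# analytic ground-truth displacement (pipeline convention: post + u = pre);
# pts is n x 3 (z, y, x) mm
phantom_true_u <- function(spec, pts) {
  pts <- matrix(pts, ncol = 3)
  A <- spec$warp_amplitude_mm
  u <- cbind(A * sin(2 * pi * pts[, 3] / 210 + 0.4),
             A * sin(2 * pi * pts[, 1] / 190 + 1.1),
             A * sin(2 * pi * pts[, 2] / 230 + 2.0))
  if (!is.na(spec$resection_offset_mm) && spec$collapse_amplitude_mm > 0) {
    plane <- phantom_cut_plane(spec)
    g <- pmax(0, 1 - abs(pts[, 3] - plane) / spec$collapse_extent_mm)
    # restrict the collapse to the operated (right) lung side
    g[pts[, 3] < spec$lung_centers$right[3] - spec$lung_semi[3]] <- 0
    u[, 3] <- u[, 3] - spec$collapse_amplitude_mm * g
  }
  u
}

#' Generate a paired synthetic CT phantom with ground truth
#'
#' Builds the pre-operative volume, applies the planar resection (resected
#' lung voxels become pleura-adjacent body HU), warps the result with the
#' known deformation field to produce the post-operative volume, adds
#' independent HU noise to both, and records every ground truth the
#' pipeline stages need (masks, tree voxels, bifurcations, true field,
#' analytic margin). Fully reproducible from the seed.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_truth` list: `pre`, `post` ([image_volume()]s),
#'   `lung_pre`, `lung_post`, `vessels_pre`, `vessels_post`, `tumor`
#'   ([binary_mask()]s), `bifurcations` (per-tree pre-space points),
#'   `true_field` (`displacement_field`), `resection_region`,
#'   `true_margin_mm`, and the `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) stop("generate_phantom: spec must be a phantom_spec")
  dims <- spec$dims; sp <- spec$spacing
  # sample the tumor sphere surface and require it inside the lung ellipsoid
  th <- seq(0, pi, length.out = 13)
  phg <- seq(0, 2 * pi, length.out = 25)
  sph <- unique(cbind(as.numeric(outer(cos(th), rep(1, 25))),
                      as.numeric(outer(sin(th), cos(phg))),
                      as.numeric(outer(sin(th), sin(phg)))))
  surf <- sweep(sph * spec$tumor_radius, 2, spec$tumor_center, "+")
  inside_one <- function(center) {
    uu <- sweep(sweep(surf, 2, center, "-"), 2, spec$lung_semi, "/")
    all(rowSums(uu^2) < 1)
  }
  if (!inside_one(spec$lung_centers$right) && !inside_one(spec$lung_centers$left))
    stop("generate_phantom: tumor is not strictly inside the lung")
  if (!is.na(spec$resection_offset_mm)) {
    plane <- phantom_cut_plane(spec)
    lung_min_x <- spec$lung_centers$right[3] - spec$lung_semi[3]
    if (plane <= lung_min_x + 3)
      stop("generate_phantom: cut face misses the lung (offset too large)")
    if (!spec$cut_through_tumor &&
        spec$wedge_halfwidth_mm <= spec$tumor_radius + spec$resection_offset_mm)
      stop("generate_phantom: wedge too narrow; its side faces would define the margin")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  body <- ellipsoid_mask(dims, sp, spec$body_center, spec$body_semi)
  lungL <- ellipsoid_mask(dims, sp, spec$lung_centers$left, spec$lung_semi)
  lungR <- ellipsoid_mask(dims, sp, spec$lung_centers$right, spec$lung_semi)
  lung <- lungL | lungR

  # trees: one axial slab per tree within each lung, so components stay apart
  n_per <- spec$n_trees %/% 2L
  slab_step <- 1.8 * spec$lung_semi[1] / max(n_per, 1)
  slab_half <- min(12, slab_step / 2 - 4)
  if (slab_half < 4) stop("generate_phantom: grid too small to separate the trees")
  slab_centers <- spec$body_center[1] + (seq_len(n_per) - (n_per + 1) / 2) * slab_step
  trees <- list()
  for (side in c("left", "right")) {
    lc <- spec$lung_centers[[side]]
    lateral <- if (side == "left") -1 else 1
    for (k in seq_len(n_per)) {
      root <- c(slab_centers[k], lc[2], lc[3] - lateral * spec$lung_semi[3] * 0.72)
      tr <- draw_tree(dims, sp, root, lateral, radius = 3.0, lung_center = lc,
                      lung_semi = spec$lung_semi,
                      zlim = c(slab_centers[k] - slab_half, slab_centers[k] + slab_half),
                      n_stations = spec$tree_depth + 2L)
      trees[[length(trees) + 1L]] <- tr
    }
  }
  vessels <- array(FALSE, dims)
  for (tr in trees) vessels[tr$voxels] <- TRUE
  vessels <- vessels & lung
  # drop sub-threshold fragments sheared off by the lung boundary clip
  vlab <- array(cpp_label(as.logical(vessels), dims, 26L), dims)
  if (max(vlab) > 0) {
    vcounts <- tabulate(vlab[vlab > 0], nbins = max(vlab))
    vessels <- array(vlab %in% which(vcounts > 250), dims)
  }

  tumor <- array(FALSE, dims)
  tz <- (seq_len(dims[1]) - 1) * sp; ty <- (seq_len(dims[2]) - 1) * sp
  tx <- (seq_len(dims[3]) - 1) * sp
  td2 <- outer(outer((tz - spec$tumor_center[1])^2, (ty - spec$tumor_center[2])^2, "+"),
               (tx - spec$tumor_center[3])^2, "+")
  tumor <- td2 <= spec$tumor_radius^2

  pre_ideal <- array(spec$hu$air, dims)
  pre_ideal[body] <- spec$hu$body
  pre_ideal[lung] <- spec$hu$lung
  pre_ideal[vessels] <- spec$hu$vessel
  pre_ideal[tumor] <- spec$hu$tumor

  # resection: a lateral wedge containing the tumor
  resected <- array(FALSE, dims)
  if (!is.na(spec$resection_offset_mm)) {
    plane <- phantom_cut_plane(spec)
    xw <- (seq_len(dims[3]) - 1) * sp
    yw <- (seq_len(dims[2]) - 1) * sp
    cut_x <- array(rep(xw >= plane, each = dims[1] * dims[2]), dims)
    in_band <- abs(yw - spec$tumor_center[2]) <= spec$wedge_halfwidth_mm
    band <- aperm(array(rep(in_band, each = dims[1]), c(dims[1], dims[2], dims[3])),
                  c(1, 2, 3))
    resected <- lung & cut_x & band
  }
  pre_resected <- pre_ideal
  pre_resected[resected] <- spec$hu$pleura_fill

  # warp: post(x) = pre_resected(x + u_true(x))
  idx_grid <- as.matrix(expand.grid(z = seq_len(dims[1]), y = seq_len(dims[2]),
                                    x = seq_len(dims[3])))
  # evaluate u analytically on the full grid (vectorized, separable terms)
  w <- (idx_grid - 1) * sp
  U <- phantom_true_u(spec, w)
  uz <- array(U[, 1], dims); uy <- array(U[, 2], dims); ux <- array(U[, 3], dims)
  warp_once <- function(arr, nearest, bg) {
    array(cpp_warp_field(as.numeric(arr), dims, rep(sp, 3), rep(0, 3),
                         as.numeric(-uz), as.numeric(-uy), as.numeric(-ux),
                         rep(TRUE, prod(dims)), nearest, bg), dims)
  }
  post_ideal <- warp_once(pre_resected, FALSE, spec$hu$air)
  lung_post <- warp_once((lung & !resected) * 1.0, TRUE, 0) > 0.5
  vessels_post <- warp_once((vessels & !resected) * 1.0, TRUE, 0) > 0.5

  pre <- pre_ideal + array(stats::rnorm(prod(dims), 0, spec$noise_sd), dims)
  post <- post_ideal + array(stats::rnorm(prod(dims), 0, spec$noise_sd), dims)

  bifs <- lapply(seq_along(trees), function(i) {
    b <- trees[[i]]$bifurcations
    cbind(tree = i, b)
  })
  bifs <- do.call(rbind, bifs)
  colnames(bifs) <- c("tree", "z", "y", "x")

  tf <- displacement_field(uz, uy, ux, array(TRUE, dims), rep(sp, 3), rep(0, 3))
  structure(list(
    pre = image_volume(pre, rep(sp, 3)), post = image_volume(post, rep(sp, 3)),
    lung_pre = binary_mask(lung, rep(sp, 3)),
    lung_post = binary_mask(lung_post, rep(sp, 3)),
    vessels_pre = binary_mask(vessels, rep(sp, 3)),
    vessels_post = binary_mask(vessels_post, rep(sp, 3)),
    tumor = binary_mask(tumor, rep(sp, 3)),
    resection_region = binary_mask(resected, rep(sp, 3)),
    bifurcations = bifs,
    true_field = tf,
    true_margin_mm = if (is.na(spec$resection_offset_mm)) NA_real_ else spec$resection_offset_mm,
    spec = spec), class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %s grid, %d tree(s), tumor %d voxels, true margin %s\n",
              paste(x$spec$dims, collapse = "x"),
              x$spec$n_trees, mask_volume(x$tumor),
              if (is.na(x$true_margin_mm)) "none" else sprintf("%.1f mm", x$true_margin_mm)))
  invisible(x)
}

#' Ground-truth vessel-bifurcation landmark pairs
#'
#' Samples `n` recorded tree-branch points (pre-operative space) evenly
#' across the trees (round-robin) and maps each through the true field to
#' its exact post-operative position (fixed-point inversion of
#' `post + u(post) = pre`). Bifurcations inside the resected region are not
#' eligible.
#'
#' @param truth A `phantom_truth`.
#' @param n Number of landmark pairs.
#' @return data.frame with `label, pre_z, pre_y, pre_x, post_z, post_y,
#'   post_x` (mm).
#' @export
bifurcation_landmarks <- function(truth, n) {
  b <- as.data.frame(truth$bifurcations)
  if (!is.na(truth$spec$resection_offset_mm)) {
    plane <- phantom_cut_plane(truth$spec)
    in_wedge <- b$x >= plane - 2 &
      abs(b$y - truth$spec$tumor_center[2]) <= truth$spec$wedge_halfwidth_mm + 2
    b <- b[!in_wedge, , drop = FALSE]
  }
  if (n > nrow(b))
    stop(sprintf("bifurcation_landmarks: %d requested but only %d available", n, nrow(b)))
  if (n == 0L) return(data.frame(label = character(), pre_z = numeric(),
                                 pre_y = numeric(), pre_x = numeric(),
                                 post_z = numeric(), post_y = numeric(),
                                 post_x = numeric()))
  # round-robin across trees for even coverage
  b <- b[order(b$tree, b$z, b$y, b$x), ]
  picked <- integer(0)
  by_tree <- split(seq_len(nrow(b)), b$tree)
  ptr <- rep(1L, length(by_tree))
  while (length(picked) < n) {
    for (ti in seq_along(by_tree)) {
      if (length(picked) >= n) break
      if (ptr[ti] <= length(by_tree[[ti]])) {
        picked <- c(picked, by_tree[[ti]][ptr[ti]])
        ptr[ti] <- ptr[ti] + 1L
      }
    }
    if (all(ptr > lengths(by_tree))) break
  }
  sel <- b[picked[seq_len(n)], ]
  pre <- as.matrix(sel[, c("z", "y", "x")])
  post <- pre
  for (i in 1:12) post <- pre - phantom_true_u(truth$spec, post)
  data.frame(label = sprintf("tree%d_b%d", sel$tree, seq_len(n)),
             pre_z = pre[, 1], pre_y = pre[, 2], pre_x = pre[, 3],
             post_z = post[, 1], post_y = post[, 2], post_x = post[, 3])
}

#' Write landmark pairs to CSV
#' @param landmarks data.frame from [bifurcation_landmarks()].
#' @param path Output path.
#' @export
write_landmarks_csv <- function(landmarks, path) {
  utils::write.csv(landmarks, path, row.names = FALSE)
  invisible(path)
}

#' Validate that a phantom satisfies the pipeline's preconditions
#'
#' Checks tree sizes (> 250 voxels), tumor placement (inside the lung, away
#' from the resection), mask geometry, and the post = warp(resect(pre))
#' construction. Errors on violation; invisibly TRUE otherwise.
#'
#' @param truth A `phantom_truth`.
#' @export
phantom_validate <- function(truth) {
  lab <- cpp_label(as.logical(truth$vessels_pre$data), vol_dims(truth$vessels_pre), 26L)
  counts <- tabulate(lab[lab > 0])
  if (length(counts) != truth$spec$n_trees)
    stop(sprintf("phantom_validate: expected %d vessel components, found %d",
                 truth$spec$n_trees, length(counts)))
  if (any(counts <= 250))
    stop("phantom_validate: a tree has <= 250 voxels")
  if (any(truth$tumor$data & !truth$lung_pre$data))
    stop("phantom_validate: tumor extends outside the lung")
  if (!is.na(truth$spec$resection_offset_mm) && !truth$spec$cut_through_tumor &&
      any(truth$tumor$data & !truth$resection_region$data))
    stop("phantom_validate: tumor is not contained in the resected wedge")
  if (!same_grid(truth$pre, truth$post))
    stop("phantom_validate: pre/post grids differ")
  invisible(TRUE)
}
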