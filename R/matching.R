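#' Topology-preserving 3D skeletonization
#'
#' Iterative thinning that deletes only simple (topology-preserving) border
#' voxels, in six directional subiterations, until no change; curve
#' endpoints are kept. The skeleton is a subset of the input and has the
#' same number of 26-connected components.
#'
#' @param mask A non-empty [binary_mask()] on an isotropic grid.
#' @return A [binary_mask()] holding the centerline voxels.
#' @export
skeletonize <- function(mask) {
  if (mask_volume(mask) == 0L) stop("skeletonize: empty mask")
  stopifnot_isotropic(mask, "skeletonize")
  dims <- vol_dims(mask)
  sk <- cpp_skeletonize(as.logical(mask$data), dims)
  binary_mask(array(sk, dims), mask$spacing, mask$origin)
}

#' Centerline points of a mask in world coordinates (mm)
#' @param mask A [binary_mask()] (typically a skeleton).
#' @return n x 3 matrix of (z, y, x) mm positions.
#' @export
skeleton_points <- function(mask) {
  voxel_to_world(mask, which(mask$data, arr.ind = TRUE))
}

#' Dice similarity coefficient of two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; 0 when both masks are empty.
#'
#' @param a,b [binary_mask()]s on the same grid.
#' @return Similarity in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot_same_grid(a, b, "dice")
  va <- sum(a$data); vb <- sum(b$data)
  if (va + vb == 0) return(0)
  2 * sum(a$data & b$data) / (va + vb)
}

#' Penalized Dice similarity
#'
#' Dice divided by the squared volume ratio `r = V1 / V2` with `V1 >= V2`,
#' penalizing size-mismatched pairs (important to avoid spurious matches of
#' small subvascular trees). Equals plain Dice when volumes are equal and is
#' never larger than it.
#'
#' @param a,b Non-empty [binary_mask()]s on the same grid.
#' @export
dice_penalized <- function(a, b) {
  stopifnot_same_grid(a, b, "dice_penalized")
  va <- sum(a$data); vb <- sum(b$data)
  if (va == 0 || vb == 0) stop("dice_penalized: masks must be non-empty")
  r <- max(va, vb) / min(va, vb)
  dice(a, b) / r^2
}

# penalized Dice from a precomputed dice value and two voxel counts
dscp_from <- function(d, v1, v2) {
  r <- max(v1, v2) / min(v1, v2)
  d / r^2
}

empty_match_result <- function(n_post, n_pre) {
  structure(list(
    pairs = data.frame(post_id = integer(), pre_id = integer(),
                       phase = character(), dsc_target = numeric(),
                       dsc_surround = numeric(), dscp = numeric(),
                       r = numeric(), stringsAsFactors = FALSE),
    unmatched_post = seq_len(n_post),
    unmatched_pre = seq_len(n_pre),
    n_post = n_post, n_pre = n_pre,
    transforms = list(), offsets = list(),
    reasons = character(0)), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  n1 <- sum(x$pairs$phase == "I"); n2 <- sum(x$pairs$phase == "II")
  cat(sprintf("<match_result> %d post / %d pre trees; matched %d (Phase I: %d, Phase II: %d); unmatched post: %d\n",
              x$n_post, x$n_pre, nrow(x$pairs), n1, n2, length(x$unmatched_post)))
  invisible(x)
}

#' Summary table of a match result (mirrors the per-case report rows)
#' @param object A `match_result`.
#' @param ... Unused.
#' @export
summary.match_result <- function(object, ...) {
  data.frame(
    phase = c("I", "II"),
    total = c(object$n_post, object$n_post - sum(object$pairs$phase == "I")),
    matched = c(sum(object$pairs$phase == "I"), sum(object$pairs$phase == "II")),
    unmatched = c(object$n_post - sum(object$pairs$phase == "I"),
                  length(object$unmatched_post)))
}

crop_window <- function(dims, center_vox, size) {
  half <- size %/% 2
  lo <- pmax(center_vox - half, 1L)
  hi <- pmin(center_vox + (size - half - 1L), dims)
  list(lo = lo, hi = hi)
}

crop_dice <- function(a, b, center_vox, size) {
  w <- crop_window(dim(a), center_vox, size)
  ca <- a[w$lo[1]:w$hi[1], w$lo[2]:w$hi[2], w$lo[3]:w$hi[3]]
  cb <- b[w$lo[1]:w$hi[1], w$lo[2]:w$hi[2], w$lo[3]:w$hi[3]]
  va <- sum(ca); vb <- sum(cb)
  if (va + vb == 0) return(0)
  2 * sum(ca & cb) / (va + vb)
}

# Resample a logical array under a rigid CPD fit (post -> pre world map),
# output on the same grid.
transform_mask_rigid <- function(mask, fit) {
  # inverse map: y = (x - t) R / s
  Ri <- t(fit$rotation) / fit$scale
  tr <- -as.numeric(Ri %*% fit$translation)
  out <- cpp_resample_affine(as.numeric(mask$data * 1.0), vol_dims(mask),
                             mask$spacing, mask$origin,
                             as.numeric(t(Ri)), tr,
                             vol_dims(mask), mask$spacing, mask$origin,
                             TRUE, 0)
  binary_mask(array(out > 0.5, vol_dims(mask)), mask$spacing, mask$origin)
}

#' Phase I subvascular-tree matching (high-similarity matches)
#'
#' For each post-operative tree, rigid CPD aligns its skeleton to each
#' candidate pre-operative tree skeleton (candidates: pre centroid within
#' `gate_mm`); the rigid transform is applied to the post tree mask and the
#' Dice with the pre tree is the target similarity, while 60x60x60-voxel
#' crops of the two whole vessel masks centered on the pre tree centroid
#' give the surrounding-area similarity. A pair is accepted iff target
#' Dice >= 0.5 and surrounding Dice >= 0.2, greedily by descending target
#' Dice with one-to-one enforcement.
#'
#' @param pre_trees,post_trees Lists from [extract_subvascular_trees()], on
#'   the common (localized) grid.
#' @param pre_vessels,post_vessels Whole vessel [binary_mask()]s.
#' @param thr_target,thr_surround Acceptance thresholds.
#' @param crop_size Surrounding crop edge length in voxels (1 mm grid).
#' @param gate_mm Candidate gate on centroid distance.
#' @return A `match_result` with Phase-I pairs; unmatched trees are left
#'   for Phase II.
#' @export
phase1_match <- function(pre_trees, post_trees, pre_vessels, post_vessels,
                         thr_target = 0.5, thr_surround = 0.2,
                         crop_size = 60L, gate_mm = 30) {
  res <- empty_match_result(length(post_trees), length(pre_trees))
  if (length(post_trees) == 0L || length(pre_trees) == 0L) return(res)
  stopifnot_same_grid(pre_vessels, post_vessels, "phase1_match")
  cand_rows <- list()
  for (po in post_trees) {
    if (nrow(po$skeleton) < 4L) next       # degenerate blob: leave for Phase II
    for (pr in pre_trees) {
      if (nrow(pr$skeleton) < 4L) next
      if (sqrt(sum((po$centroid - pr$centroid)^2)) > gate_mm) next
      fit <- rigid_cpd(po$skeleton, pr$skeleton)
      tpost <- transform_mask_rigid(tree_mask(po), fit)
      d_t <- dice(tpost, tree_mask(pr))
      if (d_t < thr_target) next    # surround crop cannot rescue it
      tvess <- transform_mask_rigid(post_vessels, fit)
      cvox <- round(world_to_voxel(pre_vessels, matrix(pr$centroid, 1)))
      d_s <- crop_dice(pre_vessels$data, tvess$data, as.integer(cvox), crop_size)
      cand_rows[[length(cand_rows) + 1L]] <- list(
        post_id = po$id, pre_id = pr$id, dsc_target = d_t, dsc_surround = d_s,
        r = max(po$volume, pr$volume) / min(po$volume, pr$volume), fit = fit)
    }
  }
  if (length(cand_rows)) {
    ord <- order(-vapply(cand_rows, `[[`, numeric(1), "dsc_target"))
    used_post <- integer(0); used_pre <- integer(0)
    for (k in ord) {
      cr <- cand_rows[[k]]
      if (cr$post_id %in% used_post || cr$pre_id %in% used_pre) next
      if (cr$dsc_target >= thr_target && cr$dsc_surround >= thr_surround) {
        res$pairs <- rbind(res$pairs, data.frame(
          post_id = cr$post_id, pre_id = cr$pre_id, phase = "I",
          dsc_target = cr$dsc_target, dsc_surround = cr$dsc_surround,
          dscp = NA_real_, r = cr$r,
          stringsAsFactors = FALSE))
        res$transforms[[paste(cr$post_id, cr$pre_id, sep = "-")]] <- cr$fit
        used_post <- c(used_post, cr$post_id)
        used_pre <- c(used_pre, cr$pre_id)
      }
    }
    res$unmatched_post <- setdiff(res$unmatched_post, used_post)
    res$unmatched_pre <- setdiff(res$unmatched_pre, used_pre)
  }
  res
}

#' Phase II subvascular-tree matching (relative positioning)
#'
#' Each still-unmatched post-operative tree is placed at a searching center
#' derived from its three nearest matched post-operative centroids (the
#' mean of their pre/post centroid offsets), dilated by 3 mm, and compared
#' against the unmatched pre-operative trees its placed mask touches. The
#' similarity is the penalized Dice of the two 3 mm-dilated masks, with the
#' volume ratio taken from the undilated trees; the best candidate is
#' accepted iff DSCP >= 0.3, one-to-one enforced.
#'
#' @param res A `match_result` from [phase1_match()].
#' @param pre_trees,post_trees Tree lists on the common grid.
#' @param pre_vessels Pre-operative vessel [binary_mask()].
#' @param thr Acceptance threshold on penalized Dice.
#' @param dilation_mm Search-mask dilation radius.
#' @return The updated `match_result`.
#' @export
phase2_match <- function(res, pre_trees, post_trees, pre_vessels,
                         thr = 0.3, dilation_mm = 3) {
  if (length(res$unmatched_post) == 0L) return(res)
  matched <- res$pairs
  for (po_id in res$unmatched_post) {
    if (nrow(matched) < 3L) {
      res$reasons[as.character(po_id)] <- "fewer than 3 matched pairs available"
      next
    }
    po <- post_trees[[po_id]]
    post_cents <- t(vapply(matched$post_id, function(i) post_trees[[i]]$centroid, numeric(3)))
    pre_cents <- t(vapply(matched$pre_id, function(i) pre_trees[[i]]$centroid, numeric(3)))
    dists <- sqrt(rowSums(sweep(post_cents, 2, po$centroid)^2))
    near3 <- order(dists)[1:3]
    offset <- colMeans(pre_cents[near3, , drop = FALSE] - post_cents[near3, , drop = FALSE])

    placed <- shift_mask(tree_mask(po), offset)
    search <- dilate_mm(placed, dilation_mm)
    best <- NULL
    for (pr_id in res$unmatched_pre) {
      pr <- pre_trees[[pr_id]]
      prm <- tree_mask(pr)
      target_vox <- prm$data & search$data
      if (!any(target_vox)) next
      # the potential target is the portion of the pre tree inside the
      # search mask (a post tree is often a truncated remnant)
      target <- binary_mask(target_vox, prm$spacing, prm$origin)
      d <- dice(search, dilate_mm(target, dilation_mm))
      dscp <- dscp_from(d, mask_volume(placed), mask_volume(target))
      if (is.null(best) || dscp > best$dscp)
        best <- list(pre_id = pr_id, dscp = dscp, d = d,
                     r = max(mask_volume(placed), mask_volume(target)) /
                       min(mask_volume(placed), mask_volume(target)))
    }
    if (!is.null(best) && best$dscp >= thr) {
      res$pairs <- rbind(res$pairs, data.frame(
        post_id = po_id, pre_id = best$pre_id, phase = "II",
        dsc_target = best$d, dsc_surround = NA_real_, dscp = best$dscp,
        r = best$r, stringsAsFactors = FALSE))
      res$offsets[[paste(po_id, best$pre_id, sep = "-")]] <- offset
      res$unmatched_post <- setdiff(res$unmatched_post, po_id)
      res$unmatched_pre <- setdiff(res$unmatched_pre, best$pre_id)
      matched <- res$pairs
    } else {
      res$reasons[as.character(po_id)] <- "no pre-operative candidate reached the similarity threshold"
    }
  }
  res
}

# Translate a mask by a world offset (mm), nearest-neighbour on its grid.
shift_mask <- function(mask, offset) {
  out <- cpp_resample_affine(as.numeric(mask$data * 1.0), vol_dims(mask),
                             mask$spacing, mask$origin,
                             as.numeric(diag(3)), -as.numeric(offset),
                             vol_dims(mask), mask$spacing, mask$origin,
                             TRUE, 0)
  binary_mask(array(out > 0.5, vol_dims(mask)), mask$spacing, mask$origin)
}

#' Build matched feature-point pairs from accepted tree pairs
#'
#' For every accepted pair, the post-operative skeleton is rigidly
#' pre-aligned (rigid CPD) and then non-rigid CPD maps it onto the
#' pre-operative skeleton; each post-operative centerline point paired with
#' its mapped pre-operative position becomes a control-point pair. Points
#' whose CPD posterior maximum falls below `posterior_cutoff` are dropped
#' as outliers.
#'
#' A post-operative tree may be a truncated version of its pre-operative
#' counterpart (part of it was resected), in which case CPD would stretch
#' the remnant over the full pre-operative skeleton; the pre-operative
#' skeleton is therefore cropped to the centroid-aligned post tree's
#' support (within `support_pad_mm`) before alignment.
#'
#' @param res A `match_result` with at least one accepted pair.
#' @param pre_trees,post_trees Tree lists on the common grid.
#' @param posterior_cutoff Retention threshold on the CPD posterior.
#' @param beta,lambda,w Non-rigid CPD hyperparameters.
#' @param support_pad_mm Support-crop distance for the pre skeleton.
#' @param consensus_mm Maximum deviation of a pair's displacement from the
#'   median displacement of its 12 nearest feature pairs.
#' @return A `feature_point_set`: list with `post_points`, `pre_points`
#'   (n x 3 mm), `source_tree` (pair label per point).
#' @export
build_feature_points <- function(res, pre_trees, post_trees,
                                 posterior_cutoff = 0.5,
                                 beta = 2, lambda = 30, w = 0.3,
                                 support_pad_mm = 6, consensus_mm = 4) {
  if (nrow(res$pairs) == 0L)
    stop("build_feature_points: no accepted tree pairs; registration impossible")
  post_list <- list(); pre_list <- list(); src <- character(0)
  for (k in seq_len(nrow(res$pairs))) {
    po <- post_trees[[res$pairs$post_id[k]]]
    pr <- pre_trees[[res$pairs$pre_id[k]]]
    if (nrow(po$skeleton) < 5L || nrow(pr$skeleton) < 5L) next
    key <- paste(po$id, pr$id, sep = "-")
    # crop the pre skeleton to the support of the offset-aligned post tree;
    # for Phase II pairs the searching offset (from matched neighbours) is
    # unbiased by the truncation, unlike the centroid difference
    off <- res$offsets[[key]]
    if (is.null(off)) off <- pr$centroid - po$centroid
    shifted <- sweep(po$skeleton, 2, off, "+")
    nn <- apply(pr$skeleton, 1, function(p) min(colSums((t(shifted) - p)^2)))
    pr_skel <- pr$skeleton[nn <= support_pad_mm^2, , drop = FALSE]
    if (nrow(pr_skel) < 5L) pr_skel <- pr$skeleton
    fit <- rigid_cpd(po$skeleton, pr_skel)
    aligned <- apply_rigid(po$skeleton, fit)
    nr <- nonrigid_cpd(aligned, pr_skel, beta = beta, lambda = lambda, w = w)
    keep <- nr$posterior_max >= posterior_cutoff
    if (sum(keep) < 3L) next
    post_list[[k]] <- po$skeleton[keep, , drop = FALSE]
    pre_list[[k]] <- nr$points[keep, , drop = FALSE]
    src <- c(src, rep(key, sum(keep)))
  }
  post_points <- do.call(rbind, post_list)
  pre_points <- do.call(rbind, pre_list)
  if (is.null(post_points) || nrow(post_points) == 0L)
    stop("build_feature_points: all candidate points were rejected as outliers")
  # local-consensus screening: a pair's displacement must agree with the
  # median displacement of its spatial neighbourhood (genuine deformation
  # varies smoothly within the remaining lung on this scale)
  disp <- pre_points - post_points
  n <- nrow(post_points)
  if (n > 20) {
    kk <- min(12L, n - 1L)
    dev <- vapply(seq_len(n), function(i) {
      d2 <- colSums((t(post_points) - post_points[i, ])^2)
      nb <- order(d2)[2:(kk + 1L)]
      med <- apply(disp[nb, , drop = FALSE], 2, stats::median)
      sqrt(sum((disp[i, ] - med)^2))
    }, numeric(1))
    ok <- dev <= consensus_mm
    if (sum(ok) >= 20) {
      post_points <- post_points[ok, , drop = FALSE]
      pre_points <- pre_points[ok, , drop = FALSE]
      src <- src[ok]
    }
  }
  structure(list(post_points = post_points, pre_points = pre_points,
                 source_tree = src), class = "feature_point_set")
}

#' @export
print.feature_point_set <- function(x, ...) {
  cat(sprintf("<feature_point_set> %d point pairs from %d tree pairs; mean displacement %.2f mm\n",
              nrow(x$post_points), length(unique(x$source_tree)),
              mean(sqrt(rowSums((x$pre_points - x$post_points)^2)))))
  invisible(x)
}

#' Export a feature point set to CSV
#' @param fps A `feature_point_set`.
#' @param path Output CSV path.
#' @export
write_feature_points_csv <- function(fps, path) {
  df <- data.frame(pre_z = fps$pre_points[, 1], pre_y = fps$pre_points[, 2],
                   pre_x = fps$pre_points[, 3], post_z = fps$post_points[, 1],
                   post_y = fps$post_points[, 2], post_x = fps$post_points[, 3],
                   tree_pair = fps$source_tree)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
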