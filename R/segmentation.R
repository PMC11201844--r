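#' Vessel filter configuration
#'
#' Parameters of the single-scale Hessian (Frangi-type) tubularity filter
#' used for pulmonary vessel enhancement. The Gaussian scale defaults to
#' 3 mm, trading fine-vessel detail for matching stability, and the vessel
#' mask is obtained by thresholding the response at a percentile of its
#' values inside the lung mask (default 95th).
#'
#' @param sigma Gaussian scale in mm (> 0).
#' @param threshold_percentile Percentile in (0, 100) of the in-lung
#'   vesselness used as the segmentation threshold.
#' @param alpha,beta Frangi plate/blob sensitivity constants.
#' @param c Structureness constant; `NA` selects the data-driven default of
#'   half the maximum Hessian Frobenius norm.
#' @return A `vessel_filter_config` list.
#' @export
vessel_filter_config <- function(sigma = 3, threshold_percentile = 95,
                                 alpha = 0.5, beta = 0.5, c = NA_real_) {
  if (!is.numeric(sigma) || sigma <= 0) stop("vessel_filter_config: sigma must be > 0")
  if (threshold_percentile <= 0 || threshold_percentile >= 100)
    stop("vessel_filter_config: threshold_percentile must be in (0, 100)")
  structure(list(sigma = sigma, threshold_percentile = threshold_percentile,
                 alpha = alpha, beta = beta, c = c),
            class = "vessel_filter_config")
}

gaussian_smooth <- function(vol, sigma_mm) {
  out <- cpp_gaussian3d(as.numeric(vol$data), vol_dims(vol), sigma_mm / vol$spacing)
  image_volume(array(out, vol_dims(vol)), vol$spacing, vol$origin)
}

#' Segment the lungs from an isotropic HU volume
#'
#' Gaussian smoothing, a fixed threshold at -775 HU, 3D connected-component
#' analysis discarding exterior air (components touching the grid boundary),
#' retention of the largest one or two interior low-density components, and
#' per-axial-slice hole filling (so vessels and tumors inside the lung are
#' part of the mask).
#'
#' @param vol An isotropic [image_volume()] in HU.
#' @param sigma Smoothing scale in mm before thresholding.
#' @param threshold_hu Lung threshold in HU.
#' @param second_component_min_frac A second interior component is kept when
#'   its volume is at least this fraction of the largest (two lungs).
#' @param fill_close_mm Closing radius applied before per-slice hole
#'   filling; seals vessel openings at the mask boundary.
#' @return A [binary_mask()] of the lung region.
#' @export
segment_lungs <- function(vol, sigma = 1, threshold_hu = -775,
                          second_component_min_frac = 0.2,
                          fill_close_mm = 4) {
  stopifnot_isotropic(vol, "segment_lungs")
  sm <- gaussian_smooth(vol, sigma)
  low <- sm$data < threshold_hu
  dims <- vol_dims(vol)
  lab <- array(cpp_label(as.logical(low), dims, 26L), dims)
  if (max(lab) == 0L) stop("segment_lungs: no voxels below the lung threshold")
  # components touching the grid boundary are exterior air
  boundary_labels <- unique(c(lab[c(1, dims[1]), , ], lab[, c(1, dims[2]), ],
                              lab[, , c(1, dims[3])]))
  boundary_labels <- boundary_labels[boundary_labels > 0]
  counts <- tabulate(lab[lab > 0], nbins = max(lab))
  interior <- setdiff(which(counts > 0), boundary_labels)
  if (length(interior) == 0L)
    stop("segment_lungs: no interior low-density component found (segmentation failure)")
  interior <- interior[order(counts[interior], decreasing = TRUE)]
  keep <- interior[1]
  if (length(interior) > 1 &&
      counts[interior[2]] >= second_component_min_frac * counts[interior[1]])
    keep <- interior[1:2]
  m <- binary_mask(array(lab %in% keep, dims), vol$spacing, vol$origin)
  # the smoothed low-density components localize the lungs; the final
  # boundary comes from the raw intensities inside a band around them, so
  # the smoothing-induced inward bias of the thresholded boundary cancels
  refined <- (vol$data < threshold_hu) & dilate_mm(m, 2 * sigma + 1)$data
  lab2 <- array(cpp_label(as.logical(refined), dims, 26L), dims)
  seed_labels <- unique(lab2[m$data & refined])
  seed_labels <- seed_labels[seed_labels > 0]
  m$data <- array(lab2 %in% seed_labels, dims)
  # closing seals openings where vessels cross the lung boundary (e.g. at a
  # resection face), so the per-slice fill can reclaim them as interior
  m <- erode_mm(dilate_mm(m, fill_close_mm), fill_close_mm)
  filled <- cpp_fill_holes_axial(as.logical(m$data), dims)
  binary_mask(array(filled, dims), vol$spacing, vol$origin)
}

#' Single-scale Hessian tubularity (vesselness) response
#'
#' Frangi-type response for bright tubular structures, computed from the
#' Hessian of the sigma-smoothed volume at the configured single scale and
#' zeroed outside the lung mask. Response is non-negative.
#'
#' @param vol Isotropic [image_volume()].
#' @param lung Non-empty lung [binary_mask()] on the same grid.
#' @param cfg A [vessel_filter_config()].
#' @return An [image_volume()] holding the scalar response.
#' @export
vesselness_filter <- function(vol, lung, cfg = vessel_filter_config()) {
  stopifnot_isotropic(vol, "vesselness_filter")
  stopifnot_same_grid(vol, lung, "vesselness_filter")
  if (mask_volume(lung) == 0L) stop("vesselness_filter: lung mask is empty")
  sm <- gaussian_smooth(vol, cfg$sigma)
  v <- cpp_vesselness(as.numeric(sm$data), vol_dims(vol), vol$spacing,
                      cfg$alpha, cfg$beta, if (is.na(cfg$c)) -1 else cfg$c)
  v <- array(v, vol_dims(vol))
  v[!lung$data] <- 0
  image_volume(v, vol$spacing, vol$origin)
}

#' Segment the pulmonary vessel tree
#'
#' Thresholds the vesselness response at the configured percentile of its
#' values inside the lung mask, then intersects with the lung eroded by
#' 4 mm so the mediastinal border (main pulmonary arteries and veins) is
#' excluded.
#'
#' @inheritParams vesselness_filter
#' @param erosion_mm Lung erosion radius in mm.
#' @return A [binary_mask()] of vessels.
#' @export
segment_vessel_tree <- function(vol, lung, cfg = vessel_filter_config(),
                                erosion_mm = 4) {
  v <- vesselness_filter(vol, lung, cfg)
  thr <- stats::quantile(v$data[lung$data], probs = cfg$threshold_percentile / 100,
                         names = FALSE, type = 7)
  core <- erode_mm(lung, erosion_mm)
  m <- v$data > thr & v$data > 0 & core$data
  binary_mask(array(m, vol_dims(vol)), vol$spacing, vol$origin)
}

#' Segment the tumor by seeded region growing
#'
#' Region-grows from the seed within the lung over voxels above a HU floor,
#' applies a 1 mm morphological opening, removes voxels whose vesselness
#' exceeds the vessel threshold (so abutting vessels are excluded), keeps
#' the seed's component, and closes by 1 mm.
#'
#' @param vol Isotropic [image_volume()].
#' @param lung Lung [binary_mask()].
#' @param seed Integer (z, y, x) 1-based voxel index inside the lung on
#'   tissue above `hu_floor`.
#' @param hu_floor HU floor for region growing.
#' @param cfg [vessel_filter_config()] used for vessel removal.
#' @param max_lung_fraction Growth beyond this fraction of the lung volume
#'   aborts with a runaway-growth error.
#' @param core_protect_mm Opening radius defining the tumor core protected
#'   from vessel subtraction; keep above the largest vessel radius.
#' @return A [binary_mask()] of the tumor.
#' @export
segment_tumor <- function(vol, lung, seed, hu_floor = -300,
                          cfg = vessel_filter_config(),
                          max_lung_fraction = 0.1, core_protect_mm = 3.5) {
  stopifnot_isotropic(vol, "segment_tumor")
  stopifnot_same_grid(vol, lung, "segment_tumor")
  seed <- as.integer(seed)
  dims <- vol_dims(vol)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > dims))
    stop("segment_tumor: seed index out of range")
  sd_ <- vol$data[seed[1], seed[2], seed[3]]
  if (!lung$data[seed[1], seed[2], seed[3]])
    stop("segment_tumor: seed lies outside the lung mask")
  if (sd_ <= hu_floor)
    stop(sprintf("segment_tumor: seed HU (%.0f) is below the %.0f HU tissue floor", sd_, hu_floor))
  grow <- vol$data > hu_floor & lung$data
  lab <- array(cpp_label(as.logical(grow), dims, 26L), dims)
  region <- lab == lab[seed[1], seed[2], seed[3]]
  if (sum(region) > max_lung_fraction * mask_volume(lung))
    stop("segment_tumor: grown region exceeds the runaway-growth guard")
  m <- binary_mask(region, vol$spacing, vol$origin)
  m <- dilate_mm(erode_mm(m, 1), 1)                    # opening
  vess <- vesselness_filter(vol, lung, cfg)
  thr <- stats::quantile(vess$data[lung$data], probs = cfg$threshold_percentile / 100,
                         names = FALSE, type = 7)
  # the Frangi subtraction targets attached vessels; a wide opening of the
  # grown region (radius above the vessel calibre) defines a protected core
  # so the subtraction cannot carve the tumor body itself
  core <- dilate_mm(erode_mm(m, core_protect_mm), core_protect_mm)
  m$data[vess$data > thr & vess$data > 0 & !core$data] <- FALSE
  lab2 <- array(cpp_label(as.logical(m$data), dims, 26L), dims)
  if (lab2[seed[1], seed[2], seed[3]] > 0) {
    m$data <- lab2 == lab2[seed[1], seed[2], seed[3]]
  } else if (max(lab2) > 0) {
    # opening/vessel removal may nibble the exact seed voxel: keep the
    # component nearest the seed
    sw <- voxel_to_world(m, matrix(seed, 1))
    comps <- seq_len(max(lab2))
    dmin <- vapply(comps, function(l) {
      idx <- which(lab2 == l, arr.ind = TRUE)
      min(sqrt(rowSums(sweep(voxel_to_world(m, idx), 2, sw[1, ], "-")^2)))
    }, numeric(1))
    m$data <- lab2 == comps[which.min(dmin)]
  } else stop("segment_tumor: nothing remains after vessel removal")
  m <- erode_mm(dilate_mm(m, 1), 1)                    # closing
  m
}

#' Decompose a vessel mask into subvascular trees
#'
#' 26-connected components of the vessel mask with a voxel count strictly
#' above `min_voxels` become subvascular trees, each skeletonized by
#' topology-preserving thinning. Labels are deterministic: decreasing
#' volume, ties broken by the lexicographically smallest voxel index.
#'
#' @param vessels Vessel [binary_mask()] on an isotropic grid.
#' @param min_voxels Strict lower bound on component voxel count.
#' @return A list of `subvascular_tree` objects (possibly empty); each has
#'   `id`, `voxels` (1-based indices), `volume`, `centroid` (mm),
#'   `skeleton` (mm point matrix) and `skeleton_idx`.
#' @export
extract_subvascular_trees <- function(vessels, min_voxels = 250) {
  stopifnot_isotropic(vessels, "extract_subvascular_trees")
  dims <- vol_dims(vessels)
  lab <- array(cpp_label(as.logical(vessels$data), dims, 26L), dims)
  if (max(lab) == 0L) return(list())
  counts <- tabulate(lab[lab > 0], nbins = max(lab))
  big <- which(counts > min_voxels)
  if (length(big) == 0L) return(list())
  # cpp_label assigns labels in scan order of first-seen voxel, so the label
  # value is itself the lexicographic tiebreaker
  big <- big[order(-counts[big], big)]
  trees <- vector("list", length(big))
  for (i in seq_along(big)) {
    l <- big[i]
    idx <- which(lab == l, arr.ind = TRUE)
    sk_idx <- skeletonize_component(vessels, idx)
    trees[[i]] <- structure(list(
      id = i,
      voxels = idx,
      volume = nrow(idx),
      centroid = colMeans(voxel_to_world(vessels, idx)),
      skeleton = voxel_to_world(vessels, sk_idx),
      skeleton_idx = sk_idx,
      spacing = vessels$spacing,
      origin = vessels$origin,
      dims = dims), class = "subvascular_tree")
  }
  trees
}

# Thin one component on its padded bounding box and map indices back.
skeletonize_component <- function(mask, idx) {
  lo <- pmax(apply(idx, 2, min) - 2L, 1L)
  hi <- pmin(apply(idx, 2, max) + 2L, vol_dims(mask))
  sub_dims <- hi - lo + 1L
  sub <- array(FALSE, sub_dims)
  sub[cbind(idx[, 1] - lo[1] + 1L, idx[, 2] - lo[2] + 1L, idx[, 3] - lo[3] + 1L)] <- TRUE
  sk <- array(cpp_skeletonize(as.logical(sub), sub_dims), sub_dims)
  out <- which(sk, arr.ind = TRUE)
  out[, 1] <- out[, 1] + lo[1] - 1L
  out[, 2] <- out[, 2] + lo[2] - 1L
  out[, 3] <- out[, 3] + lo[3] - 1L
  out
}

#' @export
print.subvascular_tree <- function(x, ...) {
  cat(sprintf("<subvascular_tree #%d> %d voxels, %d skeleton points, centroid (%.1f, %.1f, %.1f) mm\n",
              x$id, x$volume, nrow(x$skeleton), x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

# Dense logical mask of one tree on its full grid.
tree_mask <- function(tree) {
  m <- array(FALSE, tree$dims)
  m[tree$voxels] <- TRUE
  binary_mask(m, tree$spacing, tree$origin)
}

#' Serialize a set of subvascular trees
#'
#' Writes a 16-bit labelled NIfTI volume (voxel value = tree id) and a JSON
#' sidecar with id, volume, centroid and skeleton point list in mm.
#'
#' @param trees List of `subvascular_tree` objects.
#' @param path_nifti,path_json Output paths.
#' @export
write_tree_set <- function(trees, path_nifti, path_json) {
  if (length(trees) == 0L) stop("write_tree_set: empty tree list")
  dims <- trees[[1]]$dims
  lab <- array(0L, dims)
  for (tr in trees) lab[tr$voxels] <- tr$id
  img <- RNifti::asNifti(aperm(lab, c(3, 2, 1)), datatype = "int16")
  RNifti::writeNifti(img, path_nifti)
  meta <- lapply(trees, function(tr) list(
    id = tr$id, volume = tr$volume, centroid = as.numeric(tr$centroid),
    skeleton_mm = unname(apply(tr$skeleton, 1, as.numeric, simplify = FALSE))))
  jsonlite::write_json(meta, path_json, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
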