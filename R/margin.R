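#' Measure the resection margin distance
#'
#' Overlays the deformed (warped) post-operative lung mask and the
#' pre-operative tumor mask in the common pre-operative frame. The
#' resection region is the pre-operative lung minus the warped
#' post-operative lung (largest component nearest the tumor); the
#' resection edge is the warped lung surface within `edge_zone_mm` of that
#' region, and the margin is the minimum Euclidean distance between the
#' resection edge and the tumor surface, with a deterministic
#' (lexicographic scan-order) tie-break on the closest pair. Distances
#' below one voxel are flagged with the `"< 1.00 mm"` sentinel; a warped
#' lung overlapping the tumor returns distance 0 with an overlap flag.
#'
#' @param warped_post_lung Warped post-operative lung [binary_mask()].
#' @param pre_tumor Pre-operative tumor [binary_mask()] (non-empty).
#' @param pre_lung Pre-operative lung [binary_mask()].
#' @param edge_zone_mm Restriction zone of the resection edge around the
#'   resection region.
#' @return A `margin_result`: `distance` (mm), `point_on_resection`,
#'   `point_on_tumor` (mm), `resection_region`, `overlap`, `display`.
#' @export
measure_margin <- function(warped_post_lung, pre_tumor, pre_lung,
                           edge_zone_mm = 2) {
  stopifnot_same_grid(warped_post_lung, pre_tumor, "measure_margin")
  stopifnot_same_grid(warped_post_lung, pre_lung, "measure_margin")
  if (mask_volume(pre_tumor) == 0L) stop("measure_margin: tumor mask is empty")
  if (mask_volume(warped_post_lung) == 0L) stop("measure_margin: warped lung mask is empty")
  if (!any(pre_tumor$data & pre_lung$data))
    stop("measure_margin: tumor lies entirely outside the pre-operative lung")

  dims <- vol_dims(pre_lung)
  resect <- pre_lung$data & !warped_post_lung$data
  resection_region <- binary_mask(array(FALSE, dims), pre_lung$spacing, pre_lung$origin)
  if (any(resect)) {
    lab <- array(cpp_label(as.logical(resect), dims, 26L), dims)
    dtum <- array(cpp_edt(as.logical(pre_tumor$data), dims, pre_lung$spacing), dims)
    ncomp <- max(lab)
    dmin <- vapply(seq_len(ncomp), function(l) min(dtum[lab == l]), numeric(1))
    resection_region$data <- lab == which.min(dmin)
  }

  if (any(warped_post_lung$data & pre_tumor$data)) {
    ov <- which(warped_post_lung$data & pre_tumor$data, arr.ind = TRUE)
    p <- voxel_to_world(pre_lung, ov[1, , drop = FALSE])[1, ]
    return(structure(list(distance = 0, point_on_resection = p, point_on_tumor = p,
                          resection_region = resection_region, overlap = TRUE,
                          display = "0.00 mm (overlap)"), class = "margin_result"))
  }

  edge_idx <- mask_surface(warped_post_lung)
  if (mask_volume(resection_region) > 0L) {
    dres <- array(cpp_edt(as.logical(resection_region$data), dims, pre_lung$spacing), dims)
    near <- dres[edge_idx] <= edge_zone_mm + 1e-9
    if (any(near)) edge_idx <- edge_idx[near, , drop = FALSE]
  }
  tum_idx <- mask_surface(pre_tumor)
  A <- voxel_to_world(pre_lung, edge_idx)
  B <- voxel_to_world(pre_lung, tum_idx)
  cp <- cpp_closest_pair(A, B)
  dist <- cp$distance
  structure(list(distance = dist,
                 point_on_resection = A[cp$i, ],
                 point_on_tumor = B[cp$j, ],
                 resection_region = resection_region, overlap = FALSE,
                 display = margin_display(dist, min(pre_lung$spacing))),
            class = "margin_result")
}

margin_display <- function(dist, voxel_mm) {
  if (dist < voxel_mm) sprintf("< %.2f mm", voxel_mm) else sprintf("%.2f mm", dist)
}

#' @export
print.margin_result <- function(x, ...) {
  cat(sprintf("<margin_result> resection margin %s%s; resection region %d voxels\n",
              x$display, if (x$overlap) " [warped lung overlaps tumor]" else "",
              mask_volume(x$resection_region)))
  invisible(x)
}

#' Read landmark pairs from CSV
#'
#' Expected columns: `label, pre_z, pre_y, pre_x, post_z, post_y, post_x`
#' (mm world coordinates).
#' @param path CSV path.
#' @return data.frame of landmark pairs.
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "pre_z", "pre_y", "pre_x", "post_z", "post_y", "post_x")
  if (!all(need %in% names(df)))
    stop(sprintf("read_landmarks_csv: missing columns: %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  df
}

#' Target registration error of a displacement field
#'
#' For each landmark pair, the error is
#' `|| (post_point + u(post_point)) - pre_point ||` with the field sampled
#' by trilinear interpolation. Landmarks outside the field's validity mask
#' are excluded with a warning and counted.
#'
#' @param landmarks data.frame with columns `label, pre_z, pre_y, pre_x,
#'   post_z, post_y, post_x` (mm).
#' @param field A `displacement_field`.
#' @return A `tre_report`: per-landmark errors plus mean, sd, max, min and
#'   the excluded count.
#' @export
compute_tre <- function(landmarks, field) {
  if (nrow(landmarks) < 1L) stop("compute_tre: need at least one landmark")
  post <- as.matrix(landmarks[, c("post_z", "post_y", "post_x")])
  pre <- as.matrix(landmarks[, c("pre_z", "pre_y", "pre_x")])
  u <- sample_field(field, post)
  ok <- !is.na(u[, 1])
  if (!all(ok))
    warning(sprintf("compute_tre: %d landmark(s) outside the field validity mask were excluded", sum(!ok)))
  if (!any(ok)) stop("compute_tre: no landmark lies inside the field")
  err <- sqrt(rowSums((post[ok, , drop = FALSE] + u[ok, , drop = FALSE] -
                         pre[ok, , drop = FALSE])^2))
  structure(list(per_landmark = data.frame(label = landmarks$label[ok], error = err),
                 mean = mean(err), sd = if (length(err) > 1) stats::sd(err) else 0,
                 max = max(err), min = min(err),
                 n = length(err), n_excluded = sum(!ok)),
            class = "tre_report")
}

#' @export
print.tre_report <- function(x, ...) {
  cat(sprintf("<tre_report> n = %d: %.2f +/- %.2f mm (max %.2f, min %.2f)%s\n",
              x$n, x$mean, x$sd, x$max, x$min,
              if (x$n_excluded > 0) sprintf(" [%d excluded]", x$n_excluded) else ""))
  invisible(x)
}

#' Maximum intensity projection over a slab of slices
#'
#' Per-pixel maximum over `slabs` slices centered at `center_index` along
#' the chosen axis; the standard vessel-landmark visualization aid.
#'
#' @param vol An [image_volume()].
#' @param axis `"z"`, `"y"` or `"x"`.
#' @param center_index 1-based slice index; the whole slab must fit inside
#'   the volume.
#' @param slabs Odd slab thickness in slices.
#' @return 2D matrix.
#' @export
mip_slab <- function(vol, axis = c("z", "y", "x"), center_index, slabs = 5L) {
  axis <- match.arg(axis)
  ai <- match(axis, c("z", "y", "x"))
  half <- slabs %/% 2L
  n <- vol_dims(vol)[ai]
  if (center_index - half < 1L || center_index + half > n)
    stop(sprintf("mip_slab: slab [%d, %d] outside axis range 1..%d",
                 center_index - half, center_index + half, n))
  sl <- (center_index - half):(center_index + half)
  sub <- switch(axis,
                z = vol$data[sl, , , drop = FALSE],
                y = vol$data[, sl, , drop = FALSE],
                x = vol$data[, , sl, drop = FALSE])
  apply(sub, setdiff(1:3, ai), max)
}

#' Paired-sample t test on registration errors
#'
#' Classical paired t statistic on the differences with `n - 1` degrees of
#' freedom, plus the conventional significance stars (* p < 0.05,
#' ** p < 0.01, *** p < 0.001, ns otherwise). Identical samples return
#' t = 0, p = 1; nonzero constant differences are degenerate and error.
#'
#' @param errors_a,errors_b Equal-length numeric vectors (n >= 2), e.g.
#'   per-landmark TREs of two methods.
#' @return List with `t`, `p`, `df`, `stars`.
#' @export
paired_t_test <- function(errors_a, errors_b) {
  a <- as.numeric(errors_a); b <- as.numeric(errors_b)
  if (length(a) != length(b) || length(a) < 2L)
    stop("paired_t_test: need two equal-length samples of size >= 2")
  d <- a - b
  if (all(d == 0)) return(list(t = 0, p = 1, df = length(d) - 1L, stars = "ns"))
  if (stats::sd(d) == 0)
    stop("paired_t_test: zero-variance differences (degenerate input)")
  ht <- stats::t.test(a, b, paired = TRUE)
  p <- ht$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
  list(t = unname(ht$statistic), p = p, df = unname(ht$parameter), stars = stars)
}
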