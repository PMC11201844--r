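#' Candidate radius for control-point selection
#'
#' `R = 2 * dmax * exp(a * (d / dmax - 1))`: voxels close to the tumor get
#' a small sphere of interest (localized deformation), voxels far away get
#' one approaching `2 * dmax` (global deformation). Strictly increasing in
#' `d`; the growth parameter defaults to `a = 3`.
#'
#' @param d Distance from the query voxel to the tumor centroid (mm, >= 0).
#' @param dmax Furthest distance from the tumor centroid to the lung edge
#'   (mm, > 0).
#' @param a Radius growth parameter.
#' @return Candidate radius in mm (vectorized over `d`).
#' @export
candidate_radius <- function(d, dmax, a = 3) {
  if (!is.numeric(dmax) || any(dmax <= 0)) stop("candidate_radius: dmax must be > 0")
  if (any(d < 0)) stop("candidate_radius: d must be >= 0")
  2 * dmax * exp(a * (d / dmax - 1))
}

#' Registration parameters for the selective displacement field
#'
#' @param a Candidate-radius growth parameter.
#' @param dbscan_eps DBSCAN radius in displacement space (mm).
#' @param dbscan_min_pts DBSCAN core-point minimum.
#' @param k_fallback Number of nearest feature pairs used when candidates
#'   are scarce or clustering yields no cluster.
#' @param max_control Cap on control points per node-wise TPS fit (nearest
#'   members of the chosen cluster are kept).
#' @param stride Field evaluation lattice stride in voxels (1 = exact
#'   per-voxel evaluation).
#' @param ridge Ridge added to the TPS kernel diagonal (0 = exact
#'   interpolation).
#' @param domain_pad_mm Field domain: the reference lung dilated by this
#'   radius.
#' @export
field_params <- function(a = 3, dbscan_eps = 2, dbscan_min_pts = 5,
                         k_fallback = 15, max_control = 120, stride = 4L,
                         ridge = 0, domain_pad_mm = 10) {
  stopifnot(a > 0, dbscan_eps > 0, dbscan_min_pts >= 1, k_fallback >= 4,
            max_control >= 4, stride >= 1, ridge >= 0, domain_pad_mm >= 0)
  list(a = a, dbscan_eps = dbscan_eps, dbscan_min_pts = dbscan_min_pts,
       k_fallback = k_fallback, max_control = max_control,
       stride = as.integer(stride), ridge = ridge, domain_pad_mm = domain_pad_mm)
}

#' Select the control-point subset for one voxel
#'
#' Feature pairs whose post-operative point lies within the candidate
#' radius of the voxel are clustered by DBSCAN on their 3D displacement
#' vectors; noise points are discarded and the cluster whose members' mean
#' position is nearest the voxel is returned (tie: larger cluster, then
#' lower cluster id). When there are fewer candidates than `dbscan_min_pts`
#' or no cluster forms, the `k_fallback` nearest feature pairs by position
#' are used instead.
#'
#' @param voxel Query position (z, y, x) mm.
#' @param tumor_centroid Tumor centroid (mm).
#' @param dmax Furthest tumor-to-lung-edge distance (mm).
#' @param fps A non-empty `feature_point_set`.
#' @param params A [field_params()] list.
#' @return Integer indices into the feature point set.
#' @export
select_control_points <- function(voxel, tumor_centroid, dmax, fps,
                                  params = field_params()) {
  if (!inherits(fps, "feature_point_set") || nrow(fps$post_points) == 0L)
    stop("select_control_points: feature point set is empty")
  d <- sqrt(sum((as.numeric(voxel) - as.numeric(tumor_centroid))^2))
  R <- candidate_radius(d, dmax, params$a)
  mc <- if (is.finite(params$max_control)) as.integer(params$max_control)
        else nrow(fps$post_points)
  cpp_select_control_points(as.numeric(voxel), fps$post_points,
                            fps$pre_points - fps$post_points, R,
                            params$dbscan_eps, params$dbscan_min_pts,
                            params$k_fallback, mc)
}

#' Fit a 3D thin-plate spline
#'
#' Exact-interpolation TPS with the 3D kernel `U(r) = r` and a full affine
#' part: at every control source point the fitted map returns its
#' destination exactly (up to solver tolerance) when `ridge = 0`.
#' Degenerate (coplanar/collinear) control sets fall back to a regularized
#' least-squares solve with a warning.
#'
#' @param control_src,control_dst n x 3 matrices (mm), n >= 4, same length.
#' @param ridge Optional ridge on the kernel diagonal.
#' @return A `tps` object usable with [tps_predict()].
#' @export
tps_fit <- function(control_src, control_dst, ridge = 0) {
  src <- as.matrix(control_src); dst <- as.matrix(control_dst)
  if (nrow(src) != nrow(dst)) stop("tps_fit: src/dst lengths differ")
  if (nrow(src) < 4L) stop("tps_fit: need at least 4 control points")
  # affine independence check: rank of centered src must be 3
  sv <- svd(scale(src, scale = FALSE))$d
  if (sv[3] < 1e-9 * max(sv[1], 1)) {
    warning("tps_fit: control points are coplanar/degenerate; using a regularized solve")
    if (ridge <= 0) ridge <- 1e-6
  }
  coef <- cpp_tps_fit(src, dst, ridge)
  structure(list(src = src, coef = coef, ridge = ridge), class = "tps")
}

#' Evaluate a fitted thin-plate spline
#' @param fit A `tps` object.
#' @param pts m x 3 matrix of query points (mm).
#' @return m x 3 matrix of mapped points.
#' @export
tps_predict <- function(fit, pts) {
  cpp_tps_eval(fit$src, fit$coef, as.matrix(pts))
}

#' @export
predict.tps <- function(object, newdata, ...) tps_predict(object, newdata)

#' Displacement field constructor (internal representation)
#' @noRd
displacement_field <- function(uz, uy, ux, valid, spacing, origin) {
  structure(list(uz = uz, uy = uy, ux = ux, valid = valid,
                 spacing = spacing, origin = origin,
                 dims = dim(uz)), class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(x$uz^2 + x$uy^2 + x$ux^2)[x$valid]
  cat(sprintf("<displacement_field> %s grid, %d valid voxels, |u| mean %.2f / max %.2f mm\n",
              paste(x$dims, collapse = "x"), sum(x$valid),
              if (length(mag)) mean(mag) else NA, if (length(mag)) max(mag) else NA))
  invisible(x)
}

#' Build the (possibly discontinuous) displacement field
#'
#' For each node of a strided lattice over the field domain (the reference
#' lung dilated by `domain_pad_mm`), control points are chosen with
#' [select_control_points()] and an exact-interpolation TPS on that subset
#' gives the node displacement; voxels inherit the displacement of their
#' node (nearest upsampling). Because different nodes may select different
#' displacement regimes, the field can jump across the resection boundary —
#' the behaviour a classical all-control-point TPS cannot produce. The
#' `method = "all_points"` baseline fits one TPS on every feature pair,
#' evaluated on the same lattice.
#'
#' @param fps A `feature_point_set` with at least `dbscan_min_pts` pairs.
#' @param tumor,lung Non-empty [binary_mask()]s on the reference grid.
#' @param params A [field_params()] list.
#' @param method `"selective"` (default) or the `"all_points"` classical
#'   baseline.
#' @return A `displacement_field` (mm vectors on the reference grid, with a
#'   validity mask).
#' @export
build_displacement_field <- function(fps, tumor, lung, params = field_params(),
                                     method = c("selective", "all_points")) {
  method <- match.arg(method)
  if (!inherits(fps, "feature_point_set")) stop("build_displacement_field: fps must be a feature_point_set")
  if (nrow(fps$post_points) < params$dbscan_min_pts)
    stop("build_displacement_field: not enough feature pairs")
  if (mask_volume(tumor) == 0L || mask_volume(lung) == 0L)
    stop("build_displacement_field: tumor and lung masks must be non-empty")
  stopifnot_same_grid(tumor, lung, "build_displacement_field")

  tc <- mask_centroid(tumor)
  surf <- voxel_to_world(lung, mask_surface(lung))
  dmax <- max(sqrt(rowSums(sweep(surf, 2, tc)^2)))
  domain <- if (params$domain_pad_mm > 0) dilate_mm(lung, params$domain_pad_mm) else lung

  n <- nrow(fps$post_points)
  if (method == "all_points") {
    minpts <- n + 1L       # force the k-nearest fallback with k = n
    kfb <- n
    mc <- n
  } else {
    minpts <- params$dbscan_min_pts
    kfb <- params$k_fallback
    mc <- as.integer(min(params$max_control, n))
  }
  out <- cpp_build_field(fps$post_points, fps$pre_points,
                         vol_dims(lung), lung$spacing, lung$origin,
                         as.logical(domain$data), as.numeric(tc),
                         dmax, params$a, params$dbscan_eps, minpts,
                         kfb, mc, params$ridge, params$stride)
  dims <- vol_dims(lung)
  displacement_field(array(out$uz, dims), array(out$uy, dims),
                     array(out$ux, dims), array(out$valid, dims),
                     lung$spacing, lung$origin)
}

#' Warp a mask or volume with a displacement field
#'
#' Applies the displacement per voxel (content at `x` is carried to
#' `x + u(x)`, realized by reverse sampling): nearest-neighbour for masks,
#' trilinear for volumes. The zero field is the identity; voxels outside
#' the field's validity mask become background.
#'
#' @param x An [image_volume()] or [binary_mask()] on the field's grid.
#' @param field A `displacement_field`.
#' @return Same class as `x`.
#' @export
warp_with_field <- function(x, field) {
  if (!inherits(field, "displacement_field")) stop("warp_with_field: field must be a displacement_field")
  if (!identical(vol_dims(x), as.integer(field$dims)))
    stop("warp_with_field: input and field grids differ")
  is_mask <- inherits(x, "binary_mask")
  bg <- if (is_mask) 0 else -1024
  out <- cpp_warp_field(as.numeric(if (is_mask) x$data * 1.0 else x$data),
                        vol_dims(x), x$spacing, x$origin,
                        as.numeric(field$uz), as.numeric(field$uy),
                        as.numeric(field$ux), as.logical(field$valid),
                        is_mask, bg)
  out <- array(out, vol_dims(x))
  if (is_mask) binary_mask(out > 0.5, x$spacing, x$origin)
  else image_volume(out, x$spacing, x$origin)
}

#' Sample a displacement field at world points (trilinear)
#' @param field A `displacement_field`.
#' @param pts m x 3 matrix of (z, y, x) positions in mm.
#' @return m x 3 matrix of displacement vectors (mm); NA rows for points
#'   outside the validity mask.
#' @export
sample_field <- function(field, pts) {
  pts <- as.matrix(pts)
  dims <- as.integer(field$dims)
  ok <- cpp_sample_points(as.numeric(field$valid * 1.0), dims, field$spacing,
                          field$origin, pts, TRUE)
  u <- vapply(list(field$uz, field$uy, field$ux), function(comp)
    cpp_sample_points(as.numeric(comp), dims, field$spacing, field$origin, pts, FALSE),
    numeric(nrow(pts)))
  u <- matrix(u, ncol = 3)
  u[is.na(ok) | ok < 0.5, ] <- NA_real_
  u
}

#' Write a displacement field as a 4-volume NIfTI set
#'
#' Writes `<stem>_uz/uy/ux.nii.gz` (mm components) plus `<stem>_valid.nii.gz`.
#' @param field A `displacement_field`.
#' @param stem Output path stem.
#' @export
write_field <- function(field, stem) {
  for (comp in c("uz", "uy", "ux"))
    write_volume(image_volume(field[[comp]], field$spacing, field$origin),
                 paste0(stem, "_", comp, ".nii.gz"))
  write_volume(binary_mask(field$valid, field$spacing, field$origin),
               paste0(stem, "_valid.nii.gz"))
  invisible(stem)
}
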