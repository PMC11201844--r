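#' 3D image volume in Hounsfield units
#'
#' The common currency of the pipeline: a 3D scalar array with physical
#' geometry. Axis order is fixed to (z, y, x) internally; spacing and origin
#' are in mm and the world coordinate of voxel index `i` (1-based) is
#' `origin + (i - 1) * spacing`. Orientation is normalized to axis-aligned
#' identity at the I/O boundary, so no rotation is carried.
#'
#' @param data 3D numeric array, dim = (nz, ny, nx).
#' @param spacing Numeric length-3, per-axis voxel size in mm (z, y, x);
#'   strictly positive.
#' @param origin Numeric length-3, world position (mm) of voxel (1,1,1).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("image_volume: data must have exactly 3 dimensions")
  if (any(dim(data) < 1L)) stop("image_volume: all dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("image_volume: spacing must be 3 strictly positive values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("image_volume: origin must be 3 finite values")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' 3D binary mask on an image grid
#'
#' Boolean companion of [image_volume()]: shares the (z, y, x) axis order,
#' spacing and origin conventions, and annotates a volume on the same lattice
#' (lung, tumor, vessel and tree masks).
#'
#' @param data 3D logical (or coercible) array.
#' @inheritParams image_volume
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("binary_mask: data must have exactly 3 dimensions")
  storage.mode(data) <- "logical"
  data[is.na(data)] <- FALSE
  v <- image_volume(array(0, dim(data)), spacing, origin)
  structure(list(data = data, spacing = v$spacing, origin = v$origin),
            class = "binary_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm, origin %s mm, HU range [%.1f, %.1f]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = "x"),
              paste(format(x$origin, digits = 4), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, spacing %s mm, %d foreground\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = "x"),
              sum(x$data)))
  invisible(x)
}

vol_dims <- function(x) as.integer(dim(x$data))

is_isotropic <- function(x, tol = 1e-6) {
  diff(range(x$spacing)) <= tol
}

stopifnot_isotropic <- function(x, what) {
  if (!is_isotropic(x))
    stop(sprintf("%s requires an isotropic grid (resample first); spacing is %s",
                 what, paste(format(x$spacing), collapse = "x")))
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

stopifnot_same_grid <- function(a, b, what) {
  if (!same_grid(a, b)) stop(sprintf("%s: masks/volumes are not on the same grid", what))
}

#' Convert voxel indices to world coordinates
#'
#' @param x An `image_volume` or `binary_mask`.
#' @param idx Integer matrix (n x 3) of 1-based (z, y, x) voxel indices.
#' @return Numeric matrix (n x 3) of world coordinates in mm.
#' @export
voxel_to_world <- function(x, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx - 1, 2, x$spacing, "*"), 2, x$origin, "+")
}

#' Convert world coordinates (mm) to fractional 1-based voxel indices
#' @inheritParams voxel_to_world
#' @param pts Numeric matrix (n x 3) of world coordinates (z, y, x) mm.
#' @export
world_to_voxel <- function(x, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(sweep(pts, 2, x$origin, "-"), 2, x$spacing, "/") + 1
}

#' Number of foreground voxels in a mask
#' @param mask A `binary_mask`.
#' @export
mask_volume <- function(mask) sum(mask$data)

#' Centroid of a mask in world coordinates (mm)
#' @param mask A non-empty `binary_mask`.
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask$data, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask_centroid: empty mask")
  colMeans(voxel_to_world(mask, idx))
}

#' Resample a volume or mask to isotropic spacing
#'
#' Brings a CT volume to a uniform voxel size (the pipeline standard is
#' 1 mm isotropic) by linear interpolation; masks use nearest-neighbour
#' interpolation and stay boolean. The physical extent is preserved to
#' within one voxel.
#'
#' @param vol An `image_volume` or `binary_mask`.
#' @param target_spacing Target voxel size in mm (> 0), applied to all axes.
#' @param mode `"linear"` (volumes) or `"nearest"` (masks). Defaults to the
#'   natural mode for the input class.
#' @return Resampled object of the same class as the input.
#' @export
resample_isotropic <- function(vol, target_spacing = 1,
                               mode = if (inherits(vol, "binary_mask")) "nearest" else "linear") {
  if (!is.numeric(target_spacing) || target_spacing <= 0)
    stop("resample_isotropic: target_spacing must be > 0")
  mode <- match.arg(mode, c("linear", "nearest"))
  dims <- vol_dims(vol)
  if (mode == "linear" && any(dims < 2L))
    stop("resample_isotropic: linear interpolation needs every dimension >= 2")
  odims <- pmax(1L, as.integer(round(dims * vol$spacing / target_spacing)))
  osp <- rep(target_spacing, 3)
  dat <- if (inherits(vol, "binary_mask")) vol$data * 1.0 else vol$data
  out <- cpp_resample_affine(as.numeric(dat), dims, vol$spacing, vol$origin,
                             as.numeric(diag(3)), c(0, 0, 0),
                             odims, osp, vol$origin,
                             mode == "nearest", 0, clamp = TRUE)
  out <- array(out, odims)
  if (inherits(vol, "binary_mask")) binary_mask(out > 0.5, osp, vol$origin)
  else image_volume(out, osp, vol$origin)
}

ball_morph <- function(mask, radius, op) {
  if (!inherits(mask, "binary_mask")) stop("erode_mm/dilate_mm: input must be a binary_mask")
  if (!is.numeric(radius) || radius < 0) stop("erode_mm/dilate_mm: radius must be >= 0")
  stopifnot_isotropic(mask, "erode_mm/dilate_mm")
  if (radius == 0) return(mask)
  dims <- vol_dims(mask)
  if (op == "dilate") {
    d <- cpp_edt(as.logical(mask$data), dims, mask$spacing)
    out <- array(d <= radius + 1e-9, dims)
  } else {
    d <- cpp_edt(as.logical(!mask$data), dims, mask$spacing)
    # voxel is kept iff the whole ball of the given radius fits inside
    out <- array(mask$data & (d > radius + 1e-9), dims)
  }
  binary_mask(out, mask$spacing, mask$origin)
}

#' Morphological erosion / dilation with a metric ball
#'
#' The structuring element is the discrete ball of the given physical radius
#' (mm) on the mask's isotropic grid, realised through the exact Euclidean
#' distance transform. Radius 0 is the identity; erosion output is contained
#' in the input and the input is contained in the dilation output.
#'
#' @param mask A `binary_mask` on an isotropic grid.
#' @param radius Ball radius in mm (>= 0).
#' @return A `binary_mask` on the same grid.
#' @export
erode_mm <- function(mask, radius) ball_morph(mask, radius, "erode")

#' @rdname erode_mm
#' @export
dilate_mm <- function(mask, radius) ball_morph(mask, radius, "dilate")

#' Extract the surface voxels of a mask
#'
#' Returns exactly the mask voxels that have at least one six-connected
#' background neighbour; the grid edge counts as background, so a full-grid
#' mask yields its boundary voxels.
#'
#' @param mask A non-empty `binary_mask`.
#' @return Integer matrix (n x 3) of 1-based (z, y, x) voxel indices in
#'   column-major scan order.
#' @export
mask_surface <- function(mask) {
  if (mask_volume(mask) == 0L) stop("mask_surface: empty mask")
  s <- array(cpp_surface(as.logical(mask$data), vol_dims(mask)), vol_dims(mask))
  which(s, arr.ind = TRUE)
}
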