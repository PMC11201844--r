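#' Affine transform between post- and pre-operative world coordinates
#'
#' Convention: `matrix %*% x_post + translation = x_pre`, coordinates in
#' (z, y, x) mm. The linear part must be invertible with positive
#' determinant (no reflection).
#'
#' @param matrix 3x3 linear part.
#' @param translation Length-3 translation in mm.
#' @param converged Logical convergence flag from the optimizer.
#' @return An `affine_transform` object.
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0),
                             converged = TRUE) {
  matrix <- base::matrix(as.numeric(matrix), 3, 3)
  translation <- as.numeric(translation)
  d <- det(matrix)
  if (abs(d) < 1e-12) stop("affine_transform: linear part is singular")
  if (d < 0) stop("affine_transform: reflections are not allowed (determinant < 0)")
  structure(list(matrix = matrix, translation = translation,
                 converged = isTRUE(converged)),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform> post -> pre (mm)\n")
  print(round(cbind(x$matrix, x$translation), 4))
  if (!x$converged) cat("  (optimizer did not fully converge)\n")
  invisible(x)
}

#' Invert an affine transform
#' @param t An [affine_transform()].
#' @export
invert_affine <- function(t) {
  Ai <- solve(t$matrix)
  affine_transform(Ai, -Ai %*% t$translation, t$converged)
}

#' Write / read an affine transform as JSON
#' @param t An [affine_transform()].
#' @param path File path.
#' @export
write_affine_json <- function(t, path) {
  jsonlite::write_json(list(matrix = as.numeric(base::t(t$matrix)),  # row-major
                            translation = t$translation,
                            convention = "post_to_pre_mm_zyx"),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_affine_json
#' @export
read_affine_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine_transform(base::t(matrix(j$matrix, 3, 3)), j$translation)
}

# Truncated signed Euclidean distance transform of a mask (mm): negative
# inside, positive outside, clipped to +/- trunc.
signed_dt <- function(mask, trunc = 10) {
  dims <- vol_dims(mask)
  dout <- cpp_edt(as.logical(mask$data), dims, mask$spacing)
  din <- cpp_edt(as.logical(!mask$data), dims, mask$spacing)
  s <- array(pmin(dout, trunc) - pmin(din, trunc), dims)
  image_volume(s, mask$spacing, mask$origin)
}

mask_moments <- function(mask) {
  idx <- which(mask$data, arr.ind = TRUE)
  w <- voxel_to_world(mask, idx)
  list(centroid = colMeans(w), sd = apply(w, 2, stats::sd))
}

#' Coarse affine alignment of post- to pre-operative lung masks
#'
#' Multiresolution (4x, 2x, 1x) intensity registration on truncated signed
#' distance transforms of the two masks, with a mean-squares metric,
#' initialized from mask centroids and per-axis second moments. Distance
#' transforms give smooth gradients where binary masks do not. The returned
#' transform maps post-operative world coordinates to pre-operative world
#' coordinates and never degrades the Dice overlap below the moment
#' initialization.
#'
#' @param fixed Pre-operative lung [binary_mask()] (non-empty, isotropic).
#' @param moving Post-operative lung [binary_mask()].
#' @param levels Downsampling factors of the pyramid, coarse to fine.
#' @param max_iter Optimizer iteration caps per level.
#' @param sample_cap Maximum number of metric sample points per level.
#' @return An [affine_transform()] (post -> pre) with a `converged` flag.
#' @export
register_affine_masks <- function(fixed, moving, levels = c(4, 2, 1),
                                  max_iter = c(60, 40, 25),
                                  sample_cap = 40000) {
  if (mask_volume(fixed) == 0L || mask_volume(moving) == 0L)
    stop("register_affine_masks: masks must be non-empty")
  stopifnot_isotropic(fixed, "register_affine_masks")
  stopifnot_isotropic(moving, "register_affine_masks")

  mf <- mask_moments(fixed)
  mm <- mask_moments(moving)
  # init maps fixed(pre) coords into moving(post) coords
  s0 <- mm$sd / pmax(mf$sd, 1e-6)
  A0 <- diag(as.numeric(s0))
  t0 <- mm$centroid - A0 %*% mf$centroid

  # parameters: A = A0 + dM (3x3), t = t0 + dt
  par <- rep(0, 12)
  trunc <- 10
  converged <- TRUE

  for (li in seq_along(levels)) {
    f <- levels[li]
    sp <- fixed$spacing[1] * f
    ffix <- if (f > 1) resample_isotropic(fixed, sp) else fixed
    fmov <- if (f > 1) resample_isotropic(moving, sp) else moving
    sdf <- signed_dt(ffix, trunc)
    sdm <- signed_dt(fmov, trunc)
    band <- which(abs(sdf$data) < trunc - 1e-9, arr.ind = TRUE)
    if (nrow(band) > sample_cap) {
      keep <- round(seq(1, nrow(band), length.out = sample_cap))
      band <- band[keep, , drop = FALSE]
    }
    pts <- voxel_to_world(sdf, band)
    target <- sdf$data[band]
    obj <- function(p) {
      A <- A0 + matrix(p[1:9], 3, 3)
      if (det(A) < 0.05) return(1e8)
      tt <- t0 + p[10:12]
      q <- pts %*% base::t(A)
      q <- sweep(q, 2, as.numeric(tt), "+")
      v <- cpp_sample_points(as.numeric(sdm$data), vol_dims(sdm), sdm$spacing,
                             sdm$origin, q, FALSE)
      v[is.na(v)] <- trunc
      mean((target - v)^2)
    }
    res <- stats::optim(par, obj, method = "BFGS",
                        control = list(maxit = max_iter[li], reltol = 1e-7))
    par <- res$par
    if (li == length(levels) && res$convergence != 0) converged <- FALSE
  }

  A <- A0 + matrix(par[1:9], 3, 3)
  tt <- as.numeric(t0 + par[10:12])
  # (A, tt) maps pre -> post; the returned transform is its inverse
  fwd <- affine_transform(solve(A), -solve(A) %*% tt, converged)

  # guarantee: at least as good as the pure moment initialization
  init <- affine_transform(solve(A0), -solve(A0) %*% as.numeric(t0), TRUE)
  ref <- list(dims = vol_dims(fixed), spacing = fixed$spacing, origin = fixed$origin)
  d_opt <- dice(fixed, apply_affine(moving, fwd, ref))
  d_init <- dice(fixed, apply_affine(moving, init, ref))
  if (d_init > d_opt) {
    warning("register_affine_masks: optimization did not improve on moment alignment; returning the initialization")
    return(init)
  }
  if (!converged)
    warning("register_affine_masks: optimizer hit the iteration cap; returning best-so-far")
  fwd
}

as_ref_grid <- function(x) {
  if (inherits(x, "image_volume") || inherits(x, "binary_mask"))
    list(dims = vol_dims(x), spacing = x$spacing, origin = x$origin)
  else x
}

#' Resample a volume or mask under an affine transform
#'
#' Resamples the input onto a reference grid under `t` (post -> pre): the
#' output voxel at pre-operative position `x` takes the input value at
#' `t^{-1}(x)`. Linear interpolation for volumes, nearest for masks.
#'
#' @param x An [image_volume()] or [binary_mask()].
#' @param t An [affine_transform()].
#' @param reference_grid Grid to resample onto: another volume/mask or a
#'   list with `dims`, `spacing`, `origin`. Defaults to the input's grid.
#' @return Same class as `x`, on the reference grid.
#' @export
apply_affine <- function(x, t, reference_grid = NULL) {
  inv <- invert_affine(t)       # errors on singular input
  ref <- if (is.null(reference_grid)) as_ref_grid(x) else as_ref_grid(reference_grid)
  is_mask <- inherits(x, "binary_mask")
  dat <- if (is_mask) x$data * 1.0 else x$data
  bg <- if (is_mask) 0 else -1024
  out <- cpp_resample_affine(as.numeric(dat), vol_dims(x), x$spacing, x$origin,
                             as.numeric(base::t(inv$matrix)), inv$translation,
                             ref$dims, ref$spacing, ref$origin,
                             is_mask, bg)
  out <- array(out, ref$dims)
  if (is_mask) binary_mask(out > 0.5, ref$spacing, ref$origin)
  else image_volume(out, ref$spacing, ref$origin)
}
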