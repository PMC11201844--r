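#' Full pipeline configuration
#'
#' Aggregates every stage parameter with the pipeline's standard defaults
#' (1 mm resampling; -775 HU lung threshold; vessel scale sigma = 3 mm and
#' 95th-percentile threshold inside a 4 mm-eroded lung; 250-voxel tree
#' minimum; Phase I thresholds 0.5 / 0.2 with a 60-voxel surrounding crop;
#' Phase II threshold 0.3 with 3 mm dilation; candidate-radius growth
#' a = 3 with DBSCAN displacement clustering). Every constant is
#' overridable.
#'
#' @param target_spacing Isotropic resampling target (mm).
#' @param lung_sigma,lung_threshold_hu Lung segmentation parameters.
#' @param vessel Vessel filter configuration ([vessel_filter_config()]).
#' @param vessel_erosion_mm Lung erosion before vessel masking (mm).
#' @param tree_min_voxels Strict subvascular-tree voxel minimum.
#' @param phase1_thr_target,phase1_thr_surround,phase1_crop,phase1_gate_mm
#'   Phase I matching parameters.
#' @param phase2_thr,phase2_dilation_mm Phase II matching parameters.
#' @param posterior_cutoff Feature-point retention threshold.
#' @param cpd_beta,cpd_lambda,cpd_w Non-rigid CPD hyperparameters.
#' @param field [field_params()] for the displacement field.
#' @param tumor_hu_floor,tumor_max_lung_fraction Tumor growth parameters.
#' @param localization `"centroid"` (default) aligns the lung-mask centroids
#'   only; `"affine"` adds the full distance-transform refinement of
#'   [register_affine_masks()]. With a resected lung the full-DOF refinement
#'   tends to stretch the post-operative lung over the missing wedge, which
#'   the vessel-based field cannot fully undo in vessel-free regions, so the
#'   conservative initialization is the default; residual rigid offsets are
#'   absorbed by the per-tree CPD alignment.
#' @param seed RNG seed recorded in reports (the core path is
#'   deterministic; only phantom generation consumes randomness).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(target_spacing = 1,
                            lung_sigma = 1, lung_threshold_hu = -775,
                            vessel = vessel_filter_config(),
                            vessel_erosion_mm = 4,
                            tree_min_voxels = 250,
                            phase1_thr_target = 0.5, phase1_thr_surround = 0.2,
                            phase1_crop = 60L, phase1_gate_mm = 30,
                            phase2_thr = 0.3, phase2_dilation_mm = 3,
                            posterior_cutoff = 0.5,
                            cpd_beta = 2, cpd_lambda = 30, cpd_w = 0.3,
                            field = field_params(),
                            tumor_hu_floor = -300, tumor_max_lung_fraction = 0.1,
                            localization = c("centroid", "affine"),
                            seed = 1L) {
  localization <- match.arg(localization)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full margin-quantification pipeline
#'
#' Executes the standard workflow: isotropic resampling, lung segmentation
#' on both scans, affine localization of the post-operative scan onto the
#' pre-operative grid, tumor segmentation (from a seed or a supplied mask),
#' vessel and subvascular-tree segmentation, two-phase tree matching,
#' feature-point extraction, selective-control-point TPS field
#' construction, lung warping, resection-margin measurement, and optional
#' landmark TRE. Post-operative landmark coordinates are mapped through the
#' localization transform automatically.
#'
#' @param pre,post Pre-/post-operative [image_volume()]s or file paths.
#' @param tumor_seed 1-based (z, y, x) voxel index in the resampled
#'   pre-operative volume, or `NULL` when `tumor_mask` is given.
#' @param tumor_mask Optional pre-segmented tumor [binary_mask()].
#' @param landmarks Optional landmark data.frame (see [compute_tre()]) or
#'   CSV path; coordinates in original pre-/post-operative mm space.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for stage artifacts and the JSON/CSV
#'   report.
#' @param verbose Log stage progress to stderr.
#' @return A `pipeline_report` list with all stage outputs and the summary.
#' @export
run_pipeline <- function(pre, post, tumor_seed = NULL, tumor_mask = NULL,
                         landmarks = NULL, config = pipeline_config(),
                         out_dir = NULL, verbose = TRUE) {
  if (is.null(tumor_seed) && is.null(tumor_mask))
    stop("run_pipeline: supply tumor_seed or tumor_mask (configuration error)")
  log_stage <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("[stage:%s] %s", name, conditionMessage(e)), call. = FALSE))
    log_stage("stage %-12s done in %.1f s", name, proc.time()[["elapsed"]] - t0)
    res
  }

  if (is.character(pre)) pre <- read_volume(pre)
  if (is.character(post)) post <- read_volume(post)
  if (is.character(landmarks)) landmarks <- read_landmarks_csv(landmarks)

  pre_r <- stage("resample", resample_isotropic(pre, config$target_spacing))
  post_r <- stage("resample", resample_isotropic(post, config$target_spacing))

  lung_pre <- stage("lungs_pre", segment_lungs(pre_r, config$lung_sigma, config$lung_threshold_hu))
  lung_post0 <- stage("lungs_post", segment_lungs(post_r, config$lung_sigma, config$lung_threshold_hu))

  aff <- stage("localize", if (identical(config$localization, "affine")) {
    register_affine_masks(lung_pre, lung_post0)
  } else {
    mf <- mask_moments(lung_pre)
    mm <- mask_moments(lung_post0)
    affine_transform(diag(3), mf$centroid - mm$centroid)
  })
  ref <- as_ref_grid(pre_r)
  post_loc <- stage("localize", apply_affine(post_r, aff, ref))
  lung_post <- stage("localize", apply_affine(lung_post0, aff, ref))

  tumor <- if (!is.null(tumor_mask)) tumor_mask else
    stage("tumor", segment_tumor(pre_r, lung_pre, tumor_seed,
                                 hu_floor = config$tumor_hu_floor,
                                 cfg = config$vessel,
                                 max_lung_fraction = config$tumor_max_lung_fraction))

  vess_pre <- stage("vessels_pre", {
    v <- segment_vessel_tree(pre_r, lung_pre, config$vessel, config$vessel_erosion_mm)
    # the tumor's own filter response can exceed the vessel threshold; keep
    # it out of the tree decomposition
    v$data[dilate_mm(tumor, 2)$data] <- FALSE
    v
  })
  vess_post <- stage("vessels_post",
                     segment_vessel_tree(post_loc, lung_post, config$vessel, config$vessel_erosion_mm))

  trees_pre <- stage("trees", extract_subvascular_trees(vess_pre, config$tree_min_voxels))
  trees_post <- stage("trees", extract_subvascular_trees(vess_post, config$tree_min_voxels))
  if (length(trees_pre) == 0L || length(trees_post) == 0L)
    stop("[stage:trees] no subvascular trees found", call. = FALSE)

  mres <- stage("match_phase1",
                phase1_match(trees_pre, trees_post, vess_pre, vess_post,
                             config$phase1_thr_target, config$phase1_thr_surround,
                             config$phase1_crop, config$phase1_gate_mm))
  mres <- stage("match_phase2",
                phase2_match(mres, trees_pre, trees_post, vess_pre,
                             config$phase2_thr, config$phase2_dilation_mm))

  fps <- stage("feature_points",
               build_feature_points(mres, trees_pre, trees_post,
                                    config$posterior_cutoff, config$cpd_beta,
                                    config$cpd_lambda, config$cpd_w))

  field <- stage("field", build_displacement_field(fps, tumor, lung_pre, config$field))
  warped_lung <- stage("warp", warp_with_field(lung_post, field))
  margin <- stage("margin", measure_margin(warped_lung, tumor, lung_pre))

  tre <- NULL
  if (!is.null(landmarks) && nrow(landmarks) > 0) {
    lm <- landmarks
    postp <- as.matrix(lm[, c("post_z", "post_y", "post_x")])
    postp <- sweep(postp %*% t(aff$matrix), 2, aff$translation, "+")
    lm$post_z <- postp[, 1]; lm$post_y <- postp[, 2]; lm$post_x <- postp[, 3]
    tre <- stage("tre", compute_tre(lm, field))
  }

  summary_df <- data.frame(
    phase = c("I", "II"),
    total = c(length(trees_post), length(trees_post) - sum(mres$pairs$phase == "I")),
    matched = c(sum(mres$pairs$phase == "I"), sum(mres$pairs$phase == "II")),
    unmatched = c(length(trees_post) - sum(mres$pairs$phase == "I"),
                  length(mres$unmatched_post)))
  report <- structure(list(
    localization = aff, lung_pre = lung_pre, lung_post = lung_post,
    tumor = tumor, vessels_pre = vess_pre, vessels_post = vess_post,
    trees_pre = trees_pre, trees_post = trees_post,
    match = mres, feature_points = fps, field = field,
    warped_lung = warped_lung, margin = margin, tre = tre,
    summary = summary_df, config = config), class = "pipeline_report")

  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  print(x$summary)
  cat(sprintf("  feature point pairs: %d\n", nrow(x$feature_points$post_points)))
  cat(sprintf("  margin: %s\n", x$margin$display))
  if (!is.null(x$tre))
    cat(sprintf("  TRE: %.2f +/- %.2f mm (max %.2f, min %.2f, n = %d)\n",
                x$tre$mean, x$tre$sd, x$tre$max, x$tre$min, x$tre$n))
  invisible(x)
}

#' Write pipeline artifacts and the JSON/CSV case report
#'
#' @param report A `pipeline_report`.
#' @param out_dir Output directory (created if needed).
#' @export
write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(report$lung_pre, file.path(out_dir, "lung_pre.nii.gz"))
  write_volume(report$lung_post, file.path(out_dir, "lung_post_localized.nii.gz"))
  write_volume(report$tumor, file.path(out_dir, "tumor_pre.nii.gz"))
  write_volume(report$vessels_pre, file.path(out_dir, "vessels_pre.nii.gz"))
  write_volume(report$vessels_post, file.path(out_dir, "vessels_post.nii.gz"))
  write_volume(report$warped_lung, file.path(out_dir, "lung_post_warped.nii.gz"))
  write_affine_json(report$localization, file.path(out_dir, "localization.json"))
  write_feature_points_csv(report$feature_points, file.path(out_dir, "feature_points.csv"))
  write_field(report$field, file.path(out_dir, "field"))
  utils::write.csv(report$summary, file.path(out_dir, "matching_summary.csv"),
                   row.names = FALSE)
  j <- list(
    matching = list(pairs = report$match$pairs, summary = report$summary),
    margin = list(distance_mm = report$margin$distance,
                  display = report$margin$display,
                  overlap = report$margin$overlap,
                  point_on_resection = report$margin$point_on_resection,
                  point_on_tumor = report$margin$point_on_tumor),
    n_feature_points = nrow(report$feature_points$post_points))
  if (!is.null(report$tre))
    j$tre <- list(mean = report$tre$mean, sd = report$tre$sd,
                  max = report$tre$max, min = report$tre$min, n = report$tre$n)
  jsonlite::write_json(j, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}
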