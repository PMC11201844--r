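# resectmargin

Quantifies the surgical margin of a sublobar lung resection from a paired
pre- and post-operative chest CT. After a wedge resection or segmentectomy,
the clinically decisive number is the distance from the tumor edge to the
cut surface — but the specimen deforms once removed, and the remaining lung
collapses into the void, so the deformation between the two scans is
discontinuous across the cut. `resectmargin` registers the post-operative
scan back to the pre-operative frame with a deformation field that is
smooth within the remaining tissue yet allowed to jump across the
resection, then reports the margin in the pre-operative frame.

## Method at its core

1. **Subvascular trees.** Both scans are resampled to 1 mm isotropic, lungs
   are segmented at −775 HU, and vessels are enhanced with a single-scale
   Hessian (Frangi) filter (σ = 3 mm), thresholded at the 95th percentile of
   the in-lung response inside the lung eroded by 4 mm. 26-connected
   components above 250 voxels are *subvascular trees*.
2. **Two-phase matching.** Phase I aligns each post-operative tree to
   candidate pre-operative trees with rigid coherent point drift on their
   centerlines and accepts pairs with target Dice ≥ 0.5 and
   surrounding-crop (60³) Dice ≥ 0.2. Phase II places the remaining trees
   by their matched neighbours, dilates by 3 mm, and accepts the best
   pre-operative target at penalized Dice
   `DSCP = DSC / r², r = V₁/V₂ (V₁ ≥ V₂) ≥ 0.3`.
3. **Feature points.** Non-rigid coherent point drift maps each matched
   post-operative centerline onto its pre-operative counterpart, yielding
   control-point pairs.
4. **Selective thin-plate splines.** Every voxel selects control pairs
   within the candidate radius `R = 2·d_max·exp(a·(d/d_max − 1))`
   (`a = 3`, `d` = distance to the tumor centroid), clusters them by DBSCAN
   on their displacement vectors, keeps the cluster nearest the voxel, and
   interpolates with an exact 3D thin-plate spline. Near the tumor the
   field listens only to its own side of the cut and may jump across it.
5. **Margin and error.** The warped post-operative lung mask meets the
   pre-operative tumor mask on one grid; the margin is the closest surface
   distance (sub-voxel values print as `< 1.00 mm`). Landmark target
   registration error (TRE), maximum-intensity-projection slabs and a
   paired t test support evaluation.

No patient data ships with the package: a deterministic phantom generator
builds paired CT volumes (ellipsoidal lungs, six branching vessel trees, a
spherical tumor, a resected wedge with a known margin, a known smooth warp
plus localized collapse) with full ground truth.

## Worked example

```r
library(resectmargin)

spec    <- phantom_spec(seed = 42)          # 160 mm cube, 1 mm voxels
phantom <- generate_phantom(spec)
lm      <- bifurcation_landmarks(phantom, 20)
seedvox <- round(world_to_voxel(phantom$pre, matrix(spec$tumor_center, 1)))[1, ]

report <- run_pipeline(phantom$pre, phantom$post,
                       tumor_seed = seedvox, landmarks = lm)
print(report)
#> <pipeline_report>
#>   phase total matched unmatched
#> 1     I     9       3         6
#> 2    II     6       3         3
#>   feature point pairs: 733
#>   margin: 9.11 mm
#>   TRE: 1.92 +/- 2.44 mm (max 8.02, min 0.12, n = 20)
phantom$true_margin_mm
#> [1] 10
```

Reading: nine post-operative components survive segmentation (six trees
plus fragments sheared off by the wedge); the three intact left-lung trees
match in Phase I, the three right-lung remnants in Phase II, the fragments
stay unmatched. The measured margin (9.11 mm) sits within one voxel of the
constructed 10 mm ground truth, and the mean landmark error of the
recovered field is 1.92 mm.

For real scans, pass NIfTI/NRRD paths (or a DICOM directory) instead of
the phantom volumes and supply the tumor seed or a tumor mask; a thin CLI
wrapper lives at `inst/cli/resectmargin.R`.

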