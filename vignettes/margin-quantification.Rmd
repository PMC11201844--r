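---
title: "Quantifying sublobar resection margins from paired chest CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sublobar resection margins from paired chest CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After a sublobar lung resection (wedge resection or segmentectomy), the
oncological adequacy of the operation hinges on the resection margin: the
shortest distance from the tumor edge to the surgical cut surface. The
specimen is deformed once it leaves the chest, so the margin is best judged
*in situ* by reconstructing the cut surface in the pre-operative frame.
`resectmargin` registers a post-operative chest CT to its pre-operative
counterpart despite the removed tissue, then reports the margin as the
closest 3D distance between the warped post-operative lung boundary and the
pre-operative tumor surface.

The obstacle is that the deformation between the two scans is *not*
continuous: the remaining lung collapses into the void left by the
resection, so the displacement field must be allowed to jump across the cut
while staying smooth elsewhere. A classical interpolating transform fit to
all correspondences (such as a global thin-plate spline) enforces
continuity and smears the jump.

## The model

The pipeline has two core ideas.

**Subvascular-tree matching.** The pulmonary vessel tree is the densest
reliable landmark system in the lung. Both scans are resampled to 1 mm
isotropic, the lungs are segmented (Gaussian smoothing, a fixed -775 HU
threshold, interior connected components, closing and per-slice hole
filling), and vessels are enhanced with a single-scale Hessian
(Frangi-type) filter at sigma = 3 mm, thresholded at the 95th percentile of
the in-lung response and restricted to the lung eroded by 4 mm. The
26-connected components above 250 voxels are *subvascular trees*. Trees are
matched across time points in two phases:

* *Phase I* aligns each post-operative tree to nearby pre-operative
  candidates with rigid coherent point drift (CPD) on their thinned
  centerlines and accepts a pair when the Dice coefficient of the
  transformed masks is at least 0.5 and the Dice of the 60-voxel
  surrounding crops is at least 0.2 (greedy, one-to-one).
* *Phase II* places each still-unmatched post-operative tree at a searching
  center derived from its three nearest matched neighbours, dilates it by
  3 mm, and compares it against the portion of each candidate pre-operative
  tree inside the search mask using the penalized Dice
  `DSCP = DSC / r^2`, `r = V1/V2 (V1 >= V2)`; the best candidate is accepted
  at `DSCP >= 0.3`. Comparing against the *masked portion* (rather than the
  whole component) matters: a post-operative tree is frequently a truncated
  remnant whose volume ratio against the full pre-operative tree would be
  penalized out of reach.

Accepted pairs are turned into control points by non-rigid CPD: the
post-operative centerline is rigidly pre-aligned, mapped onto the
pre-operative centerline, and every confidently mapped point (posterior at
least 0.5) becomes a (post, pre) correspondence.

**Selective-control-point thin-plate splines.** For each voxel a candidate
radius

\[ R = 2\,d_{max}\, \exp\!\big(a\,(d/d_{max} - 1)\big), \qquad a = 3 \]

is computed, where `d` is the distance to the tumor centroid and `d_max`
the furthest distance from the tumor centroid to the lung edge. Control
pairs within `R` are clustered by DBSCAN on their 3D displacement vectors;
the cluster spatially nearest the voxel is kept and an exact-interpolation
3D thin-plate spline (kernel `U(r) = r`) on that subset supplies the
voxel's displacement. Near the tumor the radius is small, so voxels listen
only to their own side of the cut and the field may jump across it; far
away the radius approaches `2 d_max` and the field blends into a global
fit. An `all_points` baseline (one TPS on every pair) is provided to
demonstrate the contrast.

The warped post-operative lung mask and the pre-operative tumor mask then
live on one grid, and the margin is the minimum distance between the tumor
surface and the warped lung surface restricted to within 2 mm of the
resection region (pre-operative lung minus warped lung), with sub-voxel
results reported as "< 1.00 mm". Landmark-based target registration error
(TRE) and a paired t test complete the evaluation toolkit.

## Parameters that matter

| parameter | default | unit | note |
|---|---|---|---|
| resampling target | 1 | mm | all stages assume this grid |
| lung threshold | -775 | HU | fixed; smoothing sigma 1 mm |
| vessel scale sigma | 3 | mm | single Frangi scale |
| vessel percentile | 95 | % of in-lung response | sets the vessel budget |
| lung erosion | 4 | mm | excludes hilar vessels and cut faces |
| tree minimum | 250 | voxels | strict (> 250) |
| Phase I thresholds | 0.5 / 0.2 | Dice | target / surrounding crop |
| Phase II threshold | 0.3 | DSCP | with 3 mm search dilation |
| radius growth `a` | 3 | – | locality of control selection |
| DBSCAN | eps 2 mm, minPts 5 | displacement space | regime separation |
| field stride | 4 | voxels | nearest-upsampled node lattice |
| CPD (feature mapping) | beta 2, lambda 30, w 0.3 | – | see below |

## Numerical and design choices

* **Lung boundary refinement.** Thresholding the smoothed volume at
  -775 HU biases the boundary ~1.4 sigma into the lung (the threshold sits
  far below the lung/soft-tissue midpoint). The smoothed components are
  therefore used only to localize the lungs; the final boundary comes from
  the raw intensities inside a band around them, and a 4 mm closing seals
  the openings where vessels cross the mask boundary (without it,
  hole-filling cannot reclaim vessels that touch the cut face, because they
  connect to the exterior).
* **Tumor core protection.** A single-scale Frangi response at sigma = 3 mm
  does not separate an 8 mm sphere from 3 mm tubes (most tumor voxels
  exceed the vessel threshold). The vessel subtraction inside
  `segment_tumor()` therefore only removes response voxels outside a
  morphological core (opening at 3.5 mm, above the vessel calibre), so
  attached vessels are cut without carving the tumor body. For the same
  reason the pipeline removes the dilated tumor mask from the pre-operative
  vessel mask before tree decomposition.
* **Stiff non-rigid CPD for feature mapping.** After per-tree rigid
  alignment the residual deformation is 1–3 mm. With the conventional
  lambda = 3 the coherent field is floppy enough to stretch a truncated
  post-operative remnant over its pre-operative counterpart's extra
  branches; the feature-mapping step therefore runs at lambda = 30 with
  outlier weight 0.3, and the pre-operative centerline is first cropped to
  the support of the offset-aligned post tree. A local-consensus screen
  (each pair within 4 mm of the median displacement of its 12 nearest
  neighbours) removes residual rogue correspondences. `nonrigid_cpd()`
  itself keeps the conventional defaults.
* **Correspondence on curves.** CPD correspondences on densely sampled
  centerlines can slide tangentially by 1–2 mm (the matching problem is
  ill-posed along a curve); displaced positions remain on the right vessel,
  which is what the TPS consumes. Exact index recovery holds on scattered
  clouds (e.g., bifurcation points).
* **Localization.** The pipeline's default localization aligns lung-mask
  centroids only. The full distance-transform affine refinement
  (`register_affine_masks()`, available via
  `pipeline_config(localization = "affine")`) recovers genuine rigid and
  scale offsets accurately, but on a resected pair the mean-squares metric
  rewards stretching the post-operative lung over the missing wedge; the
  resulting anisotropic bias cannot be undone by vessel control points in
  vessel-free regions near the pleura. Residual rigid offsets are absorbed
  by the per-tree rigid CPD in Phase I.
* **Field evaluation.** The field is evaluated on a stride-4 lattice with
  per-node control selection and nearest upsampling (per-voxel evaluation
  is `stride = 1`). Node fits are cached by their selected subset; each fit
  is capped at the 120 nearest members of the chosen cluster to bound the
  TPS solve. Ties between equally near clusters go to the larger cluster,
  then the lower label. Mask warping is reverse (pull) sampling with the
  field evaluated at the target voxel; the convention matches the TRE
  definition `post + u(post) = pre`.
* **Degenerate inputs.** Coplanar TPS control sets fall back to a ridge
  solve with a warning; collinear CPD inputs are flagged; an empty mask
  surface, zero-variance paired differences, and out-of-slab MIP centers
  raise errors rather than returning silently.

## The synthetic phantom

No patient data ships with the package. `generate_phantom()` draws a
thorax-like body (40 HU) with two ellipsoidal lungs (-850 HU), six
branching vessel trees per pair of lungs (50 HU, radii tapering 3 to
~1.4 mm, one axial slab per tree so the 26-connected decomposition is
unambiguous, stems reaching from the hilum to ~75% of the lung radius), a
spherical tumor (0 HU, 8 mm by default), and white HU noise (sd 5). Surgery
is simulated by removing a lateral wedge that contains the tumor, its cut
face 10 mm from the tumor surface (the ground-truth margin), filling it
with pleura-adjacent soft tissue, and warping the result with a known field:
a 3 mm sinusoidal global warp (wavelengths ~200 mm, emulating respiratory
phase difference) plus a 5 mm collapse pulling tissue toward the cut within
15 mm of it. The post-operative volume is sampled from the resected
pre-operative volume through that field, so masks, bifurcation landmarks,
the displacement field, and the margin are known exactly.

What the phantom does *not* emulate: CT texture and reconstruction
artifacts, airways, lobar fissures, perfusion differences, stapler
artifacts, and vessels thinner than ~1.5 mm. Passing the phantom therefore
demonstrates the pipeline's geometric and algorithmic correctness under
known ground truth — not clinical-grade performance on patient scans, where
segmentation quality and anatomy are far less forgiving.

Problem sizes used by the test-suite: the end-to-end checks run one
160-voxel-cube phantom pair (the stated study conditions) plus compact
120-voxel-cube variants for unit-level checks; the acceptance script runs
the 160-cube pipeline once.

## Known limitations

* The margin is a minimum statistic over thousands of surface voxels: a
  single local field error sets it. Across phantom seeds the measured
  margin stays within roughly ±3 mm of truth (±2 mm at the default
  conditions); errors concentrate at the cut face, where the 4 mm lung
  erosion removes the very vessels that would witness the collapse peak.
* Severely bent remnants (surgical suturing) fall below the Phase II
  similarity threshold and stay unmatched, as intended — the field near
  them then relies on neighbouring trees.
* The deformation model has no boundary conditions on the pleural surface;
  in vessel-free regions the field is an extrapolation.
* Localization by centroids assumes the two scans share patient
  orientation (supine chest CT); gantry tilt and decubitus acquisitions
  are out of scope.
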