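Package: resectmargin
Title: Resection-Margin Quantification from Paired Pre- and Post-Operative Chest CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Registers a post-operative thoracic CT scan to its pre-operative
    counterpart in the presence of a surgically removed lung region, and
    quantifies the resection margin as the closest three-dimensional distance
    between the warped post-operative lung boundary and the pre-operative
    tumor surface. The pipeline segments lungs, tumor and the pulmonary vessel
    tree, decomposes the vessels into subvascular trees, matches trees across
    time points with a two-phase Dice / penalized-Dice scheme driven by
    coherent point drift, and builds a thin-plate-spline displacement field
    from per-voxel selectively chosen control points (candidate-radius rule
    plus DBSCAN displacement clustering) so the field may be discontinuous
    across the resection. Includes a deterministic synthetic CT phantom
    generator with ground-truth masks, deformation field and landmarks, plus
    target-registration-error and margin evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
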