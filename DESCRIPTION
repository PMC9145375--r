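Package: meshfair
Title: Fairing of Stair-Stepped Surface Meshes from Anisotropic Medical Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for smoothing closed triangle meshes reconstructed from
    undersampled, anisotropic binary segmentations, where stacked thick
    slices produce stair-step artifacts. Implements five fairing algorithms
    (uniform Laplacian, Laplacian with volume-compensating pre-dilation,
    scale-dependent Laplacian, cotangent mean-curvature flow with explicit
    and implicit integration, and inverse-distance weighted Laplacian)
    behind a common iteration driver, together with quantitative validation
    metrics (relative volume difference, vertex-sampled symmetric Hausdorff
    distance, per-vertex distance fields exportable as heat maps), synthetic
    voxel phantoms of small bone-like objects, and mesh/mask readers and
    writers (STL, PLY, OBJ, NIfTI).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
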