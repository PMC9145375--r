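# meshfair

Fairing of stair-stepped surface meshes from anisotropic medical
segmentations.

## The problem

Surface models of small bones (carpals, tarsals, vertebral processes) are
built by stacking thick-slice binary segmentations: in-plane voxels are
sub-millimetre, but slabs are often 2 mm or more. The stacked surface shows
terrace-like **stair-step artifacts**, while the objects themselves are tiny
(order 10³ mm³) and carry high-curvature ridges that are anatomically
meaningful. Naive smoothing removes the terraces but also shrinks the
enclosed volume and erodes the ridges, corrupting downstream morphometry and
kinematics.

`meshfair` is for researchers and image-analysis engineers who need to
smooth such meshes *and quantify what the smoothing did*. It provides:

- **Five fairing algorithms** behind one Jacobi iteration driver:
  - **M1** uniform Laplacian (umbrella operator):
    `p ← p + λ (mean(neighbors) − p)`;
  - **M2** Laplacian with volume-compensating pre-dilation: inflate by a
    solved normal offset `α` to +5 % volume, smooth until the volume is
    back within 0.5 % of the original, a vertex crosses into the original
    surface (winding-number contact test), or an iteration cap reports
    non-convergence;
  - **M3** scale-dependent Laplacian:
    `U(pᵢ) = (2/E) Σⱼ (pⱼ − pᵢ)/|eᵢⱼ|`, `E = Σⱼ |eᵢⱼ|`;
  - **M4** cotangent mean-curvature flow:
    `−κ̄n = (1/4A) Σⱼ (cot αⱼ + cot βⱼ)(pⱼ − pᵢ)` with explicit-normalized
    or implicit backward-Euler integration;
  - **M5** inverse-distance weighted Laplacian: `ωⱼ = |pᵢ − qⱼ|⁻¹`,
    normalized per ring.
- **Validation metrics**: signed relative volume difference
  `RVD = (V_S − V_G)/V_G · 100` from exact divergence-theorem mesh volumes,
  vertex-sampled symmetric Hausdorff distance with exact point-to-triangle
  distances, mean/SD/RMS/max per-vertex distance statistics, and PLY/CSV
  heat-map export.
- **Synthetic phantoms**: analytic bone-like shapes (ellipsoid,
  superellipsoid, seeded ridged blob) voxelized at anisotropic spacing with
  exact reference volumes, plus stair-step (voxel-face) and
  marching-tetrahedra surface extraction.
- **I/O**: STL (ASCII/binary), PLY (ASCII/binary, per-vertex scalar), OBJ,
  NIfTI masks; strict manifold validation, vertex welding and orientation
  fixing at the boundary.
- **A command-line tool** (`inst/scripts/meshfair`) with `phantom`,
  `smooth`, `evaluate` and `compare` subcommands, run manifests and
  classified exit codes.

## Worked example

Generate a stair-stepped phantom in the published carpal-bone size range,
smooth it with the scale-dependent Laplacian, and quantify the result:

```r
library(meshfair)

phantom <- generate_phantom("ridged_blob", seed = 1)
phantom
#> voxel_phantom: ridged_blob, grid 41 x 41 x 14, spacing (0.5, 0.5, 2.0) mm
#>   occupied voxels: 1833 (volume 916.5 mm^3)
#>   analytic volume: 906.013 mm^3

ground <- extract_surface(phantom, mode = "voxel")   # raw stacked-slice look
res <- smooth_mesh(ground, smooth_config("M3"))      # scale-dependent, 30 iters
res
#> smooth_result: M3, 30 iteration(s), termination: iterations
#>   volume 916.5 -> 878.464 mm^3 (-4.15%)

hausdorff_distance(ground, res$mesh)
#> Hausdorff distance: 0.65942 mm (G->S 0.65942, S->G 0.324856)
#>   pooled per-vertex distances: mean 0.19062, SD 0.156442, RMS 0.246597, max 0.65942 mm
```

The phantom's voxel volume (916.5 mm³) sits within ~1 % of the analytic
shape volume (906.0 mm³) — the voxelization error at this spacing — and the
stair-step mesh encloses the voxel volume *exactly*. After 30 scale-dependent
iterations the volume has shrunk by only 4.15 % and no vertex has moved more
than 0.66 mm.

Comparing all five methods under one shared default configuration:

```r
tab <- compare_methods(ground)
tab[, c("method", "rvd", "hausdorff", "mean", "rms", "termination")]
#>   method    rvd hausdorff  mean   rms termination
#> 1     M1 -28.09     1.513 0.550 0.646  iterations
#> 2     M2   2.72     0.544 0.130 0.173     contact
#> 3     M3  -4.15     0.659 0.191 0.247  iterations
#> 4     M4 -11.37     0.902 0.285 0.347  iterations
#> 5     M5 -22.10     1.310 0.450 0.541  iterations
```

Plain Laplacian smoothing (M1) loses 28 % of the volume in 30 iterations;
the scale-dependent variant (M3) loses 4 %; curvature flow (M4) and
inverse-distance weighting (M5) fall in between; pre-dilation (M2) shows the
smallest volume change and here terminated by the surface-contact rule in
its first iteration (see the methods vignette for why severely terraced
surfaces trigger contact immediately).

The same pipeline is available from the shell:

```sh
meshfair phantom --shape ridged_blob --seed 1 --out-mesh ground.stl
meshfair smooth  --method scaledep --input ground.stl --output smooth.stl
meshfair evaluate --ground ground.stl --smoothed smooth.stl \
    --report report.json --heatmap hd
meshfair compare --ground ground.stl --table table.csv
```

Every run writes a JSON manifest echoing the fully resolved configuration;
`--heatmap` exports per-vertex distance fields as PLY (`quality` property)
plus CSV for rendering.

## Vignette

`vignettes/mesh-fairing-methods.Rmd` documents the model assumptions, every
tunable parameter with its default and rationale, the stability
normalizations applied to the scale-dependent and cotangent operators, what
the phantom generator does and does not emulate, and known limitations.
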