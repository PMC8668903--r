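# sbfmorph

Quantitative analysis of 3D label volumes from serial block-face scanning
electron microscopy (SBF-SEM) of tumour tissue — for microscopists and
image analysts who have (or want to simulate) a segmented stack and need
the downstream numbers: volumes, orientations, convergence, and
vascular-distance statistics.

SBF-SEM produces intrinsically aligned serial sections with anisotropic
voxels (e.g. 15 × 15 × 100 nm). Starting from a flat integer label volume
plus a segment table (label → class, with nucleus/mitochondrion labels
parented to their cell), the package provides:

* **I/O** — multi-page TIFF stacks and label volumes, CSV segment and
  measurement tables, JSON run manifests; voxel spacing is explicit, never
  read from TIFF tags.
* **Pre-processing** — cropping and slice-wise z-score normalization to
  8 bit (per slice: `z = (v − μ)/σ` clipped at ±3σ, mapped to 0..255).
* **Label propagation** — coarse-to-fine variational optical flow between
  neighbouring sections carries labels drawn on 1 slice in 10 through the
  stack (`propagate_stack()`).
* **Morphometry** — volumes, centroids, boundary-completeness flags, and
  per-cell composition with the cytoplasm derived as cell − nucleus.
* **Orientation** — per-structure main axes by PCA of voxel coordinates in
  physical units, and the best alignment plane of a bundle of unsigned
  axes: the unit normal minimizing `Σᵢ (n·aᵢ)²`, solved exactly by
  eigen-decomposition of `M = Σᵢ aᵢaᵢᵀ`; inclination angles
  `θᵢ = asin(|n·aᵢ|)` and their 10° histogram.
* **Polarity** — virtual rays along each cell's main axis with a radial
  falloff (1 on the axis, 0 at the ray radius), voxel-wise accumulation, a
  strict-threshold hot spot (largest 26-connected component above 3.5
  a.u.), and the polarized-cell subset whose rays reach it.
* **Spatial statistics** — exact anisotropic Euclidean distance transform
  to the capillary, surface-to-surface structure distances, and Spearman
  correlations (mid-ranks; exact permutation p for n ≤ 9, t-approximation
  above; significance at p < 0.05).
* **Synthetic scenes** — a generator of tumour-like label volumes with
  complete ground truth (ellipsoidal cells with concentric nuclei and
  cytoplasmic mitochondria, a tubular capillary, plane-aligned or
  hotspot-convergent axis models, a cell-size gradient with capillary
  distance, and EM-like renderings with texture, noise and recorded
  jitter), so every stage is testable as parameter recovery.

See `vignettes/sbfmorph-methods.Rmd` for the models, conventions and
numerical choices.

## Worked example

Generate a 21-cell scene around a capillary with a size–distance gradient,
then run the full analysis:

```r
library(sbfmorph)

cfg <- scene_config(
  dims = c(128, 128, 48), spacing = voxel_spacing(300, 300, 400),
  n_cells = 21, cell_radius_mean = 2, cell_radius_sd = 0.25,
  mito_per_cell = c(5, 8), size_distance_beta = 0.5, interior_only = TRUE,
  capillary = capillary_spec(c(3, 0, 9.6), c(3, 38.4, 9.6), 2),
  seed = 601)
scene <- generate_scene(cfg)
scene
#> synthetic scene: 21 cells, 180 labelled structures, model 'isotropic'
#> label volume 128 x 128 x 48, 180 labels
#> voxel spacing: 300 x 300 x 400 nm

res <- analyze_scene(scene$labels, scene$segments,
                     ray = ray_params(radius_um = 3))
res$histogram
#> inclination histogram (10 deg bins 0..90):
#>   7 6 5 1 0 1 0 1 0
#>   n = 21, share 0-20 deg = 0.619

subset(res$correlations, var_x == "distance_to_capillary")
#>                    var_x     var_y  n        rho      p_value significant
#> 7  distance_to_capillary      cell 21 -0.7883117 2.190892e-05        TRUE
#> 8  distance_to_capillary cytoplasm 21 -0.7974026 1.500155e-05        TRUE
#> 9  distance_to_capillary   nucleus 21 -0.7922078 1.866840e-05        TRUE
#> 10 distance_to_capillary      mito 21 -0.2728765 2.313904e-01       FALSE
#> 11 distance_to_capillary  nc_ratio 21 -0.2025974 3.784517e-01       FALSE

round(mean(res$cells$nucleus_volume_um3 / res$cells$cell_volume_um3), 3)
#> [1] 0.319
```

The distance correlations show the built-in gradient: cells near the
capillary are larger, and the effect carries to cytoplasm and nucleus
volumes, while the nucleocytoplasmic ratio stays uncoupled. The recovered
nuclear volume fraction matches the generator's 0.32. Under the isotropic
axis model the inclination share at 0–20° is unremarkable; with
`orientation_plane()` or `orientation_hotspot()` the same pipeline recovers
the alignment plane and the aimed-cell subset (see the test suite).

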