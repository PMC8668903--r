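---
title: "Quantifying 3D tumour architecture from serial block-face EM label volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D tumour architecture from serial block-face EM label volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbfmorph)
```

## The problem

Serial block-face scanning electron microscopy (SBF-SEM) images a resin block
by alternately cutting an ultrathin section and scanning the freshly exposed
face. The result is an intrinsically aligned stack with fine lateral
resolution (tens of nm) and a coarser axial step equal to the cutting
thickness (~100 nm) — enough to reconstruct every cell, nucleus and
mitochondrion in tens of picolitres of tumour tissue. Turning those stacks
into biology requires a chain of quantitative steps: normalizing the raw
sections, propagating sparse manual segmentations through the stack,
measuring the labelled structures, and asking organizational questions —
do the cells align in a common plane, do their axes converge on a common
target, does cell size vary with distance to the blood supply?

`sbfmorph` implements that chain for flat integer label volumes (one 3D
grid of label ids plus a segment table assigning each id a class and, for
organelles, an owning cell). Because raw tumour stacks of this kind are
rarely publicly deposited, the package is built around a synthetic scene
generator with complete ground truth, so that every stage can be validated
as parameter recovery rather than by eye.

## Coordinate and unit conventions

Voxels are indexed 0-based as `(ix, iy, iz)`; the physical position of a
voxel is its **centre**, `((ix + 0.5) dx, (iy + 0.5) dy, (iz + 0.5) dz)`,
with the spacing `(dx, dy, dz)` in nanometres and all reported measurements
in micrometres. Centre-based positions keep centroids and inter-structure
distances unbiased under voxelization. Spacing is always explicit input:
TIFF tags encode resolution too inconsistently across exporters to be
trusted.

## Slice normalization

SBF-SEM contrast drifts slowly along the cutting axis, so each section is
standardized independently: per slice, `z = (v - mean) / sd` (population
sd), clipped to ±`clip_sigmas` (default 3), mapped affinely onto 0..255 and
rounded half-away-from-zero. The slice mean therefore always maps to grey
128, and hot pixels cannot compress the usable contrast range. The clip
value and the 8-bit transfer function are this package's choices — slice-wise
z-scoring itself does not pin them down. A constant slice has no contrast to
normalize and maps to 128 with a warning.

## Optical-flow label propagation

Manually segmenting every section is prohibitively slow; labels drawn on one
slice in `stride` (default 10) are carried through the stack. Dense 2D
displacement fields between neighbouring sections are estimated with a
coarse-to-fine variational solver of the Horn–Schunck family: a quadratic
brightness-constancy data term plus a quadratic smoothness term with weight
`smoothness_weight` (default 15 on 0–255 grey values), solved by Jacobi
iterations with incremental warping (`warp_iterations` relinearizations per
pyramid level, 3 levels by default, capped so the coarsest image stays at
least 8 px wide).

The flow convention is chosen to match label warping exactly: the field `u`
moves content from source to target, and the warped label at pixel `p` is
the source label at `p - u(p)`, sampled nearest-neighbour because labels are
categorical; samples falling outside the slice become background. Each
unannotated slice receives labels chained slice-by-slice from its **nearest
annotated** slice (lower index on ties, for determinism). Chaining short
flows was preferred over long-range flow because EM content decorrelates
within a micrometre or two of depth. Propagation is single-source: no
blending of the two flanking annotated slices is attempted, which keeps the
label set of the output a subset of the input's. On identical neighbouring
slices the data term vanishes identically, the solver returns exactly zero
flow, and static content is reproduced bit-exactly.

## Morphometry and completeness

Volume is voxel count × `dx dy dz` (converted to µm³); centroids are means
of voxel centres. Because the flat label volume stores the most specific
label per voxel, a cell's full extent is its own label unioned with the
labels parented to it. The cytoplasm is derived, not segmented: cell minus
nucleus (published compartment volumes are consistent with this convention
to rounding, e.g. 657.1 + 313.6 ≈ 970.6 µm³). Mitochondria are accounted to
the cytoplasm compartment.

A structure is **complete** when none of its voxels lies on one of the six
stack faces — the simplest testable reading of "entirely segmented". Two
filters mirror the two published analysis populations: orientation analyses
keep every cell whose **nucleus** is complete (a cut cell still has a
meaningful axis), while volumetric and distance analyses keep cells whose
own mask *and* nucleus are complete. Whether mitochondrial completeness
should also be required is not decidable from the source analyses; it is
not required here.

## Orientation: main axes and the alignment plane

The main axis of a structure is the leading eigenvector of the covariance
of its voxel-centre coordinates in physical units. Axes are **unsigned**
(`a` and `-a` are the same axis); the canonical representative has its
first nonzero component positive. When the top two eigenvalues tie the
axis is meaningless and is flagged ambiguous rather than guessed.

The alignment plane of a bundle of axes is formalized as the unit normal
`n` minimizing `sum_i (n . a_i)^2` — the axial least-squares problem, whose
exact solution is the eigenvector of the smallest eigenvalue of
`M = sum_i a_i a_i^T`. This reduces to the verbal "least-squares plane
through the main axes" description and is equivalent to minimizing the
summed squared sines of the inclination angles
`theta_i = asin(|n . a_i|)`. The fit is unweighted — nothing in the source
analyses indicates weighting by size or elongation — and uses only cells
with a complete nucleus; nucleus and capillary axes are *scored* against
the plane but never enter the fit. Histograms use nine 10° bins with the
0–20° share computed inclusively.

## Polarity: virtual-ray convergence

Each cell emits a virtual ray: the infinite line through its centroid along
its main axis, in both directions, clipped only by the volume. Voxels
within the ray radius receive an intensity given by a radial falloff with
value 1 on the axis and 0 at the radius. The published description of the
profile is self-contradictory if read literally (intensity "proportional
to" distance yet maximal on the axis); it is implemented here as the linear
decay `1 - d/radius` and exposed as a pluggable monotone function. Each
cell contributes at most its single footprint value per voxel, so the
accumulated map reads as a weighted count of converging cells and the
threshold 3.5 means "more than 3.5 cells' worth" of convergence. The hot
spot is the largest 26-connected component of strictly suprathreshold
voxels, and a cell is polarized when its ray reaches that region with
positive intensity.

The default radius is 15 µm, the published value for acquisition-scale
stacks roughly 70 µm across. The radius is a resolution parameter of the
analysis, not a constant of nature: on the desk-scale synthetic scenes
(38.4 µm wide) the recovery analyses use 3 µm, sitting between the aimed-ray
dispersion (15 µm × tan 5° ≈ 1.3 µm) and the typical miss distance of
unaimed rays (~10 µm), which is what makes aimed and unaimed cells
distinguishable at that scale.

## Capillary distance and rank statistics

Distances to the capillary use an exact anisotropic Euclidean distance
transform between voxel centres (separable lower-envelope algorithm), in
micrometres. The primary per-structure distance is the minimum of the map
over the structure's voxels (surface-to-surface proximity); the map value at
the centroid voxel is kept as a secondary sensitivity column.

Correlations are Spearman's rho on mid-ranks. The two-sided p-value uses
the exact permutation distribution for n ≤ 9 (all n! orderings) and the
t-approximation `t = rho sqrt((n-2)/(1-rho^2))` otherwise — at the n = 21
typical of complete-cell populations, exact enumeration is infeasible and
the t-approximation is standard, though it differs in the last digits from
some commercial implementations. Significance is declared at p < 0.05 with
no multiple-testing correction, reproducing the original decision rule.
Simulation places the realized type-I error of this rule at n = 21 within a
few thousandths of 0.05 and its power against a population rho of -0.6
above 0.8 (see `scripts/acceptance.R`).

## The synthetic scene generator

The generator emulates the features of the tissue that the analyses are
sensitive to, with full ground truth:

* **Cells** are ellipsoids with aspect ratio drawn from [1.5, 3], so the
  major axis is well defined and the PCA axis has an exact analytic oracle.
  The volume-equivalent radius is Gaussian (default 3 ± 0.4 µm at the
  default desk scale).
* **Nuclei** are concentric ellipsoids holding `nucleus_volume_fraction`
  of the cell volume (default 0.32, the composition observed in
  hepatoblastoma tissue). By construction a nucleus shares its cell's
  orientation exactly — nucleus inclination statistics therefore duplicate
  the cell statistics on synthetic scenes, whereas real nuclei decouple
  partially from cell shape.
* **Mitochondria** are small spheres (0.25–0.45 µm radius) confined to the
  cytoplasm, 20–40 per cell at desk scale — an order of magnitude below
  real counts (200–400), keeping label counts tractable.
* **The capillary** is a straight tube; cells are placed by sequential
  rejection sampling (1000 attempts each, then an error advising smaller
  `n_cells`) with bounding-sphere separation, which guarantees voxel-wise
  disjointness from other cells and the capillary.
* **Orientation models**: isotropic; plane-aligned with a wrapped-normal
  out-of-plane tilt of sd `sigma_deg` (the tilt *is* the inclination, so
  the expected 0–20° share is the closed-form normal mass, ≈0.76 at
  σ = 17°); and hotspot, aiming a fixed fraction of cells at a common
  point with wrapped-normal angular error.
* **Size–distance coupling**: with `size_distance_beta > 0` the mean cell
  radius falls linearly with normalized capillary distance, giving the
  negative volume–distance correlation seen in tissue.
* **Placement**: by default uniform over the volume, with boundary-touching
  cells marked incomplete in the truth; `interior_only = TRUE` keeps every
  cell clear of the faces, for recovery experiments that need the full
  cell count in the fit.

The default desk-scale grid is 256 × 256 × 64 voxels at 150 × 150 × 300 nm
(38.4 × 38.4 × 19.2 µm): the physical formulas are scale-free and
acquisition-scale grids (~4700² px) are not desk-scale. The EM renderer
composes per-class base greys, blockwise texture inside structures (so the
flow has something to track), optional recorded per-slice jitter and
Gaussian noise; it makes no attempt at real EM contrast physics, membranes
or organelle ultrastructure. Consequently, passing recovery tests show that
the *geometry pipeline* is correct under known conditions — they do not
certify segmentation quality on real EM texture.

## Numerical choices

* Degenerate PCA (tied leading eigenvalues) and degenerate plane fits
  (tied smallest eigenvalues) are flagged, with ties broken by canonical
  eigen ordering and the sign rule.
* The distance transform replaces infinity with a large finite sentinel so
  parabola intersections stay well defined; the result is exact to floating
  point (verified against O(N²) search).
* Constant slices: z-scoring maps them to 128 with a warning; the flow
  solver returns zero flow with a warning.
* Rounding to 8 bit is half-away-from-zero, making the map monotone and
  reproducible across platforms.
* Exact Spearman permutation p-values switch to the t-approximation above
  n = 9 (9! ≈ 3.6 × 10⁵ orderings is the practical enumeration limit).

## Problem sizes used by the test-suite and acceptance script

Recovery experiments run on 128 × 128 × 48 grids at 300 × 300 × 400 nm
(the same 38.4 × 38.4 × 19.2 µm of tissue as the default scene, coarser
voxels): 20 plane-aligned scenes of 50 cells (σ = 10°), four scenes of 60
cells (σ = 17°) for the inclination share, hotspot scenes of 40 cells with
15 aimed (σ = 5°, radius 3 µm, threshold 3.5), translating-disk stacks of
30 slices at stride 10, and 2000/200 replicates for the significance-rule
calibration and power at n = 21. These sizes were chosen so the entire
validation runs on a laptop in minutes while keeping every statistical
band meaningful.

## Known limitations

* No inter-slice rigid alignment: stacks are assumed aligned upstream
  (jittered synthetic stacks exist to exercise the flow, not to test
  registration).
* No deep-learning segmentation; mitochondria labels are taken as given.
* Propagation is single-source nearest-slice; bidirectional blending could
  reduce drift on long chains but would break the simple label-subset
  invariant.
* The hot spot is the single largest suprathreshold component; no
  multi-hotspot ranking is attempted, and identifying the hot spot with an
  anatomical structure is biology outside the package's scope.
* No surface-area, sphericity or spherical-statistics (Rayleigh/Bingham)
  metrics.
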