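---
title: "Berry detection and bunch architecture traits from 3D point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Berry detection and bunch architecture traits from 3D point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bunch3d)
```

## The measurement problem

Grapevine breeders select against dense bunches because tightly packed
berries favour *Botrytis* bunch rot. The traits that describe bunch
architecture — berry number, berry diameter and volume, bunch length,
width, and the volume of the whole bunch envelope — are classically
measured destructively: every berry is removed and imaged, which costs
about ten minutes of manual work per bunch. A structured-light scanner
produces a dense 3D point cloud of the intact bunch in about a minute,
but turns the measurement problem into a detection problem: individual
berries must be found in an unstructured point set that also contains
rachis, pedicels, the mounting hook, and — in the field — only the
visible side of the bunch.

`bunch3d` implements that detection pipeline and the trait extraction on
top of it. Berries are modelled as spheres; this is the central modelling
assumption. Real berries are slightly prolate and deform where they press
against each other, so fitted radii are an effective spherical radius,
and contact flattening is one reason detected diameters can deviate a few
tenths of a millimetre from caliper truth.

## Pipeline and parameters

### Downsampling

The raw scans are far denser than the geometry requires. The cloud is
reduced on a cubic voxel grid: every point is binned by
`floor(coordinate / resolution)` per axis (grid anchored at the origin)
and each occupied voxel is replaced by the centroid of its points.
The binning rule makes the operation deterministic and order-independent,
and it is idempotent at fixed resolution. The working resolution default
is **0.4 mm**: fine enough that a 5 mm berry still carries several
hundred surface points, coarse enough to keep RANSAC costs low. The same
length reappears as the detector's inlier band, so "one voxel of surface
jitter" is the unit of geometric slack throughout.

### Normals and curvature

Region growing needs per-point surface normals, which scanner PLY files
do not always carry. They are estimated by local PCA: the normal is the
eigenvector of the smallest eigenvalue of the covariance of the k = 30
nearest neighbours (plus the point itself), and the curvature score is
λ_min / (λ₁+λ₂+λ₃) — 0 on a plane, 1/3 for isotropic noise. Because no
sensor viewpoint is stored in the files, normals are oriented away from
the local neighbourhood centroid, which points outward on convex berry
surfaces; the segmentation criterion additionally uses the absolute value
of the normal dot product so residual orientation flips cannot split a
smooth region.

### Region growing

Seeds are processed in ascending (curvature, index) order — flattest
points first, with the index as a total tie-break, so the partition is
exactly reproducible. A neighbour (kNN graph, k = 30) joins the current
region when the angle between its normal and the recruiting point's
normal is at most **15°**, and continues to propagate the front only
while its curvature stays ≤ **0.05**. The defaults were chosen so that a
noiseless sphere at the working point density forms a single region
(adjacent-point normal angles there are ≈ 5–8°) while the high-curvature
creases between touching berries stop growth. Regions smaller than
**50** points are reported as unassigned: stem fragments produce small
rough patches, and the detector's 100-supporter gate would reject them
anyway. Segmentation does not need to be perfect — one region per berry
is the common case, but a region holding several berries is handled by
iterative fitting, and a berry split across regions by overlap
suppression.

### RANSAC sphere detection

Within each region, up to **1000** minimal samples of four points are
drawn per RANSAC run; each sample yields a sphere by solving the 4×4
linear system of the algebraic sphere equation
|p|² = 2p·c + (r² − |c|²) (coplanar samples are degenerate and skipped,
as are radii outside the gates). Hypotheses are scored by the number of
points within **0.4 mm** of the surface; the best one is refined by
algebraic least squares on its inliers, and inliers are recounted once.
A model is accepted only if the refined radius lies in **[1, 9] mm** and
the supporter count reaches **100** — the gates used for dense bunch
scans, where a 9 mm radius cap comfortably contains observed berry
diameters up to ~17 mm. Accepted inliers are removed from the region and
the search repeats until fewer than 100 points remain or no model is
found, which resolves undersegmented regions into their constituent
berries. The per-region random streams are derived deterministically from
the analysis seed, so identical inputs yield identical models.

Duplicate detections from oversegmentation are suppressed greedily:
models ranked by inlier count (ties: larger radius, then lexicographic
center), and a candidate is dropped when its overlap with any accepted
model exceeds **25%**. Overlap is the closed-form sphere–sphere lens
volume normalised by the smaller sphere's volume: a small spurious sphere
buried inside a true berry reaches the bar quickly, which is exactly the
duplicate case the step exists for. The greedy-by-support order is the
standard non-maximum-suppression reading of pairwise "keep the one with
more inliers", which by itself is ambiguous on overlap chains.
Erroneous spheres near the mounting hook are deliberately *not* removed
by hand; the hook fixture of the generator quantifies their effect
instead (at most a couple of spurious models per bunch in the hook
robustness test).

### Traits

Berry number, mean diameter (2r̄), mean and total sphere volume
(4/3 πr³, exported in mL, 1 mL = 1000 mm³) follow directly from the
accepted models. The convex-hull volume is computed over the union of all
models' inlier points with the package's own quickhull; it measures the
whole bunch envelope, including inter-berry space, and therefore always
exceeds the total berry volume on fully sampled bunches. Bunch length is
the vertical (y) extent spanned by the detected berries — the two
vertically most distant berries, following the OIV 202 convention — and
width the larger of the analogous x and z extents. Extents use
center ± radius rather than raw point extrema so that hook and stem
points cannot inflate them; whether the original instrument used centers
or extents is not documented, and the choice only shifts both modes by
about one berry radius.

### Compactness factors

The factor module evaluates arithmetic expressions over the seven traits
and rank-correlates them with visual OIV 204 classes (1 = very loose …
9 = very dense) using Spearman's rho with average ranks — ties are
pervasive with five class levels. The shipped defaults are volume/extent
ratios (e.g. total volume over length × width); they are the package's
own working interpretations of that family of indices, clearly not
verbatim published formulas, and the registry is configurable from plain
text so users can supply their own. On synthetic bunches whose packing
parameter defines true compactness, the volume/extent factor tracks the
class binning with rho well above 0.6; this shows the machinery works,
not that any particular factor is the right field index.

## The synthetic generator

The generator is the validation backbone: it produces clouds with known
per-berry truth. Its defaults describe one fixed, realistic study
condition and are not tuned per test:

* **Radii** uniform in 4.6–8.45 mm — berry diameters of 9.2–16.9 mm, the
  range observed across a diverse breeding population.
* **1000 points per berry** and **σ = 0.1 mm** isotropic Gaussian noise —
  surface density comparable to a 0.4 mm mesh and sub-millimetre sensor
  noise, a quarter of the inlier band.
* **100 berries** on a **140 mm** rachis at **compactness 0.9**; berry
  centers are placed around the vertical axis and relaxed pairwise until
  no two are closer than (2 − compactness)(rᵢ + rⱼ), so 1.0 means
  touching berries and smaller values looser bunches. (Packing that
  cannot satisfy the rule on the given rachis fails loudly rather than
  silently loosening.) Deformation of berries pressed against each other
  is *not* modelled; compactness 1 is the densest generated condition.
* **Stem points on** (rachis and pedicel cylinders at berry-comparable
  surface density), **hook off** — the hook is a lab-mounting artifact,
  enabled explicitly in the hook-robustness test.
* **Partial scans** remove back-facing points (surface normal pointing
  away from the camera) and points whose ray to the camera passes
  through another berry. This reproduces the visibility structure of
  single-side field scans cheaply; it does not simulate sensor tracking
  loss, wind motion or background clutter.

Dense-bunch fixtures for the partial-scan comparisons use 60 touching
berries on a 60 mm rachis — a multi-layered bunch whose rear layer is
genuinely hidden from a single viewpoint. On such fixtures the detected
count from a partial scan is close to half the 360° count, mirroring
field experience, and the mean detected diameter differs only at the
group level by a few tenths of a millimetre (partial scans see slightly
more of the large, outer berries).

What passing these tests shows — and what it does not: the pipeline
recovers spherical berries from noisy, occluded, cluttered point sets
with the stated gates, deterministically, and its geometric primitives
match independent oracles (analytic sphere truth, Monte-Carlo overlap
integration, brute-force ranking, an external qhull). It does not show
that real berries are spheres, that scanner noise is isotropic Gaussian,
or that any compactness factor reproduces a particular published
correlation with OIV 204 on a real progeny.

## Numerical choices and degenerate inputs

* Minimal-sample and least-squares sphere solvers use Gaussian
  elimination with partial pivoting; pivots below 1e-10 flag the sample
  as coplanar/cocircular, a normal RANSAC outcome rather than an error.
* The quickhull visibility epsilon is 1e-10 of the bounding-box extent;
  fewer than four points, collinear or coplanar sets give hull volume 0
  with a warning.
* Empty model lists yield all-zero traits; clouds smaller than k+1 points
  skip detection and return zeroed analyses.
* PLY I/O writes coordinates as doubles, so binary round trips are
  bit-exact; big-endian files are rejected explicitly rather than
  misparsed.
* All stochastic steps (generator, RANSAC) are seeded; batch runs derive
  a per-file stream from the master seed and the file name, so adding a
  file to a folder does not change the other results.

## Problem sizes used in the shipped validation

The test-suite and acceptance-script fixtures use bunches of 20–300
berries (clouds up to ~3·10⁵ points), 50 analytic spheres for the
sphere-fit check, 10⁷ Monte-Carlo samples per overlap case, and 20
matched full/partial scan pairs; these sizes keep the whole validation
in the minutes range on a single CPU while leaving each property's
signal far above its noise floor.

## Known limitations

* Interior berries are invisible to any surface scan; detected berry
  numbers on real dense bunches systematically undercount the truth.
* The sphere model ignores berry deformation and non-spherical shape
  classes.
* Width depends on which sides of the bunch were scanned; partial scans
  bias it low.
* The region-count monotonicity in the smoothness threshold holds on
  smooth fixtures but is not a theorem for arbitrary geometry, since BFS
  recruitment order interacts with the curvature gate.
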