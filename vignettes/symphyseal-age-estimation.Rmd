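---
title: "Methods: surface-based age estimation from the pubic symphysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surface-based age estimation from the pubic symphysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symphage)
```

## The estimation problem

The articular face of the pubic symphysis remodels with age in ways that are
visible in a high-resolution 3D scan long before they are reliably scored by
eye: young faces carry regular transverse ridges and furrows ("billowing"),
mid-life faces flatten and form a rim, and old faces grow irregular, pitted
and porous. `symphage` turns one triangulated scan of the isolated articular
surface (millimetre units, STL or PLY) into six numbers and a multi-linear
age estimate

$$\widehat{\mathrm{Age}} = a_1 x_1 + a_2 x_2 + a_3 x_3 + a_4 x_4 + a_5 x_5
+ a_6 x_6 + K.$$

The features deliberately separate orientation-free surface complexity
($x_1$: spread of local Dirichlet normal energy, $x_2$: spread of local mean
curvature, $x_3$: number of bulge regions) from orientation information
($x_4$, $x_5$: horizontally/vertically oriented regions) and topology
($x_6$: holes, i.e. porosity). `published_sass_model()` carries the
reference coefficients (offset $K = 17.85$ years); `fit_age_model()` refits
them by ordinary least squares on any feature table with known ages.
Estimates are reported unclamped — the raw regression output can fall
outside [18, 92], and clipping is left as an explicit option — because the
evaluation machinery must see the model's genuine behaviour.

Assumptions worth stating: the scan is an *open* surface patch covering the
articular face only (no extended side walls); it is manifold (each edge in
at most two faces — non-manifold input is rejected rather than repaired,
because silent repair would change the hole count); units are millimetres;
and right-sided bones are mirrored to the left before extraction so that a
single model serves both sides.

## Pipeline and numerical choices

**Pose canonicalization.** Principal axes of the (uniformly weighted) vertex
scatter define the frame: $x$ along the largest spread, $z$ along the
smallest, the centroid at the origin. Two deterministic sign rules close the
remaining ambiguity: $+z$ makes the area-weighted mean face normal point up,
and $+x$ makes the skewness of the $x$ coordinates nonnegative. A 180°
ambiguity survives when the skewness is essentially zero, but every
downstream quantity is invariant under it (orientation classes use the acute
angle to the $x$ axis). A perfectly planar vertex cloud is legitimate — flat
test fixtures must pass through the pipeline — so only clouds whose scatter
has rank < 2 (collinear or degenerate) are rejected.

**Rasterization.** The aligned surface is projected top-view onto a regular
grid (default cell 0.1 mm, enough to resolve millimetre-scale bulges). Each
cell center covered by at least one triangle receives the *largest* $z$
among the intersections along $+z$, so rare overhangs resolve to the visible
surface; uncovered cells are invalid and carry `NA`, never a number that
enters statistics. Cell validity defaults to center coverage
(`min_coverage_fraction = 1`, `supersample = 1`); fractional-coverage
supersampling is available but not the default, the simplest reading of a
top-view projection.

**Local surface descriptors.** Both descriptors share one neighborhood
scheme: a Gaussian kernel of bandwidth $h$ = 0.08 × bounding-box diagonal
(the published ariaDNE default scale; exposed in `feature_config()`),
truncated at 2.5 $h$ where the weight falls below 2e-3, with each neighbor
additionally weighted by its vertex area (one third of incident face areas).
The local normal is the smallest-eigenvalue direction of the weighted
position scatter, sign-aligned with the mesh normal. The Dirichlet energy at
a vertex is the weighted mean squared deviation of neighbor normals from
that fitted normal — zero on a plane, growing with bending. Mean curvature
comes from a weighted least-squares quadric in the tangent frame
($w = au^2 + buv + cv^2 + du + ev$, full mean-curvature formula with the
gradient terms), with a relative ridge of 1e-10 on the normal equations for
degenerate neighborhoods. The sign convention is *positive where the surface
bulges along the outward normal*: a dome of radius $r$ has curvature
$+1/r$. Reflecting coordinates in $z$ while keeping the face winding flips
the sign; a proper mirror (winding flipped) preserves it, as it must under
an ambient isometry. Vertices with fewer than four weighted neighbors raise
an increase-the-bandwidth error instead of returning noise.

**Bulge segmentation.** "Local discrepancy of the profile height" is made
operational as the residual of each valid cell against a masked Gaussian
baseline (normalized convolution, so invalid cells contribute nothing),
$\sigma$ = 2 mm by default: ridge wavelengths on young faces are roughly
3–5 mm, so a 2 mm baseline removes global shape and keeps the billows. Cells
whose residual exceeds 0.1 mm (about a fifth of a typical young ridge
amplitude) form the foreground; its 8-connected components are the bulge
regions.

**Ellipse fitting and classification.** Each region becomes the ellipse
matching its second central moments (axis length $4\sqrt{\lambda}$, the
standard image-moment convention). The moment matrix gets a $c^2/12$
diagonal term — the variance of a square cell of side $c$ — so one-cell-wide
regions keep a positive minor axis and eccentricity stays below 1; a
pleasant side effect is that axis ratios of discrete rectangles come out
exact. Regions under 3 cells are skipped with a logged count. Labels follow
the published thresholds: *small* if the major axis is under 3 mm or the
area under 1.5 mm²; else *circular-like* if eccentricity < 0.8; else
*uncertain* if the acute angle to $x$ lies within 10° of 45° (the reference
description says only "about 45°", so the band is a config knob); else
*horizontal* or *vertical*. The priority order cannot change the oriented
counts — an omitted ellipse is omitted — it only makes per-ellipse labels
deterministic.

**Hole counting.** $x_6$ is the number of interior boundary loops of the
mesh (loops minus the outer rim, taken as the loop of greatest perimeter;
the articular rim always encloses the porosity holes in practice). Counting
on the mesh rather than the raster makes the feature independent of grid
resolution.

**Fitting, selection, baselines.** `fit_age_model()` is ordinary least
squares via `lm()`, with an explicit rank check that names the collinear
columns. Features are *not* internally rescaled: the published coefficients
apply verbatim, which is why $a_1 \approx 3.1\times10^6$ against a
numerically tiny $x_1$. `greedy_select()` is forward-only selection under
$\mathrm{AIC} = n\ln(\mathrm{RSS}/n) + 2k$ with $k$ counting slopes plus
intercept (the error variance profiled out — the standard least-squares
form; the original implementation's exact variant is unstated), stopping
when no addition lowers the AIC, ties broken by candidate order. Forward AIC
admits a pure-noise candidate with asymptotic probability
$P(\chi^2_1 > 2) \approx 0.16$; the test suite checks selection behaviour
against that analytic expectation rather than against an unattainable
always-clean rate. The two baselines — uniform random ages on [18, 92] and
the constant 54.1 years (the reference sample's mean age) — provide
performance floors; the constant-*mean* baseline has exactly zero mean bias
on any dataset, an identity the tests exploit.

**Evaluation.** MAE, MBE ($\mathrm{estimated} - \mathrm{actual}$, so
negative means underestimation) and RMSE, pooled over out-of-fold
predictions of a seeded k-fold cross-validation (default $k = 5$). The
partition unit defaults to the *individual*, so both bones of one person
share a fold and cannot leak between training and validation; scan-level
partitioning is available since the original protocol is ambiguous on this
point. When both sides of an individual are present, their estimates are
averaged before scoring. Pooled (not fold-averaged) metrics are primary,
matching the convention of reporting a single error for a cross-validated
model. Per-age dispersion tables group by integer age and use
linear-interpolation quartiles (`type = 7`), with nearest-rank as an option.

## The synthetic generator

Skeletal-collection scans cannot be redistributed, so the package carries
its own ground truth: `generate_surface()` triangulates
$z(x, y) = A\sin(2\pi s/\lambda)$ (ridges; $s$ the coordinate across the
crests) plus negative Gaussian pits plus white roughness on a 35 × 15 mm
patch, then punches holes by deleting interior vertex stars. Hole sites keep
three grid cells between each other and two from the boundary so each
deletion creates exactly one interior loop; sites are re-sampled when the
constraints fail, with an error after 100 attempts. Every planted quantity
is recorded, so hole counts, region counts and orientations can be checked
exactly.

`generate_cohort()` maps age to morphology linearly over 18–92 years:
ridge amplitude 0.8 → 0.05 mm, pits 0 → 15, holes 0 → 10, roughness
0.01 → 0.08 mm — a monotone caricature of symphyseal aging. Ages come
either from a uniform draw on 18–92 or from the six reference age
categories in proportion 33:87:90:95:80:98 (largest-remainder allocation,
so a 483-scan sample reproduces the category counts exactly). A quarter of
individuals (104/374 by default) contribute both sides, the right-side scan
generated with independent roughness and mirrored. Ridge orientation is
drawn uniformly over [0, 180°) per individual: real billows are
predominantly transverse, but with a fixed orientation the
horizontal-ellipse count would be constant zero and the six-feature design
rank-deficient, so the generator trades that anatomical bias for
identifiability of both orientation features. The default tessellation is
0.5 mm — comfortably below the 4 mm default ridge wavelength and the 2 mm
smoothing baseline, so every planted structure is resolved.

What passing tests on this generator establish: that each extractor recovers
its planted quantity (holes exactly; regions and orientations under
well-separated ridges), that the whole pipeline is invariant under rigid
motion and deterministic, and that fitting plus cross-validation behave as
OLS theory predicts (cross-validated MAE near
$\sigma\sqrt{2/\pi} \approx 6.38$ years for $\sigma = 8$ noise). What they
do *not* establish: accuracy on real bone. The generator's age map is nearly
deterministic, so cross-validated errors on synthetic cohorts (around 1–1.5
years) are far below what real material yields; it contains no rim
formation, no sex- or population-specific variation, no scanning artefacts
beyond white noise, and no claim of anatomical realism.

## Problem sizes and costs

The test-suite fixtures are chosen to make every check sharp but cheap:
patches of a few thousand vertices, cohorts of 40–100 individuals, 500-row
regression tables, 1000-case rule oracles. The acceptance script uses a
483-scan baseline sample (matching the reference category counts), a 500-row
simulated regression and a 100-individual mesh cohort (~130 scans); one scan
of ~2 200 vertices takes roughly a quarter of a second through the full
extractor on one CPU, the dominant costs being the kernel-weighted
descriptors and the 0.1 mm rasterization, both implemented in C++.

## Known limitations

* The six features ignore rim morphology and porosity *size*; only counts
  and curvature statistics enter the model.
* The published coefficients were fitted on scans at scanner resolution;
  applying them to meshes with very different tessellation density shifts
  $x_1$ and $x_2$, so refitting is recommended whenever acquisition differs.
* Hole counting equates porosity with scan topology; holes introduced by
  scanning occlusion are indistinguishable from true porosity.
* The uncertain-orientation band (45° ± 10°) and the segmentation
  threshold pair (2 mm, 0.1 mm) are field-reasonable defaults, not
  optimized values; both are exposed in `feature_config()`.
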