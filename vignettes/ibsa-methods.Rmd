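---
title: "Measuring body surface area from CT: models, calibration and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring body surface area from CT: models, calibration and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibsa)
```

## The measurement problem

Body surface area (BSA) scales most cytotoxic chemotherapy doses. In
practice it is predicted from height and weight by regression formulas (Du
Bois & Du Bois, Mosteller, Haycock, Boyd, Gehan & George) whose inputs are
often self-reported and whose calibration populations poorly represent
elderly, sarcopenic or obese patients. A whole-body CT, acquired anyway for
staging, contains the actual body outline. `ibsa` turns that outline into a
surface-area measurement and provides the statistical machinery to compare
the measured and predicted values — including the clinically pointed
question: *would the disagreement change the prescribed dose band?*

## The measurement pipeline and its assumptions

1. **Calibration.** CT voxels are Hounsfield units; air is ≈ −1000 HU and
   all body tissues (fat ≈ −100, muscle ≈ 40, bone ≫ 0) are well above
   −400 HU. DICOM stored values are converted with the header's rescale
   slope/intercept; slices are ordered by spatial position, and the z
   spacing comes from inter-slice position deltas (reconstruction overlap
   makes the declared slice thickness unreliable; a >10% disagreement
   warns).
2. **Segmentation.** Thresholding at −400 HU separates body from air but
   leaves the couch, clothing specks and internal air. Morphological
   closing with a 3 mm ball (spacing-aware, implemented through exact
   Euclidean distance transforms) bridges surface noise; the largest
   26-connected component is kept (couch removal); air cavities not
   connected to the volume border are filled, both in 3D and per axial
   slice in 2D. The 2D pass matters: airways connect the lungs to outside
   air in 3D, and only a slice-wise fill makes the lungs interior, which is
   what "outer skin surface" means. Foreground uses 26-connectivity and
   background 6-connectivity, the standard dual pair that prevents
   checkerboard leaks.
3. **Meshing and area.** The binary mask is smoothed with a Gaussian
   (default σ = 1.5 voxels per axis, below) and the 0.5 iso-surface is
   extracted by marching tetrahedra — each grid cell is split into six
   tetrahedra around its main diagonal, crossing vertices are interpolated
   on tetrahedron edges and shared between cells, so the mesh is indexed,
   ambiguity-free and watertight whenever the mask does not touch the
   volume border (if it does, the surface is closed flat there and a
   warning is raised). The area is the sum of triangle areas; a per-vertex
   accumulation is not a well-defined surface integral and is not offered.

### Why σ = 1.5 voxels

Iso-surfacing a *raw* binary mask overestimates the area of smooth bodies:
the staircase surface has systematically steeper local slopes than the
underlying smooth boundary. Gaussian pre-smoothing trades that metrication
excess against curvature shrinkage (smoothing pulls convex surfaces
inward). Both effects are measurable with the package's own phantoms:

* at σ = 1 voxel the smoothed field is essentially scale-invariant in index
  space, leaving a resolution-*independent* residual of about +0.4% on a
  sphere — the error does not shrink as voxels shrink;
* at σ = 1.5 voxels the residual staircase excess is cancelled; measured
  sphere errors at 2 / 1 / 0.5 mm spacing are −1.30 / −0.28 / −0.01%,
  i.e. the estimator converges to the analytic truth, and cubes, cylinders
  and ellipsoids stay within 2–3% at 1 mm.

σ is specified per axis in index space (so a coarsely sampled z axis gets
proportionally more physical smoothing, matching its larger staircase
steps); on a (3, 1, 1) mm sphere this keeps the error at ~1.4%, whereas a
physically isotropic kernel leaves ~5%. `smoothing_sigma_vox = 0` exposes
the raw staircase behaviour for study.

Defaults: threshold −400 HU, closing 3 mm, minimum body volume 500 ml
(phantom work uses a smaller minimum), iso-level 0.5. All are configurable;
none is estimated from data at run time.

## Anthropometric formulas and error propagation

All five formulas take metres and kilograms at the interface and convert
internally (the Du Bois form used here takes H in metres —
`0.20247·100^0.725` reproduces the classical cm-based coefficient 0.007184;
the others take centimetres, Boyd grams). Differentiating Du Bois gives the
first-order sensitivity `ΔBSA/BSA = 0.725·ΔH/H + 0.425·ΔW/W`: a 50 kg
patient losing 1 kg (a 2% weight change) changes formula BSA by only
0.85% — formula BSA is intrinsically insensitive to the morphological
changes clinicians may want to track, which is part of the case for
measuring instead of predicting.

## Agreement statistics

`blandAltman()` uses proportional differences, `100·(a−b)/((a+b)/2)`; the
pair-mean denominator is the standard choice for ratio-scale data and is
switchable to denominator-b for sensitivity analysis. SD uses n−1 (the
intended use is small test-retest panels), limits of agreement are
bias ± 1.96·SD as identities, and bootstrap CIs are percentile intervals
over resampled pairs (deterministic given a seed). Variances are compared
with an F-test (larger variance in the numerator) and biases with a Welch
t-test. When both replicates of a test-retest pair carry independent
multiplicative noise s\*, the proportional-difference SD estimates s\*·√2,
not s\* — the validation tests check exactly that recovery.

## The dose-banding simulation

True BSA values are drawn uniformly on [1.2, 2.5] m²; each is perturbed
multiplicatively, `sBSA = BSA·(1 + ε)`, `ε ~ N(0, σ)` with σ the
inter-method Bland-Altman SD expressed as a fraction (default 4.11%, the
iBSA vs Du Bois value; the inter-method *bias* is deliberately not injected
— the simulated error has zero mean). Both values map to dose bands
(half-open intervals, out-of-range values clamped to the outer bands) and
the reclassification rate is the fraction that changes band, with Monte
Carlo standard error √(r(1−r)/N). A quadrature oracle integrates the exact
crossing probability over the population and agrees with the Monte Carlo
within sampling error.

**Band-table reconstruction.** The published capecitabine protocol table
behind the original analysis is not machine-readable, so the bundled table
is a reconstruction constrained by what is known: contiguous equal-width
bands spanning [1.2, 2.5] m² and per-administration doses stepping by
150 mg (one tablet). Under clamped assignment, seven equal bands yield a
27.8% reclassification rate at σ = 4.11%, while eight bands yield 32.0% —
matching the ~1/3 reclassification this analysis is known to produce — so
the bundled table uses **eight** bands (`capecitabine_bands.csv`,
1500–2550 mg, step/range = 14.3%). The two-band-shift fraction (~0.6% here)
is strongly table-dependent and is reported but never gated. Any real
protocol table can be substituted via `loadBandTable()`.

## What the synthetic validation shows — and what it cannot

The phantom factory generates solids with closed-form surface areas,
voxelized by centre sampling with no anti-aliasing, so every smoothing
effect observed downstream is attributable to the measurement pipeline,
not the generator. The composite "body" joins a cylindrical torso, an
embedded spherical head and cylindrical legs across planar cuts, keeping
its truth exact (circle and spherical-cap corrections only). The ellipsoid
truth uses the Thomsen approximation (max error ≈ 1.06%), which is why the
ellipsoid tolerance is 3% where the others use 2%.

Test-retest precision is emulated by rigidly resampling a phantom
(sub-voxel shifts, small z-rotations, trilinear interpolation) with fresh
HU noise; cohorts are truncated correlated bivariate normals (H ~ N(1.70,
0.09²) m on [1.51, 1.92], W ~ N(75, 15²) kg on [42, 115], correlation 0.6;
the latent correlation is inflated ~6% so the *delivered* sample
correlation matches the request after truncation).

What passing these tests does **not** show: performance on real bodies.
Synthetic phantoms have no limb-to-limb or arm-to-trunk contact (a known
source of underestimation in patients, since touching surfaces disappear
from the outer iso-surface), no truncated fields of view, no metal or
beam-hardening artifacts, and no tissue texture. The accuracy contract
established here is that the *estimator* is unbiased to ~2% on resolvable
smooth geometry; clinical accuracy must be established on clinical data.

## Numerical choices and problem sizes

Exact Euclidean distance transforms (separable lower-envelope algorithm)
implement the ball morphology in O(N) independent of radius; closing is
algebraically idempotent, making full segmentation a fixed point on its own
output. Degenerate (zero-area) faces are removed after meshing; band
boundaries are half-open with the last band closed; accuracy summaries use
exact order statistics with even-count medians as midpoints. Validation
suites run spheres of 40–50 mm radius at 0.5–3 mm spacing, 14-replicate
repositioning experiments, 200-pair precision panels and Monte Carlo sizes
of 10⁵–10⁶ — sizes at which every reported tolerance is in the asymptotic
regime while the whole suite stays interactive.

## Known limitations

* No de-contact algorithm for touching body parts; no pose handling.
* Partial-scan measurements are normalized per unit length
  (`normalizePartial()`), not extrapolated to whole-body BSA.
* Only single-frame, uncompressed little-endian DICOM is read.
* Non-axial acquisitions are not reoriented automatically.
* The bundled dose table is a reconstruction; protocol-level conclusions
  should use the actual protocol's table.
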