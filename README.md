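# ibsa — image-derived body surface area from CT

Chemotherapy doses are scaled by body surface area (BSA), yet BSA is almost
always *estimated* from height and weight with century-old regression
formulas rather than *measured*. Cancer patients routinely undergo CT, and a
whole-body CT contains the body's actual outer surface. `ibsa` measures it:
the package segments the body from a CT volume, extracts a triangulated
iso-surface, and integrates its area in physical units — an image-derived BSA
(iBSA). Around that core it provides everything needed to qualify such a
measurement as a quantitative imaging biomarker and to ask whether the
difference between measured and formula-based BSA would actually change
prescriptions.

It is intended for imaging scientists and quantitative-imaging groups
evaluating body-surface measurement, and for pharmacometrics-minded readers
who want the dose-banding impact simulation.

## What it computes

**Measurement pipeline.** `readCT()` loads DICOM series, NIfTI or MetaImage
volumes into a calibrated Hounsfield-unit grid with millimetre spacing.
`segmentBody()` thresholds at −400 HU and applies spacing-aware mathematical
morphology (ball closing, largest-component selection to drop the scanner
couch, 3D plus slice-wise 2D cavity filling so lungs and bowel gas become
interior). `maskToMesh()` Gaussian-smooths the binary mask and extracts the
0.5 iso-surface by marching tetrahedra; `meshArea()` sums triangle areas
`½‖(v₁−v₀)×(v₂−v₀)‖`. `measureIbsa()` chains these and reports cm² and m²;
`normalizePartial()` divides by z-coverage for partial scans.

**Anthropometric models.** `bsaFormula()` implements Du Bois & Du Bois
(`0.20247·H_m^0.725·W_kg^0.425`), Mosteller, Haycock, Boyd and Gehan &
George; `bsaRelativeError()` gives the first-order Du Bois error propagation
`ΔBSA/BSA = 0.725·ΔH/H + 0.425·ΔW/W` in percent.

**Method comparison.** `percentRelativeError()`, `accuracySummary()`,
`blandAltman()` (proportional differences, bias, SD, limits of agreement
bias ± 1.96·SD), `bootstrapCI()` (percentile, resampling pairs) and
`compareMethods()` (F-test on variances, Welch t-test on biases).

**Dose-banding impact.** `simulateReclassification()` draws N BSA values
uniformly on [1.2, 2.5] m², perturbs each by a zero-mean Gaussian relative
error (σ = the inter-method Bland-Altman SD, 4.11% by default), assigns both
values to the bands of a capecitabine dose table, and reports the fraction
whose dose band changes. `analyticReclassification()` is a quadrature oracle
for the same quantity.

**Phantom factory.** `makePhantom()` builds CT phantoms (sphere, cube,
cylinder, ellipsoid, composite body) with exact analytic surface areas;
`makeTestRetest()` produces rigidly shifted, re-noised "retest" acquisitions;
`makeCohort()` draws correlated height/weight populations. These stand in for
scanner phantoms and clinical datasets in all validation tests.

## Worked example

```r
library(ibsa)

# a 50 mm radius sphere phantom at 1 mm spacing; truth = 4*pi*r^2
ph <- makePhantom("sphere", list(r = 50), spacing_mm = 1)
m  <- measureIbsa(ph$ct, segConfig(min_component_volume_ml = 50))
m
#> iBSA: 313.72 cm^2 (0.0314 m^2), z extent 116.0 mm, 281232 faces
percentRelativeError(m@area_cm2, ph$analytic_surface_cm2)
#> [1] -0.1393791        # 0.14% below the analytic 314.159 cm^2

bsaFormula("dubois", 1.70, 70)
#> [1] 1.809684           # m^2

simulateReclassification(defaultBandTable(), seed = 42)
#> Reclassification rate: 0.3200 (MC SE 0.00047), N = 1e+06, sigma = 4.11%
```

The sphere measurement lands 0.14% from the closed-form surface; the Monte
Carlo says that with a 4.11% relative disagreement between two BSA methods,
about 32% of a uniformly distributed patient population would receive a
different capecitabine dose band — the banding is fine enough that realistic
inter-method error routinely crosses band boundaries.

A command-line interface wrapping the same functions is installed at
`exec/ibsa.R` (subcommands `measure`, `formula`, `compare`, `simulate`,
`phantom`).

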