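#' @include AllClasses.R
NULL

#' Access voxel data
#' @param x a [CTVolume-class] or [BodyMask-class].
#' @return The 3D voxel array.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' Access voxel spacing (mm)
#' @param x a [CTVolume-class] or [BodyMask-class].
#' @return Numeric length-3 `(x, y, z)` spacing in mm.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' Access physical origin (mm)
#' @param x a [CTVolume-class] or [BodyMask-class].
#' @return Numeric length-3 origin in mm.
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' Total mesh surface area
#' @param mesh a [TriangleMesh-class].
#' @return Surface area in mm^2 (sum of triangle areas).
#' @export
setGeneric("meshArea", function(mesh) standardGeneric("meshArea"))

#' @rdname voxels
#' @export
setMethod("voxels", "CTVolume", function(x) x@voxels)
#' @rdname voxels
#' @export
setMethod("voxels", "BodyMask", function(x) x@voxels)
#' @rdname spacing
#' @export
setMethod("spacing", "CTVolume", function(x) x@spacing)
#' @rdname spacing
#' @export
setMethod("spacing", "BodyMask", function(x) x@spacing)
#' @rdname origin
#' @export
setMethod("origin", "CTVolume", function(x) x@origin)
#' @rdname origin
#' @export
setMethod("origin", "BodyMask", function(x) x@origin)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CTVolume %d x %d x %d voxels, spacing (%g, %g, %g) mm, HU [%g, %g]\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3], min(object@voxels), max(object@voxels)))
})

setMethod("show", "BodyMask", function(object) {
  d <- dim(object@voxels)
  n <- sum(object@voxels)
  ml <- n * prod(object@spacing) / 1000
  cat(sprintf("BodyMask %d x %d x %d voxels, %d foreground (%.1f ml)\n",
              d[1], d[2], d[3], n, ml))
})

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces, area %.2f cm^2\n",
              nrow(object@vertices), nrow(object@faces), meshArea(object) / 100))
})

setMethod("show", "SurfaceMeasurement", function(object) {
  cat(sprintf("iBSA: %.2f cm^2 (%.4f m^2), z extent %.1f mm, %d faces\n",
              object@area_cm2, object@area_m2, object@z_extent_mm,
              object@n_faces))
  if (!is.na(object@area_per_length_cm2_per_cm))
    cat(sprintf("  per-length: %.2f cm^2/cm\n", object@area_per_length_cm2_per_cm))
})

setMethod("show", "DoseBandTable", function(object) {
  cat(sprintf("DoseBandTable '%s': %d bands over [%.3f, %.3f] m^2, doses %g-%g mg\n",
              object@name, nrow(object@bands), min(object@bands$bsa_low),
              max(object@bands$bsa_high), min(object@bands$dose_mg),
              max(object@bands$dose_mg)))
})

setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("Reclassification rate: %.4f (MC SE %.2g), N = %g, sigma = %g%%\n",
              object@reclassification_rate, object@mc_standard_error,
              object@config$n_samples, object@config$sigma_pct))
})

setMethod("show", "BlandAltmanResult", function(object) {
  u <- if (object@mode == "proportional") "%" else ""
  cat(sprintf("Bland-Altman (%s, n=%d): bias %.4f%s, SD %.4f%s, LoA [%.4f, %.4f]%s\n",
              object@mode, object@n, object@bias_pct, u, object@sd_pct, u,
              object@loa_low_pct, object@loa_high_pct, u))
})
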