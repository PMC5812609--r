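#' @import methods
NULL

# -- CT volume ----------------------------------------------------------------

#' Calibrated CT volume
#'
#' A 3D scalar field in Hounsfield units (HU) with physical voxel spacing and
#' origin. Voxels are stored as a native R array with `dim = c(nx, ny, nz)`
#' (x fastest); `spacing` and `origin` are `(x, y, z)` vectors in millimetres.
#'
#' @slot voxels numeric 3D array, HU.
#' @slot spacing numeric length-3, voxel size per axis in mm, all > 0.
#' @slot origin numeric length-3, physical position of voxel (1,1,1) in mm.
#' @export
setClass("CTVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"))

setValidity("CTVolume", function(object) {
  d <- dim(object@voxels)
  if (length(d) != 3L) return("voxels must be a 3D array")
  if (any(d < 2L)) return("grid must have >= 2 voxels per axis")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) return("spacing must be 3 positive values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite values")
  rng <- range(object@voxels)
  if (rng[1] < -1024 - 1e-6 || rng[2] > 3071 + 1e-6)
    return("HU values must lie within [-1024, 3071]")
  TRUE
})

#' Construct a CTVolume
#'
#' @param voxels numeric 3D array of HU values (dim `c(nx, ny, nz)`).
#' @param spacing voxel size `(x, y, z)` in mm.
#' @param origin physical position of the first voxel in mm.
#' @return A [CTVolume-class] object.
#' @export
CTVolume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  new("CTVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

# -- Body mask ----------------------------------------------------------------

#' Binary body mask aligned to a CT volume
#'
#' @slot voxels logical 3D array, TRUE for body voxels.
#' @slot spacing numeric length-3, mm, copied from the source volume.
#' @slot origin numeric length-3, mm.
#' @export
setClass("BodyMask",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"))

setValidity("BodyMask", function(object) {
  d <- dim(object@voxels)
  if (length(d) != 3L) return("voxels must be a 3D array")
  if (!is.logical(object@voxels)) return("mask voxels must be logical")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive values")
  TRUE
})

#' Construct a BodyMask
#'
#' @param voxels logical 3D array.
#' @param spacing voxel size `(x, y, z)` in mm.
#' @param origin physical position of the first voxel in mm.
#' @return A [BodyMask-class] object.
#' @export
BodyMask <- function(voxels, spacing, origin = c(0, 0, 0)) {
  storage.mode(voxels) <- "logical"
  new("BodyMask", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

# -- Segmentation configuration -----------------------------------------------

#' Segmentation configuration
#'
#' Parameters of the automatic body segmentation. Defaults: threshold -400 HU
#' (soft tissue and bone above, air and lung parenchyma below; lungs are
#' recovered by cavity filling), spacing-aware morphological closing with a
#' 3 mm ball, minimum body size 500 ml.
#'
#' @slot hu_threshold HU threshold; voxels with HU >= threshold are body candidates.
#' @slot closing_radius_mm radius (mm) of the ball used for morphological closing.
#' @slot min_component_volume_ml smallest acceptable body component, millilitres.
#' @slot fill_cavities fill internal air cavities (lungs, bowel gas).
#' @slot remove_couch keep only the largest connected component.
#' @export
setClass("SegmentationConfig",
  representation(hu_threshold = "numeric", closing_radius_mm = "numeric",
                 min_component_volume_ml = "numeric", fill_cavities = "logical",
                 remove_couch = "logical"))

setValidity("SegmentationConfig", function(object) {
  if (object@closing_radius_mm < 0) return("closing_radius_mm must be >= 0")
  if (object@min_component_volume_ml < 0)
    return("min_component_volume_ml must be >= 0")
  TRUE
})

#' Create a segmentation configuration
#'
#' @param hu_threshold HU threshold (default -400).
#' @param closing_radius_mm closing ball radius in mm (default 3).
#' @param min_component_volume_ml minimum body volume in ml (default 500).
#' @param fill_cavities fill internal cavities (default TRUE).
#' @param remove_couch keep only the largest component (default TRUE).
#' @return A [SegmentationConfig-class] object.
#' @export
segConfig <- function(hu_threshold = -400, closing_radius_mm = 3,
                      min_component_volume_ml = 500, fill_cavities = TRUE,
                      remove_couch = TRUE) {
  new("SegmentationConfig", hu_threshold = hu_threshold,
      closing_radius_mm = closing_radius_mm,
      min_component_volume_ml = min_component_volume_ml,
      fill_cavities = fill_cavities, remove_couch = remove_couch)
}

# -- Triangle mesh ------------------------------------------------------------

#' Triangulated iso-surface
#'
#' @slot vertices numeric matrix (n x 3), mm.
#' @slot faces integer matrix (m x 3), 1-based vertex indices.
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix"))

setValidity("TriangleMesh", function(object) {
  if (ncol(object@vertices) != 3L) return("vertices must be n x 3")
  if (ncol(object@faces) != 3L) return("faces must be m x 3")
  if (nrow(object@faces) > 0) {
    f <- object@faces
    if (min(f) < 1L || max(f) > nrow(object@vertices))
      return("face indices out of range")
  }
  TRUE
})

# -- Surface measurement ------------------------------------------------------

#' iBSA surface measurement
#'
#' @slot area_cm2 body surface area, cm^2.
#' @slot area_m2 same in m^2 (`area_cm2 / 1e4`).
#' @slot n_vertices,n_faces mesh size.
#' @slot z_extent_mm scan coverage along z, `(n_slices - 1) * z_spacing`, mm.
#' @slot area_per_length_cm2_per_cm partial-scan normalization (NA until
#'   [normalizePartial()] is applied), cm^2 per cm of z coverage.
#' @slot config_fingerprint provenance token for the configuration used.
#' @export
setClass("SurfaceMeasurement",
  representation(area_cm2 = "numeric", area_m2 = "numeric",
                 n_vertices = "integer", n_faces = "integer",
                 z_extent_mm = "numeric",
                 area_per_length_cm2_per_cm = "numeric",
                 config_fingerprint = "character"))

setValidity("SurfaceMeasurement", function(object) {
  if (object@area_cm2 <= 0) return("area_cm2 must be > 0")
  if (abs(object@area_m2 - object@area_cm2 / 1e4) > 1e-9 * object@area_m2 + 1e-12)
    return("area_m2 must equal area_cm2 / 1e4")
  if (object@z_extent_mm <= 0) return("z_extent_mm must be > 0")
  TRUE
})

# -- Dose band table ----------------------------------------------------------

#' Dose-banding table
#'
#' Ordered, contiguous BSA intervals with an assigned drug dose per band.
#'
#' @slot bands data.frame with columns `bsa_low`, `bsa_high` (m^2) and
#'   `dose_mg` (mg per administration).
#' @slot name label of the protocol.
#' @export
setClass("DoseBandTable",
  representation(bands = "data.frame", name = "character"))

setValidity("DoseBandTable", function(object) {
  b <- object@bands
  need <- c("bsa_low", "bsa_high", "dose_mg")
  if (!all(need %in% names(b))) return("bands needs bsa_low, bsa_high, dose_mg")
  if (nrow(b) < 1) return("at least one band required")
  if (any(b$bsa_high <= b$bsa_low)) return("bands must have bsa_high > bsa_low")
  if (nrow(b) > 1) {
    if (any(abs(b$bsa_low[-1] - b$bsa_high[-nrow(b)]) > 1e-9))
      return("non-contiguous bands")
    if (any(diff(b$dose_mg) < 0)) return("invalid doses")
  }
  TRUE
})

# -- Simulation result --------------------------------------------------------

#' Dose-band reclassification simulation result
#'
#' @slot reclassification_rate fraction of samples whose band changed.
#' @slot shift_histogram named numeric: fraction of samples per |band shift|.
#' @slot mc_standard_error Monte Carlo standard error of the rate.
#' @slot config list echoing the simulation configuration.
#' @export
setClass("SimulationResult",
  representation(reclassification_rate = "numeric",
                 shift_histogram = "numeric",
                 mc_standard_error = "numeric",
                 config = "list"))

setValidity("SimulationResult", function(object) {
  h <- object@shift_histogram
  if (abs(sum(h) - 1) > 1e-9) return("shift histogram must sum to 1")
  r <- object@reclassification_rate
  if (r < 0 || r > 1) return("rate must lie in [0, 1]")
  if (abs((1 - h[["0"]]) - r) > 1e-12) return("rate must equal 1 - histogram[0]")
  TRUE
})

# -- Bland-Altman result ------------------------------------------------------

#' Bland-Altman analysis result
#'
#' @slot bias_pct mean difference (percent in proportional mode).
#' @slot sd_pct sample SD (n-1) of the differences.
#' @slot loa_low_pct,loa_high_pct limits of agreement, `bias +/- 1.96 sd`.
#' @slot ci_bias,ci_sd bootstrap 95% percentile CIs (length 2, NA if not requested).
#' @slot n number of pairs.
#' @slot mode "proportional" or "absolute".
#' @export
setClass("BlandAltmanResult",
  representation(bias_pct = "numeric", sd_pct = "numeric",
                 loa_low_pct = "numeric", loa_high_pct = "numeric",
                 ci_bias = "numeric", ci_sd = "numeric",
                 n = "integer", mode = "character"))

setValidity("BlandAltmanResult", function(object) {
  if (abs(object@loa_low_pct - (object@bias_pct - 1.96 * object@sd_pct)) > 1e-9)
    return("loa_low must equal bias - 1.96 sd")
  if (abs(object@loa_high_pct - (object@bias_pct + 1.96 * object@sd_pct)) > 1e-9)
    return("loa_high must equal bias + 1.96 sd")
  TRUE
})

# -- QC bundle ----------------------------------------------------------------

#' QC overlay bundle
#'
#' Per-slice review images: the CT slice, the mask contour drawn over it, and a
#' side-by-side panel, plus a 3-plane projection snapshot of the mask.
#'
#' @slot overlays list (one per requested slice) of lists with elements
#'   `slice` (index), `ct` (grayscale matrix), `overlay` (RGB array with the
#'   contour), `panel` (side-by-side RGB array), `n_contour_px` (count).
#' @slot projection list of three mask maximum projections (xy, xz, yz).
#' @export
setClass("QcBundle", representation(overlays = "list", projection = "list"))
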