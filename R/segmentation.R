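#' Threshold a CT volume into a body-candidate mask
#'
#' A voxel is foreground iff its HU value is greater than or equal to the
#' threshold. No morphology is applied; see [refineMask()].
#'
#' @param ct a [CTVolume-class].
#' @param hu_threshold HU threshold (default -400: soft tissue and bone above,
#'   air below; aerated lung also falls below and is recovered later by cavity
#'   filling).
#' @return A [BodyMask-class] (possibly empty).
#' @export
thresholdBody <- function(ct, hu_threshold = -400) {
  BodyMask(voxels(ct) >= hu_threshold, spacing = spacing(ct),
           origin = origin(ct))
}

# distance-transform morphology: ball of radius r (mm), spacing-aware
.dilate_ball <- function(m, spacing, r) {
  if (r <= 0) return(m)
  d2 <- .cpp_edt_sq(as.vector(m), dim(m), spacing)
  array(d2 <= r * r + 1e-9, dim = dim(m))
}
.erode_ball <- function(m, spacing, r) {
  if (r <= 0) return(m)
  d2 <- .cpp_edt_sq(as.vector(!m), dim(m), spacing)
  array(m & !(d2 <= r * r + 1e-9), dim = dim(m))
}

.largest_component <- function(m) {
  lab <- .cpp_label(as.vector(m), dim(m), 26L)
  k <- attr(lab, "n_components")
  if (k == 0L) return(NULL)
  sizes <- tabulate(lab[lab > 0L], nbins = k)
  best <- which.max(sizes)
  array(lab == best, dim = dim(m))
}

# fill background components not connected to the volume border (6-connectivity)
.fill_cavities_3d <- function(m) {
  lab <- .cpp_label(as.vector(!m), dim(m), 6L)
  lab <- array(lab, dim = dim(m))
  border <- unique(c(lab[1, , ], lab[dim(m)[1], , ], lab[, 1, ],
                     lab[, dim(m)[2], ], lab[, , 1], lab[, , dim(m)[3]]))
  border <- border[border > 0L]
  m | (lab > 0L & !(lab %in% border))
}

# per-axial-slice 2D fill (closes cavities that reach outside air through
# another slice, e.g. lungs connected to outside air via the airways)
.fill_cavities_2d <- function(m) {
  d <- dim(m)
  for (k in seq_len(d[3])) {
    sl <- m[, , k]
    if (!any(sl) || all(sl)) next
    lab <- .cpp_label(as.vector(!sl), c(d[1], d[2], 1L), 6L)
    lab <- array(lab, dim = c(d[1], d[2]))
    border <- unique(c(lab[1, ], lab[d[1], ], lab[, 1], lab[, d[2]]))
    border <- border[border > 0L]
    m[, , k] <- sl | (lab > 0L & !(lab %in% border))
  }
  m
}

#' Refine a thresholded mask with mathematical morphology
#'
#' In order: (1) morphological closing with a spacing-aware ball of radius
#' `closing_radius_mm` (bridges skin-surface noise); (2) retention of the
#' largest 26-connected component (removes the scanner couch, clothing and
#' noise specks); (3) filling of all air cavities not connected to the volume
#' border, both in 3D and per axial slice in 2D (lungs, bowel gas and airways
#' become interior, so the surface is the outer skin surface).
#'
#' @param mask a nonempty [BodyMask-class].
#' @param config a [SegmentationConfig-class].
#' @return The refined [BodyMask-class]: one connected component, cavity-free.
#' @export
refineMask <- function(mask, config = segConfig()) {
  m <- voxels(mask)
  if (!any(m)) stop("no body found", call. = FALSE)
  sp <- spacing(mask)
  r <- config@closing_radius_mm
  if (r > 0) {
    m <- .dilate_ball(m, sp, r)
    m <- .erode_ball(m, sp, r)
  }
  if (config@remove_couch) {
    m <- .largest_component(m)
    if (is.null(m)) stop("no body found", call. = FALSE)
  }
  vol_ml <- sum(m) * prod(sp) / 1000
  if (vol_ml < config@min_component_volume_ml)
    stop("no body found", call. = FALSE)
  if (config@fill_cavities) {
    m <- .fill_cavities_3d(m)
    m <- .fill_cavities_2d(m)
    m <- .fill_cavities_3d(m)  # 2D filling can create new 3D-enclosed pockets
  }
  BodyMask(m, spacing = sp, origin = origin(mask))
}

#' Fully automatic body segmentation
#'
#' Composition of [thresholdBody()] and [refineMask()]; deterministic, requires
#' no a-priori information.
#'
#' @param ct a [CTVolume-class].
#' @param config a [SegmentationConfig-class].
#' @return A [BodyMask-class].
#' @export
segmentBody <- function(ct, config = segConfig()) {
  refineMask(thresholdBody(ct, config@hu_threshold), config)
}

#' Count internal cavities of a mask
#'
#' Diagnostic helper: number of background components (6-connectivity) not
#' reachable from the volume border. A refined mask has zero.
#'
#' @param mask a [BodyMask-class].
#' @return Integer cavity count.
#' @export
countCavities <- function(mask) {
  m <- voxels(mask)
  lab <- .cpp_label(as.vector(!m), dim(m), 6L)
  k <- attr(lab, "n_components")
  if (k == 0L) return(0L)
  lab <- array(lab, dim = dim(m))
  border <- unique(c(lab[1, , ], lab[dim(m)[1], , ], lab[, 1, ],
                     lab[, dim(m)[2], ], lab[, , 1], lab[, , dim(m)[3]]))
  border <- border[border > 0L]
  length(setdiff(seq_len(k), border))
}
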