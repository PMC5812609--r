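#' Read a CT volume
#'
#' Reads a CT volume from a NIfTI file (`.nii`/`.nii.gz`), a MetaImage file
#' (`.mha`/`.mhd`) or a directory containing one DICOM series, into the
#' canonical calibrated [CTVolume-class] representation (HU, mm spacing).
#' For DICOM, stored values are rescaled with `RescaleSlope`/`RescaleIntercept`,
#' slices are sorted by spatial position (never by filename) and the z spacing
#' is taken from inter-slice position deltas, with a warning when it disagrees
#' with the declared `SliceThickness` by more than 10%.
#'
#' @param path file (NIfTI/MetaImage) or directory (DICOM series).
#' @param format one of `"auto"`, `"dicom_dir"`, `"nifti"`, `"metaimage"`.
#' @return A [CTVolume-class].
#' @export
readCT <- function(path, format = c("auto", "dicom_dir", "nifti", "metaimage")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("format error: path does not exist", call. = FALSE)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom_dir"
      else if (grepl("\\.(nii|nii\\.gz)$", path, ignore.case = TRUE)) "nifti"
      else if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) "metaimage"
      else stop("format error: unrecognised extension", call. = FALSE)
  }
  switch(format,
    dicom_dir = .read_dicom_dir(path),
    nifti = .read_nifti(path),
    metaimage = .read_metaimage(path))
}

.read_nifti <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("format error", call. = FALSE))
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim = dim(arr)[1:3])
  sp <- RNifti::pixdim(img)[seq_len(3)]
  aff <- try(RNifti::xform(img), silent = TRUE)
  orig <- if (!inherits(aff, "try-error")) as.numeric(aff[1:3, 4]) else c(0, 0, 0)
  arr <- pmin(pmax(arr, -1024), 3071)
  CTVolume(arr, spacing = abs(sp), origin = orig)
}

.as_nifti <- function(arr, spacing, origin) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  img
}

#' Write a body mask as NIfTI
#'
#' Persists a [BodyMask-class] as a 0/1 uint8 NIfTI volume with the geometry
#' (spacing, origin) copied from its reference CT. Read-back equals the input
#' voxel for voxel.
#'
#' @param mask a [BodyMask-class].
#' @param ref the [CTVolume-class] the mask belongs to.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
writeMask <- function(mask, ref, path) {
  if (!identical(dim(voxels(mask)), dim(voxels(ref))))
    stop("geometry mismatch", call. = FALSE)
  arr <- array(as.integer(voxels(mask)), dim = dim(voxels(mask)))
  storage.mode(arr) <- "integer"
  img <- .as_nifti(arr, spacing(ref), origin(ref))
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a mask written by [writeMask()]
#'
#' @param path NIfTI path.
#' @return A [BodyMask-class].
#' @export
readMask <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("format error", call. = FALSE))
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim = dim(arr)[1:3])
  sp <- abs(RNifti::pixdim(img)[seq_len(3)])
  aff <- try(RNifti::xform(img), silent = TRUE)
  orig <- if (!inherits(aff, "try-error")) as.numeric(aff[1:3, 4]) else c(0, 0, 0)
  BodyMask(arr > 0.5, spacing = sp, origin = orig)
}

# -- QC overlays --------------------------------------------------------------

.window_gray <- function(slice, lo = -1000, hi = 400) {
  g <- (slice - lo) / (hi - lo)
  g[g < 0] <- 0; g[g > 1] <- 1
  g
}

.contour2d <- function(m) {
  # boundary pixels: foreground with at least one 4-neighbour background pixel
  nx <- nrow(m); ny <- ncol(m)
  pad <- matrix(FALSE, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- m
  interior <- pad[1:nx, 2:(ny + 1)] & pad[3:(nx + 2), 2:(ny + 1)] &
    pad[2:(nx + 1), 1:ny] & pad[2:(nx + 1), 3:(ny + 2)]
  m & !interior
}

#' Build QC overlay images for segmentation review
#'
#' For each requested axial slice, renders the windowed CT slice, the same
#' slice with the mask contour drawn in red, and a side-by-side panel of the
#' two, plus a 3-plane maximum-projection snapshot of the mask — the review
#' layout used to visually confirm that segmentations follow the body outline.
#'
#' @param ct a [CTVolume-class].
#' @param mask the matching [BodyMask-class].
#' @param slices integer vector of axial slice indices (1-based).
#' @return A [QcBundle-class].
#' @export
qcOverlay <- function(ct, mask, slices) {
  d <- dim(voxels(ct))
  if (!identical(d, dim(voxels(mask)))) stop("geometry mismatch", call. = FALSE)
  slices <- as.integer(slices)
  if (any(slices < 1L | slices > d[3])) stop("slice out of range", call. = FALSE)
  overlays <- lapply(slices, function(k) {
    g <- .window_gray(voxels(ct)[, , k])
    ctr <- .contour2d(voxels(mask)[, , k])
    rgb <- array(rep(g, 3L), dim = c(d[1], d[2], 3L))
    r <- rgb[, , 1]; gg <- rgb[, , 2]; b <- rgb[, , 3]
    r[ctr] <- 1; gg[ctr] <- 0; b[ctr] <- 0
    rgb[, , 1] <- r; rgb[, , 2] <- gg; rgb[, , 3] <- b
    base <- array(rep(g, 3L), dim = c(d[1], d[2], 3L))
    panel <- array(0, dim = c(2L * d[1], d[2], 3L))
    panel[seq_len(d[1]), , ] <- base
    panel[d[1] + seq_len(d[1]), , ] <- rgb
    list(slice = k, ct = g, overlay = rgb, panel = panel,
         n_contour_px = sum(ctr))
  })
  m <- voxels(mask)
  projection <- list(xy = apply(m, c(1, 2), max),
                     xz = apply(m, c(1, 3), max),
                     yz = apply(m, c(2, 3), max))
  new("QcBundle", overlays = overlays, projection = projection)
}

#' Write a QC bundle to PNG files
#'
#' @param bundle a [QcBundle-class].
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
writeQcBundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (ov in bundle@overlays) {
    p <- file.path(dir, sprintf("qc_slice_%04d.png", ov$slice))
    # image rows run along y: transpose so the PNG is upright
    png::writePNG(aperm(ov$panel, c(2, 1, 3)), p)
    paths <- c(paths, p)
  }
  for (nm in names(bundle@projection)) {
    p <- file.path(dir, sprintf("qc_projection_%s.png", nm))
    png::writePNG(t(bundle@projection[[nm]] * 1), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
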