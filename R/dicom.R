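# Minimal DICOM series support: single-frame, uncompressed, little-endian CT
# slices (explicit or implicit VR). Covers what a thresholding/meshing pipeline
# needs: geometry, rescale calibration and pixel data. Compressed transfer
# syntaxes and multi-frame enhanced CT are rejected as "format error".

.TS_IMPLICIT <- "1.2.840.10008.1.2"
.TS_EXPLICIT <- "1.2.840.10008.1.2.1"

.u16 <- function(raw, at) {
  as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
}
.u32 <- function(raw, at) {
  as.numeric(raw[at]) + 256 * as.numeric(raw[at + 1L]) +
    65536 * as.numeric(raw[at + 2L]) + 16777216 * as.numeric(raw[at + 3L])
}

# Parse one element stream starting at `pos`; returns a list of tag -> raw value.
# Stops at end of raw or when `stop_group` (e.g. leaving group 0002) is passed.
.dcm_parse <- function(raw, pos, explicit, only_group = NULL) {
  out <- list()
  n <- length(raw)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= n) {
    grp <- .u16(raw, pos); ele <- .u16(raw, pos + 2L)
    if (!is.null(only_group) && grp != only_group) break
    if (explicit && grp != 0xFFFE) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- .u32(raw, pos + 8L); hdr <- 12L
      } else {
        len <- .u16(raw, pos + 6L); hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- .u32(raw, pos + 4L); hdr <- 8L
    }
    tag <- sprintf("%04x,%04x", grp, ele)
    if (len == 4294967295) {  # undefined length (sequence): skip to delimiter
      p <- pos + hdr
      repeat {
        if (p + 7L > n) stop("format error", call. = FALSE)
        if (.u16(raw, p) == 0xFFFE && .u16(raw, p + 2L) == 0xE0DD) {
          p <- p + 8L; break
        }
        p <- p + 1L
      }
      pos <- p
      next
    }
    val <- if (len > 0) raw[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
    out[[tag]] <- list(vr = vr, value = val)
    pos <- pos + hdr + len
  }
  attr(out, "end") <- pos
  out
}

.dcm_str <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(gsub("\\x00", "", rawToChar(el$value), useBytes = TRUE))
}
.dcm_ds <- function(el) {
  s <- .dcm_str(el)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
.dcm_us <- function(el) {
  if (is.null(el)) return(NULL)
  .u16(el$value, 1L)
}

# Read one DICOM file; returns header fields + pixel matrix [x, y] (stored values).
.read_dicom_slice <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("format error", call. = FALSE)
  meta <- .dcm_parse(raw, 133L, explicit = TRUE, only_group = 0x0002)
  ts <- .dcm_str(meta[["0002,0010"]])
  if (is.null(ts)) ts <- .TS_EXPLICIT
  if (!ts %in% c(.TS_IMPLICIT, .TS_EXPLICIT)) stop("format error", call. = FALSE)
  els <- .dcm_parse(raw, attr(meta, "end"), explicit = ts == .TS_EXPLICIT)
  rows <- .dcm_us(els[["0028,0010"]]); cols <- .dcm_us(els[["0028,0011"]])
  px <- els[["7fe0,0010"]]
  if (is.null(rows) || is.null(cols) || is.null(px)) stop("format error", call. = FALSE)
  bits <- .dcm_us(els[["0028,0100"]]); if (is.null(bits)) bits <- 16L
  if (bits != 16L) stop("format error", call. = FALSE)
  signed <- identical(.dcm_us(els[["0028,0103"]]), 1L)
  v <- readBin(px$value, "integer", n = rows * cols, size = 2L,
               signed = signed, endian = "little")
  if (!signed) v[v < 0] <- v[v < 0] + 65536  # readBin size=2 unsigned safety
  ipp <- .dcm_ds(els[["0020,0032"]])
  ps <- .dcm_ds(els[["0028,0030"]])
  slope <- .dcm_ds(els[["0028,1053"]]); if (is.null(slope)) slope <- 1
  inter <- .dcm_ds(els[["0028,1052"]]); if (is.null(inter)) inter <- 0
  list(series_uid = .dcm_str(els[["0020,000e"]]),
       ipp = ipp, pixel_spacing = ps,
       slice_thickness = .dcm_ds(els[["0018,0050"]]),
       slope = slope, intercept = inter,
       pixels = matrix(v, nrow = cols))   # DICOM rows are y; columns (x) fastest
}

# Assemble a sorted, calibrated CTVolume from all DICOM files in a directory.
.read_dicom_dir <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 2) stop("inconsistent series", call. = FALSE)
  slices <- lapply(files, .read_dicom_slice)
  uids <- unique(vapply(slices, function(s) s$series_uid %||% "", ""))
  if (length(uids) > 1) stop("multiple series", call. = FALSE)
  z <- vapply(slices, function(s) s$ipp[3], 0)
  if (anyNA(z)) stop("inconsistent series", call. = FALSE)
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  dz <- diff(z)
  if (any(dz < 1e-9)) stop("inconsistent series", call. = FALSE)  # duplicates
  if (max(dz) - min(dz) > 0.01 * mean(dz))
    stop("inconsistent series", call. = FALSE)                    # missing slice
  zsp <- mean(dz)
  thick <- slices[[1]]$slice_thickness
  if (!is.null(thick) && is.finite(thick) &&
      abs(zsp - thick) > 0.1 * thick)
    warning(sprintf(
      "slice spacing from positions (%.3f mm) differs >10%% from declared thickness (%.3f mm); using positions",
      zsp, thick))
  ps <- slices[[1]]$pixel_spacing  # (row spacing = y, column spacing = x)
  d <- dim(slices[[1]]$pixels)
  vox <- array(0, dim = c(d[1], d[2], length(slices)))
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    if (!identical(dim(s$pixels), d)) stop("inconsistent series", call. = FALSE)
    vox[, , i] <- s$pixels * s$slope + s$intercept
  }
  vox <- pmin(pmax(vox, -1024), 3071)
  ipp1 <- slices[[1]]$ipp
  CTVolume(vox, spacing = c(ps[2], ps[1], zsp),
           origin = c(ipp1[1], ipp1[2], ipp1[3]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- minimal writer (fixture construction and round-trip tests) ---------------

.dcm_pad <- function(x, pad = as.raw(0x20)) {
  if (length(x) %% 2 == 1) c(x, pad) else x
}

.dcm_element <- function(group, element, vr, value_raw) {
  tag <- writeBin(as.integer(c(group, element)), raw(), size = 2L,
                  endian = "little")
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(tag, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4L, endian = "little"), value_raw)
  } else {
    c(tag, charToRaw(vr),
      writeBin(length(value_raw), raw(), size = 2L, endian = "little"), value_raw)
  }
}

.dcm_el_str <- function(group, element, vr, s, pad = as.raw(0x20)) {
  .dcm_element(group, element, vr, .dcm_pad(charToRaw(s), pad))
}
.dcm_el_us <- function(group, element, v) {
  .dcm_element(group, element, "US", writeBin(as.integer(v), raw(), size = 2L,
                                              endian = "little"))
}

# Write one axial CT slice (int16 stored values, explicit VR little endian).
.write_dicom_slice <- function(path, pixels, ipp, pixel_spacing_yx,
                               slice_thickness, series_uid,
                               rescale_slope = 1, rescale_intercept = -1024) {
  nxp <- nrow(pixels); nyp <- ncol(pixels)
  ds <- function(v) paste(format(v, scientific = FALSE, trim = TRUE), collapse = "\\")
  body <- c(
    .dcm_el_str(0x0008, 0x0060, "CS", "CT"),
    .dcm_el_str(0x0018, 0x0050, "DS", ds(slice_thickness)),
    .dcm_el_str(0x0020, 0x000E, "UI", series_uid, pad = as.raw(0)),
    .dcm_el_str(0x0020, 0x0032, "DS", ds(ipp)),
    .dcm_el_str(0x0020, 0x0037, "DS", ds(c(1, 0, 0, 0, 1, 0))),
    .dcm_el_us(0x0028, 0x0010, nyp),            # Rows (y)
    .dcm_el_us(0x0028, 0x0011, nxp),            # Columns (x)
    .dcm_el_str(0x0028, 0x0030, "DS", ds(pixel_spacing_yx)),
    .dcm_el_us(0x0028, 0x0100, 16),
    .dcm_el_us(0x0028, 0x0101, 16),
    .dcm_el_us(0x0028, 0x0102, 15),
    .dcm_el_us(0x0028, 0x0103, 1),
    .dcm_el_str(0x0028, 0x1052, "DS", ds(rescale_intercept)),
    .dcm_el_str(0x0028, 0x1053, "DS", ds(rescale_slope)),
    .dcm_element(0x7FE0, 0x0010, "OW",
                 writeBin(as.integer(as.vector(pixels)), raw(), size = 2L,
                          endian = "little"))
  )
  ts <- .dcm_el_str(0x0002, 0x0010, "UI", .TS_EXPLICIT, pad = as.raw(0))
  meta <- c(.dcm_element(0x0002, 0x0000, "UL",
                         writeBin(length(ts), raw(), size = 4L, endian = "little")),
            ts)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}
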