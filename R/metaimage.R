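# MetaImage (.mhd header + raw, or single-file .mha) reader/writer for
# little-endian scalar volumes. Order on disk is x fastest, matching R arrays.

.met_types <- c(MET_CHAR = "integer", MET_UCHAR = "integer",
                MET_SHORT = "integer", MET_USHORT = "integer",
                MET_INT = "integer", MET_FLOAT = "double", MET_DOUBLE = "double")
.met_sizes <- c(MET_CHAR = 1L, MET_UCHAR = 1L, MET_SHORT = 2L, MET_USHORT = 2L,
                MET_INT = 4L, MET_FLOAT = 4L, MET_DOUBLE = 8L)

.read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  data_offset <- 0L
  repeat {
    line <- character(0)
    ch <- readBin(con, "raw", 1L)
    while (length(ch) == 1 && ch != as.raw(10L)) {
      line <- c(line, rawToChar(ch))
      ch <- readBin(con, "raw", 1L)
    }
    line <- trimws(paste(line, collapse = ""))
    if (!nzchar(line)) break
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("format error", call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (is.null(hdr$DimSize) || is.null(hdr$ElementType) ||
      is.null(hdr$ElementDataFile)) stop("format error", call. = FALSE)
  if (!is.null(hdr$CompressedData) && tolower(hdr$CompressedData) == "true")
    stop("format error", call. = FALSE)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (length(dims) != 3) stop("format error", call. = FALSE)
  sp <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  orig <- hdr$Offset %||% hdr$Position
  orig <- if (!is.null(orig)) as.numeric(strsplit(orig, "\\s+")[[1]]) else c(0, 0, 0)
  type <- hdr$ElementType
  if (!type %in% names(.met_types)) stop("format error", call. = FALSE)
  n <- prod(dims)
  if (tolower(hdr$ElementDataFile) == "local") {
    v <- readBin(con, .met_types[[type]], n = n, size = .met_sizes[[type]],
                 signed = !type %in% c("MET_UCHAR", "MET_USHORT"),
                 endian = "little")
  } else {
    rawpath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(rawpath)) stop("format error", call. = FALSE)
    v <- readBin(rawpath, .met_types[[type]], n = n, size = .met_sizes[[type]],
                 signed = !type %in% c("MET_UCHAR", "MET_USHORT"),
                 endian = "little")
  }
  if (length(v) != n) stop("format error", call. = FALSE)
  vox <- array(as.numeric(v), dim = dims)
  vox <- pmin(pmax(vox, -1024), 3071)
  CTVolume(vox, spacing = sp, origin = orig)
}

.write_metaimage <- function(ct, path) {
  d <- dim(voxels(ct))
  hdr <- paste0(
    "ObjectType = Image\n", "NDims = 3\n", "BinaryData = True\n",
    "BinaryDataByteOrderMSB = False\n",
    sprintf("DimSize = %d %d %d\n", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %g %g %g\n", spacing(ct)[1], spacing(ct)[2],
            spacing(ct)[3]),
    sprintf("Offset = %g %g %g\n", origin(ct)[1], origin(ct)[2], origin(ct)[3]),
    "ElementType = MET_SHORT\n", "ElementDataFile = LOCAL\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  writeBin(as.integer(round(as.vector(voxels(ct)))), con, size = 2L,
           endian = "little")
  invisible(path)
}
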