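# Minimal DICOM single-series reader: uncompressed little-endian transfer
# syntaxes only (implicit VR 1.2.840.10008.1.2 and explicit VR
# 1.2.840.10008.1.2.1), which covers CT series exported without
# compression. Sequences with undefined length are rejected.

.dcmTag <- function(group, element) sprintf("%04X,%04X", group, element)

.dcmLongVRs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

# Parse one element at offset `pos` (1-based) of raw vector `raw`.
.dcmReadElement <- function(raw, pos, explicit) {
  u16 <- function(at) readBin(raw[at:(at + 1)], "integer", size = 2,
                              endian = "little", signed = FALSE)
  u32 <- function(at) readBin(raw[at:(at + 3)], "numeric", size = 4,
                              endian = "little") # placeholder, not used
  group <- u16(pos); element <- u16(pos + 2)
  if (explicit) {
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% .dcmLongVRs) {
      len <- readBin(raw[(pos + 8):(pos + 11)], "integer", size = 4,
                     endian = "little")
      valAt <- pos + 12
    } else {
      len <- u16(pos + 6)
      valAt <- pos + 8
    }
  } else {
    vr <- NA_character_
    len <- readBin(raw[(pos + 4):(pos + 7)], "integer", size = 4,
                   endian = "little")
    valAt <- pos + 8
  }
  if (len < 0)
    stop("DICOM element with undefined length (sequences are not supported)")
  value <- if (len > 0) raw[valAt:(valAt + len - 1)] else raw(0)
  list(group = group, element = element, vr = vr, value = value,
       nextPos = valAt + len)
}

.dcmString <- function(v) trimws(rawToChar(v[v != as.raw(0)]))
.dcmNumeric <- function(v)
  as.numeric(strsplit(.dcmString(v), "\\\\")[[1]])
.dcmUS <- function(v) readBin(v, "integer", size = 2, endian = "little",
                              signed = FALSE)

# Read one DICOM file; returns the tags needed to assemble a CT volume.
.dcmReadFile <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  pos <- 1L
  explicit <- TRUE
  ts <- NULL
  if (length(raw) > 132 && rawToChar(raw[129:132]) == "DICM") {
    pos <- 133L
    # file meta group (0002) is always explicit VR little endian
    while (pos <= length(raw)) {
      el <- .dcmReadElement(raw, pos, explicit = TRUE)
      if (el$group != 2L) break
      if (el$element == 0x0010) ts <- .dcmString(el$value)
      pos <- el$nextPos
    }
    if (is.null(ts)) stop("DICOM meta header lacks a transfer syntax UID")
    if (ts == "1.2.840.10008.1.2") explicit <- FALSE
    else if (ts != "1.2.840.10008.1.2.1")
      stop("unsupported transfer syntax: ", ts)
  } else {
    explicit <- FALSE  # headerless implicit-VR file
  }

  out <- list()
  while (pos + 7 <= length(raw)) {
    el <- .dcmReadElement(raw, pos, explicit)
    tag <- .dcmTag(el$group, el$element)
    out[[tag]] <- el
    pos <- el$nextPos
  }

  gets <- function(tag) if (!is.null(out[[tag]])) .dcmString(out[[tag]]$value) else NULL
  getn <- function(tag) if (!is.null(out[[tag]])) .dcmNumeric(out[[tag]]$value) else NULL
  getu <- function(tag) if (!is.null(out[[tag]])) .dcmUS(out[[tag]]$value) else NULL

  rows <- getu("0028,0010"); cols <- getu("0028,0011")
  bits <- getu("0028,0100"); pixrep <- getu("0028,0103")
  if (is.null(rows) || is.null(cols)) stop("DICOM file lacks Rows/Columns")
  if (is.null(bits)) bits <- 16L
  slope <- getn("0028,1053"); intercept <- getn("0028,1052")
  if (is.null(slope) || is.null(intercept))
    stop("DICOM file lacks RescaleSlope/RescaleIntercept; cannot convert to HU")
  pd <- out[["7FE0,0010"]]
  if (is.null(pd)) stop("DICOM file lacks PixelData")
  signed <- !is.null(pixrep) && pixrep == 1
  vals <- readBin(pd$value, "integer", n = rows * cols, size = bits / 8,
                  endian = "little", signed = if (bits == 8) signed else signed)
  if (!signed && bits == 16) {
    # readBin cannot read unsigned 16-bit directly
    vals <- readBin(pd$value, "integer", n = rows * cols, size = 2,
                    endian = "little", signed = TRUE)
    vals <- ifelse(vals < 0, vals + 65536, vals)
  }
  # pixel order: column (x) fastest within each row (y)
  mat <- matrix(vals * slope + intercept, nrow = cols, ncol = rows)

  ipp <- getn("0020,0032")
  iop <- getn("0020,0037")
  list(pixels = mat,
       series = gets("0020,000E"),
       instance = getn("0020,0013"),
       position = ipp, orientation = iop,
       sliceLocation = getn("0020,1041"),
       pixelSpacing = getn("0028,0030"))
}

# Assemble a sorted single-series volume from a directory of DICOM slices.
readDicomSeries <- function(dir, gapTolerance = 0.01) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no files in DICOM directory: ", dir)
  slices <- lapply(files, .dcmReadFile)

  series <- unique(vapply(slices, function(s)
    if (is.null(s$series)) NA_character_ else s$series, character(1)))
  series <- series[!is.na(series)]
  if (length(series) > 1)
    stop("directory contains more than one DICOM series: ",
         paste(series, collapse = ", "))

  # sort by position projected on the slice normal; fall back to
  # SliceLocation, then InstanceNumber
  key <- vapply(slices, function(s) {
    if (!is.null(s$position) && !is.null(s$orientation) &&
        length(s$orientation) == 6) {
      r <- s$orientation[1:3]; c_ <- s$orientation[4:6]
      nrm <- c(r[2] * c_[3] - r[3] * c_[2],
               r[3] * c_[1] - r[1] * c_[3],
               r[1] * c_[2] - r[2] * c_[1])
      sum(s$position * nrm)
    } else if (!is.null(s$sliceLocation)) s$sliceLocation
    else if (!is.null(s$instance)) s$instance
    else NA_real_
  }, numeric(1))
  if (any(is.na(key)))
    stop("DICOM slices lack position/instance information for sorting")
  ord <- order(key)
  slices <- slices[ord]; key <- key[ord]

  shp <- vapply(slices, function(s) dim(s$pixels), integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    stop("DICOM slices have inconsistent matrix sizes")

  dz <- 1
  if (length(key) > 1) {
    gaps <- diff(key)
    if (any(gaps <= 0)) stop("duplicate or unsorted DICOM slice positions")
    if ((max(gaps) - min(gaps)) > gapTolerance * mean(gaps))
      stop("non-uniform DICOM slice spacing beyond tolerance")
    dz <- mean(gaps)
  }
  ps <- slices[[1]]$pixelSpacing
  if (is.null(ps) || length(ps) != 2) ps <- c(1, 1)
  # PixelSpacing is (row spacing, column spacing) = (dy, dx)
  spacing <- c(ps[2], ps[1], dz)

  vox <- array(0, c(dim(slices[[1]]$pixels), length(slices)))
  for (i in seq_along(slices)) vox[, , i] <- slices[[i]]$pixels
  vol <- ctVolume(vox, spacing)
  if (min(vox) >= 0)
    warning("DICOM volume contains no negative HU values (no air?)")
  vol
}
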