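# Byte-level writer for tiny single-frame DICOM files (explicit VR little
# endian), used to exercise the DICOM series reader without binary
# fixtures in the repository.

.dcmPadString <- function(s) {
  if (nchar(s) %% 2 == 1) s <- paste0(s, " ")
  charToRaw(s)
}

.dcmShortElement <- function(group, element, vr, valueRaw) {
  con <- raw(0)
  c(con,
    writeBin(as.integer(group), raw(), size = 2, endian = "little"),
    writeBin(as.integer(element), raw(), size = 2, endian = "little"),
    charToRaw(vr),
    writeBin(length(valueRaw), raw(), size = 2, endian = "little"),
    valueRaw)
}

.dcmLongElement <- function(group, element, vr, valueRaw) {
  c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
    writeBin(as.integer(element), raw(), size = 2, endian = "little"),
    charToRaw(vr), as.raw(c(0, 0)),
    writeBin(length(valueRaw), raw(), size = 4, endian = "little"),
    valueRaw)
}

.dcmUS <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")

# mat is indexed [x, y]; stored values are uint16; HU = value*slope + intercept
writeDicomSlice <- function(path, mat, series = "1.2.3.4", instance = 1,
                            position = c(0, 0, 0),
                            orientation = c(1, 0, 0, 0, 1, 0),
                            pixelSpacing = c(0.426, 0.426),
                            slope = 1, intercept = -1024) {
  stored <- as.integer(round((mat - intercept) / slope))
  stopifnot(all(stored >= 0), all(stored < 65536))
  pix <- writeBin(as.vector(stored), raw(), size = 2, endian = "little")

  out <- c(raw(128), charToRaw("DICM"),
    .dcmShortElement(0x0002, 0x0010, "UI", .dcmPadString("1.2.840.10008.1.2.1")),
    .dcmShortElement(0x0008, 0x0060, "CS", .dcmPadString("CT")),
    .dcmShortElement(0x0020, 0x000E, "UI", .dcmPadString(series)),
    .dcmShortElement(0x0020, 0x0013, "IS", .dcmPadString(as.character(instance))),
    .dcmShortElement(0x0020, 0x0032, "DS",
                     .dcmPadString(paste(position, collapse = "\\"))),
    .dcmShortElement(0x0020, 0x0037, "DS",
                     .dcmPadString(paste(orientation, collapse = "\\"))),
    .dcmShortElement(0x0028, 0x0010, "US", .dcmUS(ncol(mat))),   # Rows (y)
    .dcmShortElement(0x0028, 0x0011, "US", .dcmUS(nrow(mat))),   # Columns (x)
    .dcmShortElement(0x0028, 0x0030, "DS",
                     .dcmPadString(paste(rev(pixelSpacing), collapse = "\\"))),
    .dcmShortElement(0x0028, 0x0100, "US", .dcmUS(16)),
    .dcmShortElement(0x0028, 0x0103, "US", .dcmUS(0)),
    .dcmShortElement(0x0028, 0x1052, "DS", .dcmPadString(as.character(intercept))),
    .dcmShortElement(0x0028, 0x1053, "DS", .dcmPadString(as.character(slope))),
    .dcmLongElement(0x7FE0, 0x0010, "OW", pix))
  writeBin(out, path)
  invisible(path)
}

writeDicomSeries <- function(dir, vol, spacing = c(0.426, 0.426, 5),
                             series = "1.2.3.4", slope = 1,
                             intercept = -1024) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (z in seq_len(dim(vol)[3])) {
    writeDicomSlice(file.path(dir, sprintf("slice%03d.dcm", z)),
                    vol[, , z], series = series, instance = z,
                    position = c(0, 0, (z - 1) * spacing[3]),
                    pixelSpacing = spacing[1:2],
                    slope = slope, intercept = intercept)
  }
  invisible(dir)
}
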