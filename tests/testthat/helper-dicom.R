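# Minimal DICOM writer used to build test fixtures in code (explicit VR
# little endian, 16-bit pixel data). Written independently of the package's
# reader so round-trips exercise both directions.

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.elem <- function(group, elem, vr, bytes) {
  if (length(bytes) %% 2 == 1) bytes <- c(bytes, as.raw(0))
  hdr <- c(.u16(group), .u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "UT", "UN", "SQ")) {
    c(hdr, as.raw(c(0, 0)), .u32(length(bytes)), bytes)
  } else {
    c(hdr, .u16(length(bytes)), bytes)
  }
}

.strElem <- function(group, elem, vr, s) .elem(group, elem, vr, charToRaw(s))

writeDicomSlice <- function(path, pixels, z, slope = 1, intercept = 0,
                            pixelSpacing = c(1, 1), signed = TRUE) {
  # pixels: matrix indexed [x (column), y (row)], stored raw values
  rows <- ncol(pixels); cols <- nrow(pixels)
  px <- writeBin(as.integer(as.vector(pixels)), raw(), size = 2,
                 endian = "little")
  meta <- c(.elem(0x0002, 0x0010, "UI",
                  charToRaw("1.2.840.10008.1.2.1")))
  body <- c(
    .strElem(0x0020, 0x0032, "DS", sprintf("0\\0\\%g", z)),
    .elem(0x0028, 0x0010, "US", .u16(rows)),
    .elem(0x0028, 0x0011, "US", .u16(cols)),
    .strElem(0x0028, 0x0030, "DS",
             sprintf("%g\\%g", pixelSpacing[1], pixelSpacing[2])),
    .elem(0x0028, 0x0100, "US", .u16(16)),
    .elem(0x0028, 0x0103, "US", .u16(if (signed) 1 else 0)),
    .strElem(0x0028, 0x1052, "DS", sprintf("%g", intercept)),
    .strElem(0x0028, 0x1053, "DS", sprintf("%g", slope)),
    .elem(0x7FE0, 0x0010, "OW", px))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

writeDicomSeries <- function(dir, raw3d, slope = 1, intercept = 0,
                             pixelSpacing = c(1, 1), dz = 2.5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(raw3d)
  for (k in seq_len(d[3]))
    writeDicomSlice(file.path(dir, sprintf("slice%03d.dcm", k)),
                    raw3d[, , k], z = (k - 1) * dz, slope = slope,
                    intercept = intercept, pixelSpacing = pixelSpacing)
  invisible(dir)
}
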