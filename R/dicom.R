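# Minimal DICOM series reader (explicit VR, little endian, uncompressed
# 16-bit pixel data). Covers the header subset needed to reconstruct a CT
# volume in HU: matrix size, pixel representation, rescale slope/intercept,
# pixel spacing, slice positions. No R DICOM package is available in the
# supported dependency set, so this is implemented natively.

# 4-byte-length VRs per PS3.5; everything else uses 2-byte lengths
.dicom_long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

.read_uint16 <- function(raw, off) {
  as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
}

# parse one explicit-VR dataset, returning the tags we care about
.parse_dicom <- function(raw) {
  n <- length(raw)
  if (n < 132L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file")
  off <- 132L
  out <- list()
  repeat {
    if (off + 8L > n) break
    group <- .read_uint16(raw, off)
    elem <- .read_uint16(raw, off + 2L)
    vr <- rawToChar(raw[(off + 5L):(off + 6L)])
    if (vr %in% .dicom_long_vrs) {
      len <- sum(as.integer(raw[(off + 9L):(off + 12L)]) * 256^(0:3))
      hdr <- 12L
    } else {
      len <- .read_uint16(raw, off + 6L)
      hdr <- 8L
    }
    body <- raw[(off + hdr + 1L):(off + hdr + len)]
    key <- sprintf("%04x,%04x", group, elem)
    out[[key]] <- list(vr = vr, bytes = body)
    off <- off + hdr + len
    if (key == "7fe0,0010") break
  }
  out
}

.tag_str <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$bytes))
}

.tag_us <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NULL)
  .read_uint16(el$bytes, 0L)
}

#' Read a DICOM series directory into a CTVolume
#'
#' Reads every parseable DICOM file in `dir`, orders slices by the z
#' component of Image Position (Patient), applies the rescale
#' slope/intercept to obtain HU, and stacks the slices into a 3D volume.
#' Only explicit-VR little-endian, uncompressed 16-bit data are supported.
#'
#' @param dir directory containing one DICOM series.
#' @param label optional class label.
#' @return a [CTVolume].
#' @export
readDicomSeries <- function(dir, label = NA_integer_) {
  if (!dir.exists(dir)) stop("readDicomSeries: no such directory: ", dir)
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("readDicomSeries: empty directory")
  slices <- lapply(files, function(f) {
    raw <- readBin(f, "raw", file.info(f)$size)
    tags <- tryCatch(.parse_dicom(raw), error = function(e) NULL)
    if (is.null(tags) || is.null(tags[["7fe0,0010"]])) return(NULL)
    ts <- .tag_str(tags, "0002,0010")
    if (!is.null(ts) && ts != "1.2.840.10008.1.2.1")
      stop("readDicomSeries: unsupported transfer syntax: ", ts)
    rows <- .tag_us(tags, "0028,0010")
    cols <- .tag_us(tags, "0028,0011")
    bits <- .tag_us(tags, "0028,0100")
    if (is.null(bits) || bits != 16L)
      stop("readDicomSeries: only 16-bit pixel data supported")
    signed <- identical(.tag_us(tags, "0028,0103"), 1L)
    slope <- as.numeric(.tag_str(tags, "0028,1053") %||% "1")
    inter <- as.numeric(.tag_str(tags, "0028,1052") %||% "0")
    ipp <- .tag_str(tags, "0020,0032")
    z <- if (is.null(ipp)) NA_real_ else
      as.numeric(strsplit(ipp, "\\\\")[[1]])[3]
    ps <- .tag_str(tags, "0028,0030")
    ps <- if (is.null(ps)) c(1, 1) else as.numeric(strsplit(ps, "\\\\")[[1]])
    px <- readBin(tags[["7fe0,0010"]]$bytes, "integer", n = rows * cols,
                  size = 2L, signed = signed, endian = "little")
    if (!signed) px[px < 0] <- px[px < 0] + 65536L
    # pixel data is row-major: x (column index) varies fastest
    mat <- matrix(slope * px + inter, nrow = cols, ncol = rows)
    list(mat = mat, z = z, ps = ps)
  })
  slices <- Filter(Negate(is.null), slices)
  if (length(slices) == 0L) stop("readDicomSeries: no DICOM images found")
  zs <- vapply(slices, `[[`, numeric(1), "z")
  ord <- order(zs)
  slices <- slices[ord]
  zs <- zs[ord]
  d <- dim(slices[[1]]$mat)
  vox <- array(NA_real_, c(d[1], d[2], length(slices)))
  for (i in seq_along(slices)) vox[, , i] <- slices[[i]]$mat
  dz <- if (length(zs) > 1L && all(is.finite(zs))) abs(zs[2] - zs[1]) else 1
  ps <- slices[[1]]$ps  # (row spacing, column spacing) = (dy, dx)
  CTVolume(vox, spacing = c(ps[2], ps[1], dz), label = label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
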