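#' Read a CT volume from NIfTI or a DICOM series directory
#'
#' Voxels are returned in Hounsfield units with spacing taken from the
#' header. Axis order is (x, y, z) with z the axial slice index, voxel
#' indices 0-based in all coordinate conventions documented here. For a
#' DICOM series, slices are ordered by the z component of the image
#' position and the stored values are rescaled as `slope * raw + intercept`.
#'
#' @param path file path (NIfTI) or directory (DICOM series).
#' @param format "nifti" or "dicom_dir".
#' @param label optional class label attached to the volume.
#' @return a [CTVolume].
#' @export
readCTVolume <- function(path, format = c("nifti", "dicom_dir"),
                         label = NA_integer_) {
  format <- match.arg(format)
  if (format == "nifti") {
    if (!file.exists(path)) stop("readCTVolume: no such file: ", path)
    img <- RNifti::readNifti(path)
    a <- structure(as.vector(img), dim = dim(img))
    if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1]
    if (length(dim(a)) != 3L)
      stop("readCTVolume: image is not 3D (dims: ",
           paste(dim(a), collapse = "x"), ")")
    sp <- RNifti::pixdim(img)[1:3]
    CTVolume(a, spacing = sp, label = label)
  } else {
    readDicomSeries(path, label = label)
  }
}

#' Write a CT volume to NIfTI-1
#'
#' @param v a [CTVolume].
#' @param path output file (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeCTVolume <- function(v, path) {
  stopifnot(is(v, "CTVolume"))
  img <- RNifti::asNifti(v@voxels)
  RNifti::pixdim(img) <- v@spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write a texture map set as NIfTI files
#'
#' One file per feature map, named `<prefix><FeatureName>.nii.gz`.
#'
#' @param tms a [TextureMapSet].
#' @param dir output directory.
#' @param spacing voxel spacing to record, mm.
#' @param prefix file-name prefix.
#' @return named character vector of paths, invisibly.
#' @export
writeTextureMaps <- function(tms, dir, spacing = c(1, 1, 1), prefix = "") {
  stopifnot(is(tms, "TextureMapSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(tms@maps), function(nm) {
    p <- file.path(dir, paste0(prefix, nm, ".nii.gz"))
    writeCTVolume(CTVolume(tms@maps[[nm]], spacing = spacing), p)
    p
  }, character(1))
  invisible(paths)
}
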