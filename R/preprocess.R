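#' Min-max normalize an array to [0, 1]
#'
#' Maps the minimum to 0 and the maximum to 1. A constant array maps to all
#' zeros so that degenerate inputs stay usable downstream.
#'
#' @param a a numeric array (any shape).
#' @return array of the same shape with values in [0, 1].
#' @examples
#' minMaxNormalize(c(-1, 0, 3))
#' @export
minMaxNormalize <- function(a) {
  if (any(!is.finite(a))) stop("minMaxNormalize: array contains NaN/Inf")
  lo <- min(a); hi <- max(a)
  if (hi == lo) return(array(0, dim = if (is.null(dim(a))) length(a) else dim(a)) * a)
  (a - lo) / (hi - lo)
}

#' Clip intensities to a window
#'
#' @param a numeric array.
#' @param window numeric(2), (low, high).
#' @return clipped array.
#' @export
clipWindow <- function(a, window = c(-1000, 400)) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  pmin(pmax(a, window[1]), window[2])
}

#' Axial center crop
#'
#' Retains the central `fraction` of the first two (in-plane) axes; the
#' axial (z) extent is kept whole.
#'
#' @param a 3D numeric array.
#' @param fraction fraction of each in-plane axis to keep, in (0, 1].
#' @return cropped 3D array.
#' @export
centerCrop <- function(a, fraction = 0.75) {
  stopifnot(length(dim(a)) == 3L, fraction > 0, fraction <= 1)
  d <- dim(a)
  keep <- pmax(1L, as.integer(round(d[1:2] * fraction)))
  lo <- (d[1:2] - keep) %/% 2L + 1L
  a[lo[1]:(lo[1] + keep[1] - 1L), lo[2]:(lo[2] + keep[2] - 1L), , drop = FALSE]
}

#' Trilinear resize of a 3D array
#'
#' Deterministic trilinear interpolation onto a target grid with
#' center-aligned sampling and edge clamping; constant arrays are
#' resize-invariant.
#'
#' @param a 3D numeric array.
#' @param targetShape integer(3).
#' @return resized array of dim `targetShape`.
#' @export
resizeVolume <- function(a, targetShape) {
  stopifnot(length(dim(a)) == 3L, length(targetShape) == 3L)
  resize_trilinear_cpp(a, as.integer(targetShape))
}

#' Preprocess a CT volume: crop, clip, resize
#'
#' Center-crops axially to focus the lung region, clips intensities to the
#' lung window, and resamples trilinearly to the target grid. Clipping is
#' applied before resampling to avoid interpolating values outside the
#' window. The label and (rescaled) voxel spacing are carried through.
#'
#' @param v a [CTVolume].
#' @param spec a [PreprocessSpec].
#' @return a [CTVolume] of shape `spec@targetShape`.
#' @examples
#' v <- CTVolume(array(rnorm(64 * 64 * 16, -500, 300), c(64, 64, 16)))
#' out <- preprocessVolume(v, PreprocessSpec(targetShape = c(32, 32, 16)))
#' dim(out)
#' @export
preprocessVolume <- function(v, spec = PreprocessSpec()) {
  stopifnot(is(v, "CTVolume"), is(spec, "PreprocessSpec"))
  validObject(v); validObject(spec)
  d <- dim(v@voxels)
  if (any(d < 2L)) stop("preprocessVolume: input must have >= 2 voxels per axis")
  a <- centerCrop(v@voxels, spec@cropFraction)
  a <- clipWindow(a, spec@window)
  a <- resizeVolume(a, spec@targetShape)
  # physical extent of the cropped grid divided by the output grid
  newSpacing <- v@spacing * c(dim(v@voxels)[1:2] * spec@cropFraction,
                              dim(v@voxels)[3]) / spec@targetShape
  CTVolume(a, spacing = newSpacing, label = v@label)
}
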