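#' Gaussian smoothing of a 3D array
#'
#' Separable Gaussian kernel applied as a full 3D convolution with
#' edge-replicated borders; used to build correlated random fields.
#'
#' @param a 3D numeric array.
#' @param sigma kernel standard deviation in voxels; <= 0 returns `a`.
#' @return smoothed array, same shape.
#' @export
gaussSmooth3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  h <- max(1L, as.integer(ceiling(2.5 * sigma)))
  k1 <- dnorm(seq(-h, h), sd = sigma)
  k1 <- k1 / sum(k1)
  kern <- outer(outer(k1, k1), k1)
  d <- dim(a)
  ix <- pmin(pmax(seq(1 - h, d[1] + h), 1L), d[1])
  iy <- pmin(pmax(seq(1 - h, d[2] + h), 1L), d[2])
  iz <- pmin(pmax(seq(1 - h, d[3] + h), 1L), d[3])
  ap <- a[ix, iy, iz]
  dim(ap) <- c(dim(ap), 1L, 1L)
  k <- 2L * h + 1L
  dim(kern) <- c(k, k, k, 1L, 1L)
  out <- conv3d_fwd_cpp(ap, kern, 0, 1L, 0L)
  array(out, d)
}

# correlated field with unit-normalized local contrast: smoothed white
# noise scaled so adjacent-voxel differences have standard deviation
# `contrast`; the correlation length then controls only the arrangement
localContrastField <- function(d, sigma, contrast) {
  f <- gaussSmooth3d(array(rnorm(prod(d)), d), sigma)
  nd <- sd(f[-1, , ] - f[-d[1], , ])
  if (nd > 0) f <- f / nd * contrast
  f
}

#' Generate a labeled synthetic texture phantom
#'
#' Produces one 3D volume in HU-like intensities emulating one of two
#' classes that differ in local gray-level co-occurrence structure:
#' \describe{
#'   \item{diffuse_texture (label 1)}{a correlated Gaussian random field
#'     (smoothed white noise rescaled to `textureSd`, correlation length
#'     `textureCorrelationLength` voxels) over the background mean -- a
#'     surrogate for diffuse parenchymal texture.}
#'   \item{focal_nodule (label 0)}{a weakly correlated background field
#'     (correlation length `backgroundCorrelationLength`, sd
#'     `backgroundSd`, so both classes have comparable local gray-level
#'     spread) plus `noduleCount` hyperintense spheres with a soft
#'     (sigmoid) edge -- a surrogate for focal lesions. The diffuse class
#'     additionally sits `diffuseShift` HU above the background mean,
#'     emulating the raised attenuation of diffuse infiltrates.}
#' }
#' White noise of `noiseSd` HU is added to both classes. The seed fixes
#' the volume bit-exactly; the caller's RNG state is untouched.
#'
#' @param spec a [PhantomSpec].
#' @return list with `volume` (a labeled [CTVolume]), `noduleMask`
#'   (logical array; all-FALSE for the diffuse class) and `spec`.
#' @examples
#' ph <- makePhantom(PhantomSpec(class = "focal_nodule", seed = 7))
#' volumeLabel(ph$volume); sum(ph$noduleMask)
#' @export
makePhantom <- function(spec = PhantomSpec()) {
  validObject(spec)
  d <- spec@shape
  withSeed(spec@seed, {
    mask <- array(FALSE, d)
    if (spec@phantomClass == "diffuse_texture") {
      field <- localContrastField(d, spec@textureCorrelationLength,
                                  spec@textureSd)
      v <- spec@backgroundMean + spec@diffuseShift + field
      label <- 1L
    } else {
      bg <- localContrastField(d, spec@backgroundCorrelationLength,
                               spec@backgroundSd)
      v <- spec@backgroundMean + bg
      if (spec@noduleCount > 0L) {
        r <- spec@noduleRadius
        gx <- seq_len(d[1]); gy <- seq_len(d[2]); gz <- seq_len(d[3])
        for (i in seq_len(spec@noduleCount)) {
          ctr <- vapply(d, function(dd)
            runif(1, r + 1, dd - r), numeric(1))
          dist <- sqrt(outer(outer((gx - ctr[1])^2, (gy - ctr[2])^2, "+"),
                             (gz - ctr[3])^2, "+"))
          v <- v + spec@noduleContrast / (1 + exp((dist - r) / 0.7))
          mask <- mask | (dist <= r)
        }
      }
      label <- 0L
    }
    if (spec@noiseSd > 0)
      v <- v + array(rnorm(prod(d), sd = spec@noiseSd), d)
    list(volume = CTVolume(v, label = label), noduleMask = mask,
         spec = spec)
  })
}

#' Generate a balanced labeled phantom cohort
#'
#' `nPerClass` phantoms of each class with per-volume seeds derived from
#' the master seed, plus a manifest. The `regime` presets set the class
#' effect size: `"easy"` uses the default parameters (separability by
#' co-occurrence structure essentially guaranteed), `"hard"` shrinks the
#' texture contrast and raises the noise for ablation-ordering
#' experiments.
#'
#' @param nPerClass volumes per class.
#' @param shape volume shape.
#' @param seed master seed.
#' @param regime "easy" or "hard".
#' @param ... overrides passed to [PhantomSpec()] for both classes.
#' @return list: `volumes` (list of labeled [CTVolume]), `masks`,
#'   `manifest` (data.frame id, class, label, seed).
#' @export
makeCohort <- function(nPerClass, shape = c(32L, 32L, 16L), seed = 1L,
                       regime = c("easy", "hard"), ...) {
  regime <- match.arg(regime)
  stopifnot(nPerClass >= 1L)
  over <- list(...)
  if (regime == "hard")
    over <- modifyList(list(textureSd = 30, textureCorrelationLength = 2.1,
                            diffuseShift = 60, noduleContrast = 250,
                            noiseSd = 65), over)
  n <- 2L * nPerClass
  seeds <- deriveSeeds(seed, n)
  classes <- rep(c("diffuse_texture", "focal_nodule"), each = nPerClass)
  volumes <- vector("list", n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    args <- modifyList(list(shape = shape, class = classes[i],
                            seed = seeds[i]), over)
    ph <- makePhantom(do.call(PhantomSpec, args))
    volumes[[i]] <- ph$volume
    masks[[i]] <- ph$noduleMask
  }
  manifest <- data.frame(
    id = sprintf("phantom%03d", seq_len(n)), class = classes,
    label = ifelse(classes == "diffuse_texture", 1L, 0L), seed = seeds)
  list(volumes = volumes, masks = masks, manifest = manifest)
}

#' Prepare normalized network inputs from volumes
#'
#' Builds the two input channels of the ensemble for each volume: the CT
#' channel is the volume clipped to the lung window and min-max
#' normalized; the radiomics channel is the selected Haralick texture map
#' (computed on the window-clipped intensities by default) min-max
#' normalized per volume.
#'
#' @param volumes list of [CTVolume].
#' @param window lung window for clipping.
#' @param textureSpec a [TextureSpec]; by default gray levels are quantized
#'   over the fixed lung window so that bins are comparable across volumes.
#' @param mapName texture map used as the radiomics channel (default
#'   HaralickCorrelation).
#' @param textureOnClipped compute texture maps on window-clipped (TRUE,
#'   default) or raw intensities.
#' @return list: `ct`, `rad` (lists of normalized 3D arrays), `labels`.
#' @export
prepareEnsembleInputs <- function(volumes, window = c(-1000, 400),
                                  textureSpec = TextureSpec(quantizeRange = window),
                                  mapName = "HaralickCorrelation",
                                  textureOnClipped = TRUE) {
  stopifnot(mapName %in% HARALICK_FEATURES)
  ct <- list(); rad <- list()
  labels <- integer(length(volumes))
  for (i in seq_along(volumes)) {
    v <- volumes[[i]]
    clipped <- clipWindow(v@voxels, window)
    src <- if (textureOnClipped) clipped else v@voxels
    tms <- textureMaps(src, textureSpec)
    ct[[i]] <- minMaxNormalize(clipped)
    rad[[i]] <- minMaxNormalize(tms@maps[[mapName]])
    labels[i] <- v@label
  }
  list(ct = ct, rad = rad, labels = labels)
}
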