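#' The eight Haralick texture feature names
#'
#' Alphabetically ordered names of the gray-level co-occurrence statistics
#' computed by [textureMaps()] and [haralickFeatures()].
#'
#' @export
HARALICK_FEATURES <- c(
  "ClusterProminence", "ClusterShade", "Correlation", "Energy",
  "Entropy", "HaralickCorrelation", "Inertia", "InverseDifferenceMoment")

#' CTVolume: a 3D scalar volume with voxel spacing
#'
#' Container for a CT (or CT-like) volume. Voxels are stored as a 3D array
#' indexed (x, y, z) with z the axial slice index; intensities are in
#' Hounsfield units for raw CT input. The optional binary label follows the
#' package convention: 1 = diffuse-texture / pulmonary sarcoidosis-like
#' (positive class), 0 = focal-nodule / lung cancer-like.
#'
#' @slot voxels 3D numeric array (x, y, z).
#' @slot spacing numeric(3), voxel spacing in mm, strictly positive.
#' @slot label integer(1), 0, 1 or NA.
#'
#' @examples
#' v <- CTVolume(array(rnorm(8 * 8 * 4), c(8, 8, 4)), spacing = c(1, 1, 2.5))
#' dim(voxels(v))
#' @export CTVolume
#' @exportClass CTVolume
CTVolume <- setClass("CTVolume",
  slots = c(voxels = "array", spacing = "numeric", label = "integer"))

setValidity("CTVolume", function(object) {
  d <- dim(object@voxels)
  if (length(d) != 3L) return("voxels must be a 3D array")
  if (any(d < 1L)) return("all three dimensions must be >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) return("spacing must be 3 positive numbers")
  if (length(object@label) != 1L ||
      (!is.na(object@label) && !object@label %in% c(0L, 1L)))
    return("label must be 0, 1 or NA")
  TRUE
})

#' @describeIn CTVolume constructor
#' @param voxels 3D numeric array.
#' @param spacing voxel spacing in mm.
#' @param label optional class label (0, 1 or NA).
#' @export
CTVolume <- function(voxels, spacing = c(1, 1, 1), label = NA_integer_) {
  new("CTVolume", voxels = voxels, spacing = as.numeric(spacing),
      label = as.integer(label))
}

#' @rdname radct-generics
#' @export
setMethod("voxels", "CTVolume", function(x) x@voxels)

#' @rdname radct-generics
#' @export
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)

#' @rdname radct-generics
#' @export
setMethod("volumeLabel", "CTVolume", function(x) x@label)

#' @export
setMethod("dim", "CTVolume", function(x) dim(x@voxels))

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CTVolume %d x %d x %d, spacing %s mm, label %s\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x "),
              ifelse(is.na(object@label), "<none>", object@label)))
  rng <- range(object@voxels)
  cat(sprintf("  intensity range [%.1f, %.1f]\n", rng[1], rng[2]))
})

#' PreprocessSpec: crop / resize / window parameters
#'
#' Parameters for [preprocessVolume()]: the central fraction of each in-plane
#' axis retained by the axial center crop, the output grid, and the lung
#' window (HU) to which intensities are clipped before resampling.
#'
#' @slot targetShape integer(3), output grid (default 256 x 256 x 64).
#' @slot window numeric(2), (low, high) clip range in HU, default (-1000, 400).
#' @slot cropFraction numeric(1) in (0, 1], fraction of the in-plane extent
#'   kept by the center crop (default 0.75).
#'
#' @export PreprocessSpec
#' @exportClass PreprocessSpec
PreprocessSpec <- setClass("PreprocessSpec",
  slots = c(targetShape = "integer", window = "numeric",
            cropFraction = "numeric"))

setValidity("PreprocessSpec", function(object) {
  if (length(object@targetShape) != 3L || any(object@targetShape < 8L))
    return("targetShape must be 3 integers >= 8")
  if (length(object@window) != 2L || object@window[1] >= object@window[2])
    return("window must be (low, high) with low < high")
  if (object@cropFraction <= 0 || object@cropFraction > 1)
    return("cropFraction must be in (0, 1]")
  TRUE
})

#' @describeIn PreprocessSpec constructor
#' @param targetShape,window,cropFraction see slots.
#' @export
PreprocessSpec <- function(targetShape = c(256L, 256L, 64L),
                           window = c(-1000, 400), cropFraction = 0.75) {
  new("PreprocessSpec", targetShape = as.integer(targetShape),
      window = as.numeric(window), cropFraction = as.numeric(cropFraction))
}

#' TextureSpec: GLCM texture-map parameters
#'
#' Parameters for the sliding-window gray-level co-occurrence computation:
#' an odd cubic window edge, the offset distance defining the set of unique
#' 3D directions, and the number of gray-level quantization bins.
#'
#' @slot window integer(1), odd window edge >= 3 (default 3).
#' @slot offsetDistance integer(1), offset magnitude in voxels (default 1).
#' @slot grayLevels integer(1), quantization bins G >= 2 (default 32).
#' @slot quantizeRange numeric(2) or NA: fixed (low, high) range for the
#'   equal-width bins; NA quantizes over each volume's own range.
#' @slot perWindowQuantize logical, re-quantize each window over its own
#'   range (slow reference mode) instead of once per volume.
#'
#' @export TextureSpec
#' @exportClass TextureSpec
TextureSpec <- setClass("TextureSpec",
  slots = c(window = "integer", offsetDistance = "integer",
            grayLevels = "integer", quantizeRange = "numeric",
            perWindowQuantize = "logical"))

setValidity("TextureSpec", function(object) {
  if (object@window < 3L || object@window %% 2L == 0L)
    return("window must be odd and >= 3")
  if (object@offsetDistance < 1L) return("offsetDistance must be >= 1")
  if (object@grayLevels < 2L) return("grayLevels must be >= 2")
  if (!(length(object@quantizeRange) == 2L || all(is.na(object@quantizeRange))))
    return("quantizeRange must be numeric(2) or NA")
  TRUE
})

#' @describeIn TextureSpec constructor
#' @param window,offsetDistance,grayLevels,quantizeRange,perWindowQuantize
#'   see slots.
#' @export
TextureSpec <- function(window = 3L, offsetDistance = 1L, grayLevels = 32L,
                        quantizeRange = NA_real_, perWindowQuantize = FALSE) {
  new("TextureSpec", window = as.integer(window),
      offsetDistance = as.integer(offsetDistance),
      grayLevels = as.integer(grayLevels),
      quantizeRange = as.numeric(quantizeRange),
      perWindowQuantize = perWindowQuantize)
}

#' TextureMapSet: the eight co-registered Haralick texture maps
#'
#' Eight named 3D feature maps, each the same shape as the source volume,
#' produced by [textureMaps()].
#'
#' @slot maps named list of 8 numeric arrays (see [HARALICK_FEATURES]).
#' @slot spec the [TextureSpec] used.
#'
#' @export TextureMapSet
#' @exportClass TextureMapSet
TextureMapSet <- setClass("TextureMapSet",
  slots = c(maps = "list", spec = "TextureSpec"))

setValidity("TextureMapSet", function(object) {
  if (!identical(sort(names(object@maps)), sort(HARALICK_FEATURES)))
    return("maps must contain exactly the 8 Haralick feature maps")
  d <- dim(object@maps[[1]])
  for (m in object@maps)
    if (!identical(dim(m), d)) return("all maps must share one shape")
  TRUE
})

#' @rdname radct-generics
#' @export
setMethod("textureMapList", "TextureMapSet", function(x) x@maps)

#' @export
setMethod("dim", "TextureMapSet", function(x) dim(x@maps[[1]]))

setMethod("show", "TextureMapSet", function(object) {
  d <- dim(object)
  cat(sprintf("TextureMapSet: 8 maps, %d x %d x %d, G = %d, window = %d\n",
              d[1], d[2], d[3], object@spec@grayLevels, object@spec@window))
})

#' ImportanceReport: random-forest Gini importances and the selected map
#'
#' Cross-validated mean decrease in Gini impurity for the 16 patch features
#' (mean and standard deviation of each texture map), plus the per-map score
#' (mean-column + sd-column importance) and the winning map.
#'
#' @slot importance data.frame with columns feature, mean, sd.
#' @slot mapScores named numeric(8), per-map combined score.
#' @slot selectedMap character(1), one of [HARALICK_FEATURES].
#' @slot folds integer(1), number of cross-validation folds used.
#'
#' @export ImportanceReport
#' @exportClass ImportanceReport
ImportanceReport <- setClass("ImportanceReport",
  slots = c(importance = "data.frame", mapScores = "numeric",
            selectedMap = "character", folds = "integer"))

setValidity("ImportanceReport", function(object) {
  if (any(object@importance$mean < 0)) return("importances must be >= 0")
  if (!object@selectedMap %in% HARALICK_FEATURES)
    return("selectedMap must be a Haralick feature name")
  if (!isTRUE(all.equal(unname(object@mapScores[object@selectedMap]),
                        max(object@mapScores))))
    return("selectedMap must have the maximal map score")
  TRUE
})

#' @rdname radct-generics
#' @export
setMethod("selectedMap", "ImportanceReport", function(x) x@selectedMap)

#' @rdname radct-generics
#' @export
setMethod("importanceTable", "ImportanceReport", function(x) x@importance)

setMethod("show", "ImportanceReport", function(object) {
  cat(sprintf("ImportanceReport (%d-fold): selected map = %s\n",
              object@folds, object@selectedMap))
  sc <- sort(object@mapScores, decreasing = TRUE)
  cat("  map scores (mean+sd column importance):\n")
  for (nm in names(sc)) cat(sprintf("    %-24s %.3f\n", nm, sc[[nm]]))
})

#' EnsembleConfig: architecture hyperparameters of the CNN-ViT ensemble
#'
#' Full-scale defaults follow the reference architecture: a 7-block 3D CNN
#' (one stride-1 block, then six stride-2 downsampling blocks with filter
#' widths 16, 32, 64, 128, 256, 512; first kernel 3, downsampling kernel 4)
#' pooled and projected to a 768-long feature vector, and a 3D ViT over
#' 16^3 patches with 12 pre-norm transformer blocks, hidden dimension 768
#' and 6 attention heads. `fusion` selects the classifier variant:
#' `"concat"` (both branches, fused fully connected head), `"cnn_only"` or
#' `"vit_only"`.
#'
#' @slot inputChannels integer, 1 or 2.
#' @slot inputShape integer(3).
#' @slot cnnFilters integer vector, ascending stride-2 block widths.
#' @slot cnnFirstKernel integer, kernel of the stride-1 block (default 3).
#' @slot cnnDownKernel integer, kernel of stride-2 blocks (default 4).
#' @slot cnnFeatureDim integer, CNN feature-vector length (default 768).
#' @slot vitPatchEdge integer, cubic patch edge (default 16).
#' @slot vitDepth integer, number of transformer blocks (default 12).
#' @slot vitDim integer, token embedding dimension (default 768).
#' @slot vitHeads integer, attention heads (default 6).
#' @slot vitMlpRatio numeric, MLP hidden width / vitDim (default 4).
#' @slot fusion character, one of "concat", "cnn_only", "vit_only".
#' @slot bnAfterRelu logical, block ordering conv - ReLU - batch norm
#'   (default TRUE); FALSE swaps to the more common conv - BN - ReLU.
#'
#' @export EnsembleConfig
#' @exportClass EnsembleConfig
EnsembleConfig <- setClass("EnsembleConfig",
  slots = c(inputChannels = "integer", inputShape = "integer",
            cnnFilters = "integer", cnnFirstKernel = "integer",
            cnnDownKernel = "integer", cnnFeatureDim = "integer",
            vitPatchEdge = "integer", vitDepth = "integer",
            vitDim = "integer", vitHeads = "integer",
            vitMlpRatio = "numeric", fusion = "character",
            bnAfterRelu = "logical"))

setValidity("EnsembleConfig", function(object) {
  if (!object@inputChannels %in% c(1L, 2L))
    return("inputChannels must be 1 or 2")
  if (length(object@inputShape) != 3L || any(object@inputShape < 4L))
    return("inputShape must be 3 integers >= 4")
  if (length(object@cnnFilters) < 1L || is.unsorted(object@cnnFilters))
    return("cnnFilters must be nonempty and ascending")
  if (object@fusion != "cnn_only") {
    if (any(object@inputShape %% object@vitPatchEdge != 0L))
      return("inputShape must be divisible by vitPatchEdge on every axis")
    if (object@vitDim %% object@vitHeads != 0L)
      return("vitDim must be divisible by vitHeads")
  }
  if (object@fusion != "vit_only") {
    s <- object@inputShape
    for (i in seq_along(object@cnnFilters)) {
      if (any(s %% 2L != 0L))
        return("inputShape not divisible through the stride-2 chain")
      s <- s %/% 2L
    }
  }
  if (!object@fusion %in% c("concat", "cnn_only", "vit_only"))
    return("fusion must be concat, cnn_only or vit_only")
  TRUE
})

#' @describeIn EnsembleConfig constructor with full-scale defaults.
#' @param inputChannels,inputShape,cnnFilters,cnnFirstKernel,cnnDownKernel
#'   see slots.
#' @param cnnFeatureDim,vitPatchEdge,vitDepth,vitDim,vitHeads,vitMlpRatio
#'   see slots.
#' @param fusion,bnAfterRelu see slots.
#' @export
EnsembleConfig <- function(inputChannels = 2L,
                           inputShape = c(256L, 256L, 64L),
                           cnnFilters = c(16L, 32L, 64L, 128L, 256L, 512L),
                           cnnFirstKernel = 3L, cnnDownKernel = 4L,
                           cnnFeatureDim = 768L, vitPatchEdge = 16L,
                           vitDepth = 12L, vitDim = 768L, vitHeads = 6L,
                           vitMlpRatio = 4, fusion = "concat",
                           bnAfterRelu = TRUE) {
  new("EnsembleConfig", inputChannels = as.integer(inputChannels),
      inputShape = as.integer(inputShape),
      cnnFilters = as.integer(cnnFilters),
      cnnFirstKernel = as.integer(cnnFirstKernel),
      cnnDownKernel = as.integer(cnnDownKernel),
      cnnFeatureDim = as.integer(cnnFeatureDim),
      vitPatchEdge = as.integer(vitPatchEdge),
      vitDepth = as.integer(vitDepth), vitDim = as.integer(vitDim),
      vitHeads = as.integer(vitHeads), vitMlpRatio = as.numeric(vitMlpRatio),
      fusion = fusion, bnAfterRelu = bnAfterRelu)
}

#' Reduced desk-scale ensemble configuration
#'
#' A small configuration for 32 x 32 x 16 volumes: CNN filter widths (8, 16),
#' feature dimension 64, ViT patch edge 8, depth 2, dimension 64, 4 heads.
#' Used by the synthetic-cohort experiments and the test suite; the
#' architecture is identical in form to the full-scale default.
#'
#' @param inputChannels 1 or 2.
#' @param inputShape volume shape, default c(32, 32, 16).
#' @param fusion "concat", "cnn_only" or "vit_only".
#' @param ... further arguments passed to [EnsembleConfig()].
#' @return an [EnsembleConfig].
#' @export
reducedConfig <- function(inputChannels = 2L, inputShape = c(32L, 32L, 16L),
                          fusion = "concat", ...) {
  EnsembleConfig(inputChannels = inputChannels, inputShape = inputShape,
                 cnnFilters = c(8L, 16L), cnnFeatureDim = 64L,
                 vitPatchEdge = 8L, vitDepth = 2L, vitDim = 64L,
                 vitHeads = 4L, fusion = fusion, ...)
}

setMethod("show", "EnsembleConfig", function(object) {
  cat(sprintf("EnsembleConfig: %d-channel %s, input %s\n",
              object@inputChannels, object@fusion,
              paste(object@inputShape, collapse = " x ")))
  if (object@fusion != "vit_only")
    cat(sprintf("  CNN: %d blocks (1 stride-1 + %d stride-2), filters %s -> %d\n",
                length(object@cnnFilters) + 1L, length(object@cnnFilters),
                paste(object@cnnFilters, collapse = ","), object@cnnFeatureDim))
  if (object@fusion != "cnn_only")
    cat(sprintf("  ViT: patch %d, depth %d, dim %d, heads %d\n",
                object@vitPatchEdge, object@vitDepth, object@vitDim,
                object@vitHeads))
})

#' TrainSpec: optimization and augmentation parameters
#'
#' Training recipe for the ensemble: binary cross-entropy loss, AdamW
#' optimization, learning rate 1e-5 over 50 epochs at full scale. The
#' augmentation list applies a random flip, random Gaussian noise and a
#' random affine transform, each independently with its own probability;
#' spatial transforms use one shared displacement for all input channels.
#'
#' @slot learningRate numeric > 0 (default 1e-5).
#' @slot epochs integer >= 1 (default 50).
#' @slot batchSize integer >= 1 (default 2).
#' @slot weightDecay numeric, AdamW decoupled weight decay (default 0.01).
#' @slot augment named list with elements `flip` (p, axes), `noise`
#'   (p, sdMax -- sd drawn uniformly from (0, sdMax) on normalized
#'   intensities) and `affine` (p, degrees about the axial axis, scale
#'   range).
#' @slot valFraction numeric in [0, 0.5], fraction of the training set held
#'   out for the per-epoch validation loss when no explicit validation set
#'   is given.
#' @slot seed integer, random seed for initialization, shuffling and
#'   augmentation.
#'
#' @export TrainSpec
#' @exportClass TrainSpec
TrainSpec <- setClass("TrainSpec",
  slots = c(learningRate = "numeric", epochs = "integer",
            batchSize = "integer", weightDecay = "numeric",
            augment = "list", valFraction = "numeric", seed = "integer"))

setValidity("TrainSpec", function(object) {
  if (object@learningRate <= 0) return("learningRate must be > 0")
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@valFraction < 0 || object@valFraction > 0.5)
    return("valFraction must be in [0, 0.5]")
  TRUE
})

#' @describeIn TrainSpec constructor
#' @param learningRate,epochs,batchSize,weightDecay,augment,valFraction,seed
#'   see slots.
#' @export
TrainSpec <- function(learningRate = 1e-5, epochs = 50L, batchSize = 2L,
                      weightDecay = 0.01,
                      augment = list(
                        flip = list(p = 0.5, axes = 1L),
                        noise = list(p = 0.5, sdMax = 0.05),
                        affine = list(p = 0.5, degrees = 10, scales = c(0.9, 1.1))),
                      valFraction = 0.2, seed = 1L) {
  new("TrainSpec", learningRate = learningRate, epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), weightDecay = weightDecay,
      augment = augment, valFraction = valFraction, seed = as.integer(seed))
}

#' Reduced desk-scale training recipe
#'
#' Shorter, higher-learning-rate recipe suited to the reduced configuration
#' and small synthetic cohorts: learning rate 1e-3, 12 epochs, batch size 8.
#'
#' @param learningRate,epochs,batchSize,seed,... passed to [TrainSpec()].
#' @return a [TrainSpec].
#' @export
reducedTrainSpec <- function(learningRate = 1e-3, epochs = 12L,
                             batchSize = 8L, seed = 1L, ...) {
  TrainSpec(learningRate = learningRate, epochs = epochs,
            batchSize = batchSize, seed = seed, ...)
}

#' ConfusionMatrix: binary classification counts
#'
#' Counts with the package's positive-class convention: TP is a correctly
#' predicted diffuse-texture (sarcoidosis-like) volume, TN a correctly
#' predicted focal-nodule (lung cancer-like) volume.
#'
#' @slot tp,tn,fp,fn nonnegative integer counts.
#' @export ConfusionMatrix
#' @exportClass ConfusionMatrix
ConfusionMatrix <- setClass("ConfusionMatrix",
  slots = c(tp = "integer", tn = "integer", fp = "integer", fn = "integer"))

setValidity("ConfusionMatrix", function(object) {
  v <- c(object@tp, object@tn, object@fp, object@fn)
  if (any(v < 0L)) return("counts must be nonnegative")
  TRUE
})

#' @describeIn ConfusionMatrix constructor
#' @param tp,tn,fp,fn counts.
#' @export
ConfusionMatrix <- function(tp, tn, fp, fn) {
  new("ConfusionMatrix", tp = as.integer(tp), tn = as.integer(tn),
      fp = as.integer(fp), fn = as.integer(fn))
}

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix: TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              object@tp, object@tn, object@fp, object@fn,
              object@tp + object@tn + object@fp + object@fn))
})

#' FoldResults: cross-validated classification results
#'
#' Per-fold confusion matrices and metric sets, cross-fold mean and standard
#' deviation, out-of-fold scores pooled across folds, and the combined AUC
#' of the pooled ROC.
#'
#' @slot variant character, the model variant name.
#' @slot folds list of per-fold results (confusion matrix, metrics, indices,
#'   scores, labels, fold AUC, loss curves).
#' @slot metrics data.frame, one row per fold with the five metrics.
#' @slot summary data.frame with mean and sd per metric.
#' @slot pooled data.frame of pooled out-of-fold (score, label, fold).
#' @slot combinedAUC numeric(1) in [0, 1].
#' @slot pooledConfusion a [ConfusionMatrix] over all out-of-fold predictions.
#'
#' @export FoldResults
#' @exportClass FoldResults
FoldResults <- setClass("FoldResults",
  slots = c(variant = "character", folds = "list", metrics = "data.frame",
            summary = "data.frame", pooled = "data.frame",
            combinedAUC = "numeric", pooledConfusion = "ConfusionMatrix"))

setValidity("FoldResults", function(object) {
  if (length(object@combinedAUC) != 1L || object@combinedAUC < 0 ||
      object@combinedAUC > 1) return("combinedAUC must be in [0, 1]")
  TRUE
})

#' @rdname radct-generics
#' @export
setMethod("combinedAUC", "FoldResults", function(x) x@combinedAUC)

#' @rdname radct-generics
#' @export
setMethod("foldMetrics", "FoldResults", function(x) x@metrics)

#' @rdname radct-generics
#' @export
setMethod("pooledScores", "FoldResults", function(x) x@pooled)

setMethod("show", "FoldResults", function(object) {
  cat(sprintf("FoldResults [%s]: %d folds, combined AUC %.3f\n",
              object@variant, length(object@folds), object@combinedAUC))
  s <- object@summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
})

#' AttentionMap: a volumetric saliency map
#'
#' A saliency volume co-registered with its source input, produced by
#' [hiResCAM()] (CNN branch) or [attentionRollout()] (ViT branch). Raw signed
#' values are retained; [displayValues()] min-max normalizes for display.
#'
#' @slot values 3D numeric array, input-volume shape.
#' @slot source character, "hirescam" or "rollout".
#' @slot classIndex integer, the explained class (1 = positive).
#'
#' @export AttentionMap
#' @exportClass AttentionMap
AttentionMap <- setClass("AttentionMap",
  slots = c(values = "array", source = "character", classIndex = "integer"))

setValidity("AttentionMap", function(object) {
  if (length(dim(object@values)) != 3L) return("values must be 3D")
  if (any(!is.finite(object@values))) return("values must be finite")
  if (!object@source %in% c("hirescam", "rollout"))
    return("source must be hirescam or rollout")
  TRUE
})

#' @describeIn AttentionMap constructor
#' @param values,source,classIndex see slots.
#' @export
AttentionMap <- function(values, source, classIndex = 1L) {
  new("AttentionMap", values = values, source = source,
      classIndex = as.integer(classIndex))
}

#' @describeIn AttentionMap display-normalized values in [0, 1]
#' @param x an AttentionMap.
#' @export
displayValues <- function(x) {
  stopifnot(is(x, "AttentionMap"))
  minMaxNormalize(x@values)
}

setMethod("show", "AttentionMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("AttentionMap [%s] %d x %d x %d, class %d, range [%.3g, %.3g]\n",
              object@source, d[1], d[2], d[3], object@classIndex,
              min(object@values), max(object@values)))
})

#' PhantomSpec: synthetic 3D texture phantom parameters
#'
#' Parameters for [makePhantom()]. The diffuse-texture class (label 1) is a
#' correlated Gaussian random field emulating diffuse parenchymal texture;
#' the focal-nodule class (label 0) is a smooth background with spherical
#' hyperintense inclusions emulating focal lesions. Intensities are HU-like
#' and lie within the lung window.
#'
#' @slot shape integer(3).
#' @slot phantomClass character, "diffuse_texture" or "focal_nodule" (the
#'   constructor argument is named `class`).
#' @slot textureCorrelationLength numeric, Gaussian correlation length of the
#'   diffuse field, voxels.
#' @slot backgroundCorrelationLength numeric, correlation length of the
#'   focal-class background field, voxels.
#' @slot textureSd numeric, local texture contrast of the diffuse field:
#'   the standard deviation of adjacent-voxel differences, HU.
#' @slot noduleCount integer, spheres in the focal class.
#' @slot noduleRadius numeric, sphere radius, voxels.
#' @slot noduleContrast numeric > 0, HU contrast of the spheres.
#' @slot backgroundMean numeric, HU mean of the background.
#' @slot backgroundSd numeric, local contrast (adjacent-voxel difference
#'   sd, HU) of the focal-class background field.
#' @slot diffuseShift numeric, HU added to the diffuse-texture class mean
#'   over the background (emulates the increased attenuation of diffuse
#'   infiltrates).
#' @slot noiseSd numeric, white-noise HU standard deviation.
#' @slot seed integer; fixes the phantom bit-exactly.
#'
#' @export PhantomSpec
#' @exportClass PhantomSpec
PhantomSpec <- setClass("PhantomSpec",
  slots = c(shape = "integer", phantomClass = "character",
            textureCorrelationLength = "numeric", textureSd = "numeric",
            backgroundCorrelationLength = "numeric",
            noduleCount = "integer", noduleRadius = "numeric",
            noduleContrast = "numeric", backgroundMean = "numeric",
            backgroundSd = "numeric", diffuseShift = "numeric",
            noiseSd = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 3L))
    return("shape must be 3 integers >= 3")
  if (!object@phantomClass %in% c("diffuse_texture", "focal_nodule"))
    return("class must be diffuse_texture or focal_nodule")
  if (object@noduleContrast <= 0) return("noduleContrast must be > 0")
  if (object@phantomClass == "focal_nodule" && object@noduleCount > 0L &&
      any(2 * object@noduleRadius + 2 > object@shape))
    return("nodules do not fit the volume shape")
  TRUE
})

#' @describeIn PhantomSpec constructor
#' @param shape,class,textureCorrelationLength,textureSd see slots.
#' @param noduleCount,noduleRadius,noduleContrast see slots.
#' @param backgroundMean,backgroundSd,diffuseShift,noiseSd,seed see slots.
#' @export
PhantomSpec <- function(shape = c(32L, 32L, 16L), class = "diffuse_texture",
                        textureCorrelationLength = 2.5, textureSd = 50,
                        backgroundCorrelationLength = 2.2,
                        noduleCount = 2L, noduleRadius = 4,
                        noduleContrast = 650, backgroundMean = -800,
                        backgroundSd = 50, diffuseShift = 350,
                        noiseSd = 45, seed = 1L) {
  new("PhantomSpec", shape = as.integer(shape), phantomClass = class,
      textureCorrelationLength = textureCorrelationLength,
      textureSd = textureSd,
      backgroundCorrelationLength = backgroundCorrelationLength,
      noduleCount = as.integer(noduleCount),
      noduleRadius = noduleRadius, noduleContrast = noduleContrast,
      backgroundMean = backgroundMean, backgroundSd = backgroundSd,
      diffuseShift = diffuseShift, noiseSd = noiseSd,
      seed = as.integer(seed))
}
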