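#' Patch statistics of a texture map set
#'
#' Divides each of the eight texture maps into non-overlapping
#' `patchEdge^3` patches and computes the patch mean and standard deviation
#' of each map, giving a 16-element feature vector per patch. Each patch
#' inherits the volume's label. Trailing voxels that do not fill a whole
#' patch are discarded.
#'
#' @param tms a [TextureMapSet].
#' @param patchEdge patch edge length in voxels (default 16).
#' @param volumeId identifier recorded per row.
#' @param label volume label inherited by every patch (0/1).
#' @return data.frame: volume, patch index triple (px, py, pz), label, and
#'   16 feature columns `mean_<Feature>` / `sd_<Feature>`.
#' @export
patchFeatures <- function(tms, patchEdge = 16L, volumeId = "vol1",
                          label = NA_integer_) {
  stopifnot(is(tms, "TextureMapSet"))
  d <- dim(tms)
  pe <- as.integer(patchEdge)
  if (any(pe > d)) stop("patchFeatures: patchEdge larger than a volume dim")
  ng <- d %/% pe
  grid <- expand.grid(px = seq_len(ng[1]), py = seq_len(ng[2]),
                      pz = seq_len(ng[3]))
  out <- data.frame(volume = volumeId, grid, label = as.integer(label))
  for (f in HARALICK_FEATURES) {
    a <- tms@maps[[f]][seq_len(ng[1] * pe), seq_len(ng[2] * pe),
                       seq_len(ng[3] * pe), drop = FALSE]
    dim(a) <- c(pe, ng[1], pe, ng[2], pe, ng[3])
    means <- apply(a, c(2, 4, 6), mean)
    sds <- apply(a, c(2, 4, 6), sd)
    out[[paste0("mean_", f)]] <- means[as.matrix(grid)]
    out[[paste0("sd_", f)]] <- sds[as.matrix(grid)]
  }
  out
}

#' Names of the 16 patch feature columns
#' @return character(16).
#' @export
patchFeatureNames <- function() {
  as.vector(rbind(paste0("mean_", HARALICK_FEATURES),
                  paste0("sd_", HARALICK_FEATURES)))
}

#' Rank texture maps by cross-validated random-forest Gini importance
#'
#' Fits a random forest (default 100 trees) on the 16 patch features in a
#' k-fold cross-validation and reports, per feature, the cross-fold mean and
#' standard deviation of the mean decrease in Gini impurity (the per-forest
#' importance averaged over trees). The per-map score is the sum of the
#' map's mean-column and sd-column importances; the map with the maximal
#' score is selected as the network input channel.
#'
#' Folds are split at volume level by default so that patches of one volume
#' never straddle a fold boundary; `foldBy = "patch"` splits at patch level
#' for fidelity experiments.
#'
#' @param table a patch feature table from [patchFeatures()] (rows from
#'   several volumes concatenated).
#' @param nTrees trees per forest (default 100).
#' @param k folds (default 5).
#' @param seed RNG seed for fold assignment and forest fitting.
#' @param foldBy "volume" or "patch".
#' @return an [ImportanceReport].
#' @export
rankFeatures <- function(table, nTrees = 100L, k = 5L, seed = 1L,
                         foldBy = c("volume", "patch")) {
  foldBy <- match.arg(foldBy)
  feats <- patchFeatureNames()
  stopifnot(all(feats %in% names(table)))
  labs <- table$label
  if (length(unique(labs)) < 2L)
    stop("rankFeatures: both classes must be present")
  if (foldBy == "volume") {
    vols <- unique(table$volume)
    vlab <- vapply(vols, function(v) labs[match(v, table$volume)], integer(1))
    if (any(tabulate(factor(vlab)) < k))
      stop("rankFeatures: need >= k volumes per class for volume-level folds")
    vf <- stratifiedFolds(vlab, k, seed)
    fold <- vf[match(table$volume, vols)]
  } else {
    fold <- stratifiedFolds(labs, k, seed)
  }
  subSeeds <- deriveSeeds(seed, k)
  imp <- matrix(NA_real_, nrow = length(feats), ncol = k,
                dimnames = list(feats, NULL))
  for (f in seq_len(k)) {
    tr <- table[fold != f, , drop = FALSE]
    fit <- withSeed(subSeeds[f],
      randomForest::randomForest(x = tr[, feats], y = factor(tr$label),
                                 ntree = nTrees))
    imp[, f] <- fit$importance[feats, "MeanDecreaseGini"]
  }
  impMean <- rowMeans(imp)
  impSd <- apply(imp, 1, sd)
  mapScores <- vapply(HARALICK_FEATURES, function(m)
    impMean[[paste0("mean_", m)]] + impMean[[paste0("sd_", m)]], numeric(1))
  sel <- HARALICK_FEATURES[which.max(mapScores)]
  ImportanceReport(
    importance = data.frame(feature = feats, mean = unname(impMean),
                            sd = unname(impSd)),
    mapScores = mapScores, selectedMap = sel, folds = as.integer(k))
}
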