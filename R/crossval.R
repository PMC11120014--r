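#' Stratified k-fold cross-validation of the ensemble
#'
#' Assigns volumes to stratified folds (volume level, fixed seed), trains a
#' model from scratch on each training split with the held-out fold as the
#' validation set, and evaluates out-of-fold predictions. The combined AUC
#' is the AUC of a single ROC over the out-of-fold scores pooled across
#' folds; per-fold AUCs and metrics (threshold 0.5) are reported alongside,
#' and metrics of the pooled confusion counts are included in the summary.
#'
#' @param xs list of (X, Y, Z, C) arrays.
#' @param labels integer 0/1 labels.
#' @param cfg an [EnsembleConfig].
#' @param spec a [TrainSpec]; each fold derives its own seed from
#'   `spec@seed`.
#' @param k number of folds (default 5).
#' @param seed seed for the fold assignment (default `spec@seed`).
#' @param variant name recorded in the result.
#' @return a [FoldResults].
#' @export
crossValidate <- function(xs, labels, cfg, spec = reducedTrainSpec(),
                          k = 5L, seed = spec@seed, variant = cfg@fusion) {
  labels <- as.integer(labels)
  if (k < 2L) stop("crossValidate: k must be >= 2")
  if (any(tabulate(factor(labels, levels = c(0, 1))) < k))
    stop("crossValidate: need >= k volumes per class")
  folds <- stratifiedFolds(labels, k, seed)
  foldSeeds <- deriveSeeds(seed + 1L, k)
  foldRes <- vector("list", k)
  pooled <- data.frame(score = numeric(0), label = integer(0),
                       fold = integer(0))
  metrics <- NULL
  for (f in seq_len(k)) {
    tr <- folds != f
    foldSpec <- spec
    foldSpec@seed <- foldSeeds[f]
    foldSpec@valFraction <- 0
    fit <- trainModel(xs[tr], labels[tr], cfg, foldSpec,
                      valXs = xs[!tr], valLabels = labels[!tr])
    sc <- predictProb(fit$model, xs[!tr])
    cm <- confusionFromScores(sc, labels[!tr])
    mt <- computeMetrics(cm)
    foldAUC <- if (length(unique(labels[!tr])) == 2L)
      pooledAUC(sc, labels[!tr]) else NA_real_
    foldRes[[f]] <- list(confusion = cm, metrics = mt,
                         indices = which(!tr), scores = sc,
                         labels = labels[!tr], auc = foldAUC,
                         history = fit$history)
    pooled <- rbind(pooled, data.frame(score = sc, label = labels[!tr],
                                       fold = f))
    metrics <- rbind(metrics, mt)
  }
  metrics <- as.data.frame(metrics)
  rownames(metrics) <- paste0("fold", seq_len(k))
  pcm <- confusionFromScores(pooled$score, pooled$label)
  pmt <- computeMetrics(pcm)
  summ <- data.frame(metric = colnames(metrics),
                     mean = colMeans(metrics, na.rm = TRUE),
                     sd = apply(metrics, 2, sd, na.rm = TRUE),
                     pooled = as.numeric(pmt), row.names = NULL)
  FoldResults(variant = variant, folds = foldRes, metrics = metrics,
              summary = summ, pooled = pooled,
              combinedAUC = pooledAUC(pooled$score, pooled$label),
              pooledConfusion = pcm)
}

#' The five ablation variants
#'
#' Input channels and fusion mode for each model variant of the ablation
#' design: CT-ViT and CT-CNN are single-branch CT-only models, CT-CNNViT
#' the CT-only ensemble, Rad-CNNViT the texture-map-only ensemble, and
#' RadCT-CNNViT the two-channel (CT + texture map) ensemble.
#'
#' @return data.frame with variant, channels, fusion.
#' @export
ablationVariants <- function() {
  data.frame(
    variant = c("CT-ViT", "CT-CNN", "CT-CNNViT", "Rad-CNNViT",
                "RadCT-CNNViT"),
    channels = c("ct", "ct", "ct", "rad", "ct+rad"),
    fusion = c("vit_only", "cnn_only", "concat", "concat", "concat"),
    stringsAsFactors = FALSE)
}

assembleChannels <- function(ct, rad, channels) {
  n <- length(ct)
  lapply(seq_len(n), function(i) {
    chans <- switch(channels,
                    "ct" = list(ct[[i]]),
                    "rad" = list(rad[[i]]),
                    "ct+rad" = list(ct[[i]], rad[[i]]),
                    stop("unknown channel set: ", channels))
    array(unlist(chans, use.names = FALSE),
          c(dim(chans[[1]]), length(chans)))
  })
}

#' Run the five-variant ablation study
#'
#' Cross-validates every requested variant on the same stratified folds
#' (identical fold seed) so that the variants are directly comparable.
#'
#' @param ct list of normalized CT volumes (3D arrays).
#' @param rad list of normalized texture-map volumes (3D arrays).
#' @param labels integer 0/1 labels.
#' @param inputShape volume shape (passed to [reducedConfig()] /
#'   [EnsembleConfig()]).
#' @param spec a [TrainSpec].
#' @param k folds.
#' @param seed fold seed shared across variants.
#' @param variants subset of `ablationVariants()$variant`.
#' @param configFor function(inputChannels, fusion) returning an
#'   [EnsembleConfig]; defaults to [reducedConfig()] at `inputShape`.
#' @return named list of [FoldResults], one per variant.
#' @export
runAblation <- function(ct, rad, labels, inputShape = dim(ct[[1]]),
                        spec = reducedTrainSpec(), k = 3L, seed = spec@seed,
                        variants = ablationVariants()$variant,
                        configFor = NULL) {
  av <- ablationVariants()
  stopifnot(all(variants %in% av$variant))
  if (is.null(configFor))
    configFor <- function(nc, fusion)
      reducedConfig(inputChannels = nc, inputShape = inputShape,
                    fusion = fusion)
  res <- list()
  for (vn in variants) {
    row <- av[av$variant == vn, ]
    xs <- assembleChannels(ct, rad, row$channels)
    cfg <- configFor(if (row$channels == "ct+rad") 2L else 1L, row$fusion)
    res[[vn]] <- crossValidate(xs, labels, cfg, spec, k = k, seed = seed,
                               variant = vn)
  }
  res
}

#' Summarize an ablation run as one table
#'
#' One row per variant with cross-fold mean +/- sd of each metric and the
#' combined AUC, in the format of the reference ablation table.
#'
#' @param results named list of [FoldResults] from [runAblation()].
#' @return data.frame.
#' @export
ablationTable <- function(results) {
  do.call(rbind, lapply(names(results), function(vn) {
    r <- results[[vn]]
    s <- r@summary
    row <- data.frame(variant = vn)
    for (i in seq_len(nrow(s)))
      row[[s$metric[i]]] <- sprintf("%.2f ± %.2f", s$mean[i], s$sd[i])
    row$AUC <- sprintf("%.2f", r@combinedAUC)
    row
  }))
}
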