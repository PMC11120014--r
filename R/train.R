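#' Randomly augment a multichannel volume
#'
#' Applies, each independently with its configured probability, a random
#' flip, additive Gaussian noise (sd drawn uniformly from (0, sdMax)), and
#' a random affine transform (rotation about the axial axis and isotropic
#' scaling, trilinearly resampled). All channels receive the identical
#' spatial transform; noise is drawn per channel. Draws come from the
#' current RNG state, so a fixed seed fixes the augmentation.
#'
#' @param x array (X, Y, Z, C).
#' @param augment augmentation list as in [TrainSpec()].
#' @return augmented array, same shape.
#' @export
augmentVolume <- function(x, augment = TrainSpec()@augment) {
  stopifnot(length(dim(x)) == 4L)
  d <- dim(x)
  fl <- augment$flip
  if (!is.null(fl) && fl$p > 0 && runif(1) < fl$p) {
    for (ax in fl$axes) {
      idx <- rep(list(quote(expr = )), 4)
      idx[[ax]] <- rev(seq_len(d[ax]))
      x <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
    }
  }
  af <- augment$affine
  if (!is.null(af) && af$p > 0 && runif(1) < af$p) {
    theta <- runif(1, -af$degrees, af$degrees) * pi / 180
    s <- runif(1, af$scales[1], af$scales[2])
    ctr <- (d[1:3] - 1) / 2
    R <- matrix(c(cos(theta), -sin(theta), 0,
                  sin(theta), cos(theta), 0,
                  0, 0, 1), 3, 3, byrow = TRUE) / s
    M <- cbind(R, ctr - R %*% ctr)
    for (c in seq_len(d[4]))
      x[, , , c] <- affine_warp_cpp(x[, , , c, drop = TRUE], M)
  }
  no <- augment$noise
  if (!is.null(no) && no$p > 0 && runif(1) < no$p) {
    sdv <- runif(1, 0, no$sdMax)
    x <- x + array(rnorm(length(x), sd = sdv), d)
  }
  x
}

bceLoss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

stackBatch <- function(xs) {
  d <- dim(xs[[1]])
  array(unlist(xs, use.names = FALSE), c(d, length(xs)))
}

evalLoss <- function(model, xs, labels, batchSize = 8L) {
  n <- length(xs)
  tot <- 0
  for (b in split(seq_len(n), ceiling(seq_len(n) / batchSize))) {
    p <- forwardModel(model, stackBatch(xs[b]))$prob
    tot <- tot + bceLoss(p, labels[b]) * length(b)
  }
  tot / n
}

#' Train the ensemble with binary cross-entropy and AdamW
#'
#' Trains a model built from `cfg` on labeled multichannel volumes using
#' binary cross-entropy loss, AdamW optimization and the augmentation
#' recipe in `spec`. Per-epoch training and validation losses are recorded.
#' Two runs with the same data and spec seed produce identical models and
#' loss curves.
#'
#' @param xs list of (X, Y, Z, C) arrays.
#' @param labels integer vector of 0/1 labels, one per volume.
#' @param cfg an [EnsembleConfig].
#' @param spec a [TrainSpec].
#' @param valXs,valLabels optional explicit validation set; if absent,
#'   `spec@valFraction` of the training set is held out (stratified).
#' @return list of class "radctFit": `model`, `history` (data.frame with
#'   epoch, trainLoss, valLoss), `spec`, `cfg`.
#' @export
trainModel <- function(xs, labels, cfg, spec = reducedTrainSpec(),
                       valXs = NULL, valLabels = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("trainModel: need at least two volumes per class")
  stopifnot(length(xs) == length(labels))
  if (is.null(valXs) && spec@valFraction > 0) {
    hold <- stratifiedFolds(labels, max(2L, round(1 / spec@valFraction)),
                            spec@seed + 7L) == 1L
    valXs <- xs[hold]; valLabels <- labels[hold]
    xs <- xs[!hold]; labels <- labels[!hold]
  }
  model <- buildModel(cfg, seed = spec@seed)
  opt <- adamW(model$paramEnvs, lr = spec@learningRate,
               weightDecay = spec@weightDecay)
  n <- length(xs)
  hist <- data.frame(epoch = seq_len(spec@epochs), trainLoss = NA_real_,
                     valLoss = NA_real_)
  withSeed(spec@seed + 1L, {
    for (ep in seq_len(spec@epochs)) {
      ord <- sample.int(n)
      epochLoss <- 0
      for (b in split(ord, ceiling(seq_along(ord) / spec@batchSize))) {
        xb <- lapply(xs[b], augmentVolume, augment = spec@augment)
        yb <- labels[b]
        out <- forwardModel(model, stackBatch(xb), training = TRUE)
        epochLoss <- epochLoss + bceLoss(out$prob, yb) * length(b)
        zeroGrads(model$paramEnvs)
        backwardModel(model, (out$prob - yb) / length(b))
        opt$step()
      }
      hist$trainLoss[ep] <- epochLoss / n
      if (!is.null(valXs) && length(valXs) > 0)
        hist$valLoss[ep] <- evalLoss(model, valXs, valLabels)
    }
  })
  structure(list(model = model, history = hist, spec = spec, cfg = cfg),
            class = "radctFit")
}

#' @export
print.radctFit <- function(x, ...) {
  h <- x$history
  cat(sprintf("radctFit: %d epochs, train loss %.4f -> %.4f",
              nrow(h), h$trainLoss[1], h$trainLoss[nrow(h)]))
  if (!all(is.na(h$valLoss)))
    cat(sprintf(", val loss %.4f", h$valLoss[nrow(h)]))
  cat("\n")
  invisible(x)
}
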