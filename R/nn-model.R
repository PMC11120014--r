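# Assembly of the 3D CNN branch, the 3D ViT branch and the fused
# classification head into one model object ("radctModel": a list of layer
# environments plus metadata). Activations: (X, Y, Z, C, N) arrays in, a
# probability per volume out.

buildCnnBranch <- function(cfg) {
  cin <- cfg@inputChannels
  layers <- list()
  addBlock <- function(layers, cin, cout, k, stride) {
    conv <- layerConv3d(cin, cout, k, stride, pad = (k - 1L) %/% 2L)
    if (cfg@bnAfterRelu)
      c(layers, list(conv, layerReLU(), layerBatchNorm3d(cout)))
    else
      c(layers, list(conv, layerBatchNorm3d(cout), layerReLU()))
  }
  # one stride-1 block at the first width, then the stride-2 chain
  layers <- addBlock(layers, cin, cfg@cnnFilters[1], cfg@cnnFirstKernel, 1L)
  prev <- cfg@cnnFilters[1]
  for (f in cfg@cnnFilters) {
    layers <- addBlock(layers, prev, f, cfg@cnnDownKernel, 2L)
    prev <- f
  }
  layers <- c(layers, list(layerGlobalAvgPool3d(),
                           layerDense(prev, cfg@cnnFeatureDim)))
  layers
}

buildVitBranch <- function(cfg) {
  e <- newLayer("vit")
  D <- cfg@vitDim; p <- cfg@vitPatchEdge; C <- cfg@inputChannels
  d <- cfg@inputShape
  ng <- d %/% p
  P <- prod(ng)
  e$P <- P; e$D <- D; e$ng <- ng; e$p <- p; e$C <- C
  # separable patch gather index: token rows = within-patch (x,y,z,c),
  # token columns = patch grid (x fastest)
  wo <- as.matrix(expand.grid(ox = 0:(p - 1), oy = 0:(p - 1),
                              oz = 0:(p - 1), c = 0:(C - 1)))
  qg <- as.matrix(expand.grid(qx = 0:(ng[1] - 1), qy = 0:(ng[2] - 1),
                              qz = 0:(ng[3] - 1)))
  X <- d[1]; XY <- d[1] * d[2]; XYZ <- prod(d)
  a <- wo[, 1] + X * wo[, 2] + XY * wo[, 3] + XYZ * wo[, 4]
  b <- p * (qg[, 1] + X * qg[, 2] + XY * qg[, 3])
  e$gather <- outer(a, b, "+") + 1     # (p^3*C, P) voxel indices
  e$embed <- layerDense(p^3 * C, D, init = "vit")
  e$params$cls <- matrix(rnorm(D, sd = 0.02), D, 1)
  e$params$pos <- matrix(rnorm(D * (P + 1), sd = 0.02), D, P + 1)
  e$decay <- c(cls = FALSE, pos = FALSE)
  e$blocks <- lapply(seq_len(cfg@vitDepth), function(i)
    list(ln1 = layerLayerNorm(D),
         attn = layerMHSA(D, cfg@vitHeads),
         ln2 = layerLayerNorm(D),
         mlp = layerMLP(D, round(cfg@vitMlpRatio * D))))
  e$lnf <- layerLayerNorm(D)
  e$fwd <- function(x, training = FALSE) {   # x: (X,Y,Z,C,N)
    N <- dim(x)[5]
    T <- e$P + 1L
    seqs <- array(0, c(e$D, T, N))
    vox <- prod(dim(x)[1:4])
    toks <- matrix(0, nrow(e$gather), e$P * N)
    for (n in seq_len(N)) {
      xv <- as.numeric(x[, , , , n])
      toks[, (n - 1) * e$P + seq_len(e$P)] <-
        matrix(xv[as.vector(e$gather)], nrow(e$gather), e$P)
    }
    emb <- e$embed$fwd(toks, training)     # (D, P*N)
    for (n in seq_len(N))
      seqs[, , n] <- cbind(e$params$cls,
                           emb[, (n - 1) * e$P + seq_len(e$P)]) + e$params$pos
    h <- seqs
    for (blk in e$blocks) {
      d2 <- dim(h)
      hm <- matrix(h, nrow = e$D)
      a1 <- array(blk$ln1$fwd(hm, training), d2)
      h <- h + blk$attn$fwd(a1, training)
      hm <- matrix(h, nrow = e$D)
      h <- h + array(blk$mlp$fwd(blk$ln2$fwd(hm, training), training), d2)
    }
    hm <- matrix(h, nrow = e$D)
    hf <- array(e$lnf$fwd(hm, training), dim(h))
    e$cacheN <- N
    hf[, 1, , drop = TRUE]               # class token -> (D, N)
  }
  e$bwd <- function(dcls) {               # dcls: (D, N)
    N <- e$cacheN; T <- e$P + 1L
    dh <- array(0, c(e$D, T, N))
    dh[, 1, ] <- dcls
    dm <- e$lnf$bwd(matrix(dh, nrow = e$D))
    dh <- array(dm, c(e$D, T, N))
    for (blk in rev(e$blocks)) {
      dmlp <- blk$ln2$bwd(blk$mlp$bwd(matrix(dh, nrow = e$D)))
      dh <- dh + array(dmlp, dim(dh))
      dattn <- blk$attn$bwd(dh)
      dln1 <- blk$ln1$bwd(matrix(dattn, nrow = e$D))
      dh <- dh + array(dln1, dim(dh))
    }
    # position embedding / class token grads
    e$grads$pos <- e$grads$pos + apply(dh, c(1, 2), sum)
    e$grads$cls <- e$grads$cls + matrix(rowSums(dh[, 1, , drop = FALSE]), e$D, 1)
    demb <- matrix(0, e$D, e$P * N)
    for (n in seq_len(N))
      demb[, (n - 1) * e$P + seq_len(e$P)] <- dh[, -1, n]
    dtok <- e$embed$bwd(demb)             # (p^3*C, P*N)
    NULL                                   # input gradient not propagated
  }
  # per-layer head-wise attention of the most recent forward pass
  e$attentionMaps <- function() lapply(e$blocks, function(b) b$attn$attention)
  e
}

vitParamEnvs <- function(vit) {
  envs <- list(vit, vit$embed)
  for (blk in vit$blocks)
    envs <- c(envs, list(blk$ln1, blk$attn, blk$ln2, blk$mlp$fc1,
                         blk$mlp$fc2))
  c(envs, list(vit$lnf))
}

#' Build the multichannel CNN-ViT ensemble model
#'
#' Constructs the network described by an [EnsembleConfig]: a 3D CNN branch
#' (stride-1 block then stride-2 downsampling chain, global average pooling
#' and projection to the CNN feature dimension), a 3D ViT branch (patch
#' embedding, class token, learned position embeddings, pre-norm transformer
#' blocks, class-token readout), and a fully connected sigmoid head over the
#' concatenated branch outputs (or a single branch for the `cnn_only` /
#' `vit_only` ablation variants). Weights are initialized from the given
#' seed; two builds with the same seed are identical.
#'
#' @param cfg an [EnsembleConfig].
#' @param seed integer RNG seed for weight initialization.
#' @return a model object (list with class "radctModel").
#' @export
buildModel <- function(cfg, seed = 1L) {
  validObject(cfg)
  withSeed(seed, {
    cnn <- if (cfg@fusion != "vit_only") buildCnnBranch(cfg) else NULL
    vit <- if (cfg@fusion != "cnn_only") buildVitBranch(cfg) else NULL
    width <- switch(cfg@fusion,
                    concat = cfg@cnnFeatureDim + cfg@vitDim,
                    cnn_only = cfg@cnnFeatureDim,
                    vit_only = cfg@vitDim)
    head <- layerDense(width, 1L)
    envs <- c(cnn %||% list(), if (!is.null(vit)) vitParamEnvs(vit),
              list(head))
    model <- list(cfg = cfg, cnn = cnn, vit = vit, head = head,
                  fusionWidth = width, paramEnvs = envs, seed = seed)
    class(model) <- "radctModel"
    model
  })
}

#' @export
print.radctModel <- function(x, ...) {
  np <- sum(vapply(x$paramEnvs, function(e)
    sum(vapply(e$params, length, numeric(1))), numeric(1)))
  cat(sprintf("radctModel (%s, %d channel(s)), %s parameters\n",
              x$cfg@fusion, x$cfg@inputChannels, format(np, big.mark = ",")))
  invisible(x)
}

#' Forward pass of the ensemble
#'
#' @param model a model from [buildModel()].
#' @param x input array (X, Y, Z, C, N) or (X, Y, Z, C) for one volume.
#' @param training logical; batch-norm uses batch statistics and layers
#'   retain caches for the backward pass.
#' @param retain retain caches even in evaluation mode (needed for
#'   [hiResCAM()]).
#' @return list with `prob` (numeric N), `logit` (numeric N), and branch
#'   feature matrices `cnnFeatures` / `vitFeatures` (D x N or NULL).
#' @export
forwardModel <- function(model, x, training = FALSE, retain = FALSE) {
  if (length(dim(x)) == 4L) dim(x) <- c(dim(x), 1L)
  stopifnot(dim(x)[4] == model$cfg@inputChannels)
  keep <- training || retain
  cnnOut <- NULL; vitOut <- NULL
  if (!is.null(model$cnn)) {
    h <- x
    for (i in seq_along(model$cnn)) {
      e <- model$cnn[[i]]
      e$retain <- keep
      h <- e$fwd(h, training)
      if (keep) e$out <- h
    }
    cnnOut <- h
  }
  if (!is.null(model$vit)) {
    vitOut <- model$vit$fwd(x, training)
    if (is.null(dim(vitOut))) vitOut <- matrix(vitOut, ncol = dim(x)[5])
  }
  feat <- switch(model$cfg@fusion,
                 concat = rbind(cnnOut, vitOut),
                 cnn_only = cnnOut,
                 vit_only = vitOut)
  logit <- model$head$fwd(feat, training)
  prob <- 1 / (1 + exp(-logit))
  list(prob = as.numeric(prob), logit = as.numeric(logit),
       cnnFeatures = cnnOut, vitFeatures = vitOut)
}

# backward pass from d(loss)/d(logit); records per-layer output gradients
# on the CNN branch (e$dout) for explainability
backwardModel <- function(model, dlogit) {
  dfeat <- model$head$bwd(matrix(dlogit, nrow = 1))
  cfg <- model$cfg
  dcnn <- dvit <- NULL
  if (cfg@fusion == "concat") {
    dcnn <- dfeat[seq_len(cfg@cnnFeatureDim), , drop = FALSE]
    dvit <- dfeat[cfg@cnnFeatureDim + seq_len(cfg@vitDim), , drop = FALSE]
  } else if (cfg@fusion == "cnn_only") dcnn <- dfeat else dvit <- dfeat
  if (!is.null(model$vit) && !is.null(dvit)) model$vit$bwd(dvit)
  if (!is.null(model$cnn) && !is.null(dcnn)) {
    g <- dcnn
    for (i in rev(seq_along(model$cnn))) {
      e <- model$cnn[[i]]
      e$dout <- g
      g <- e$bwd(g)
    }
    model$cnn[[1]]$dinput <- g   # gradient of the score w.r.t. the input
  }
  invisible(NULL)
}

#' Predict class probabilities for volumes
#'
#' @param model a fitted model.
#' @param xs list of (X, Y, Z, C) arrays or one (X, Y, Z, C, N) array.
#' @return numeric vector of probabilities for the positive class.
#' @export
predictProb <- function(model, xs) {
  if (is.list(xs)) {
    vapply(xs, function(x) forwardModel(model, x)$prob, numeric(1))
  } else {
    forwardModel(model, xs)$prob
  }
}

#' Save a model checkpoint
#'
#' Serializes all parameters, batch-norm running statistics and the
#' embedded [EnsembleConfig] to an RDS file.
#'
#' @param model a model from [buildModel()] (or a `radctFit$model`).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
saveModel <- function(model, path) {
  stopifnot(inherits(model, "radctModel"))
  state <- lapply(model$paramEnvs, function(e)
    list(params = e$params, rm = e$rm, rv = e$rv))
  saveRDS(list(cfg = model$cfg, seed = model$seed, state = state), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Rebuilds the architecture from the embedded configuration and restores
#' all parameters and running statistics.
#'
#' @param path file written by [saveModel()].
#' @return a model object.
#' @export
loadModel <- function(path) {
  ck <- readRDS(path)
  model <- buildModel(ck$cfg, seed = ck$seed)
  stopifnot(length(model$paramEnvs) == length(ck$state))
  for (i in seq_along(ck$state)) {
    e <- model$paramEnvs[[i]]
    e$params <- ck$state[[i]]$params
    if (!is.null(ck$state[[i]]$rm)) e$rm <- ck$state[[i]]$rm
    if (!is.null(ck$state[[i]]$rv)) e$rv <- ck$state[[i]]$rv
  }
  model
}
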