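#' HiResCAM saliency map for the CNN branch
#'
#' Computes the gradient of the raw class score (the pre-sigmoid logit for
#' the positive class; its negation for the negative class) with respect to
#' a designated CNN feature layer, multiplies it element-wise with the
#' feature activations, and sums over the feature channels. The resulting
#' map is trilinearly upsampled to the input volume shape. Raw signed
#' values are retained; no rectification is applied. Use [displayValues()]
#' for the min-max normalized display version.
#'
#' @param model a model from [buildModel()] with a CNN branch.
#' @param x input array (X, Y, Z, C) or (X, Y, Z, C, 1).
#' @param classIndex class to explain: 1 (positive, default) or 0.
#' @param layer index into the CNN layer list of the feature layer A;
#'   default is the output of the last convolution block (before pooling).
#' @return an [AttentionMap] with source "hirescam".
#' @export
hiResCAM <- function(model, x, classIndex = 1L, layer = NULL) {
  if (is.null(model$cnn))
    stop("hiResCAM: model has no CNN branch")
  if (length(dim(x)) == 4L) dim(x) <- c(dim(x), 1L)
  stopifnot(dim(x)[5] == 1L)
  if (is.null(layer)) layer <- length(model$cnn) - 2L  # last conv block out
  e <- model$cnn[[layer]]
  forwardModel(model, x, training = FALSE, retain = TRUE)
  zeroGrads(model$paramEnvs)
  backwardModel(model, if (classIndex == 1L) 1 else -1)
  A <- e$out; dA <- e$dout
  if (is.null(dim(A)) || length(dim(A)) != 5L)
    stop("hiResCAM: chosen layer has no spatial extent")
  sp <- dim(A)[1:3]; C <- dim(A)[4]
  M <- A * dA
  dim(M) <- c(prod(sp), C)
  m <- rowSums(M)
  dim(m) <- sp
  AttentionMap(values = resizeVolume(m, dim(x)[1:3]), source = "hirescam",
               classIndex = classIndex)
}

#' Attention rollout matrix
#'
#' Recursively multiplies identity-augmented attention matrices:
#' R_1 = norm(A_1 + I), R_L = norm(A_L + I) R_{L-1}, where each A_L is the
#' head-averaged self-attention matrix of layer L. With
#' `renormalize = TRUE` (default, the original rollout formulation) rows of
#' (A + I) are renormalized to sum 1 so every R_L stays row-stochastic;
#' `renormalize = FALSE` preserves the raw product (A_L + I) ... (A_1 + I).
#'
#' @param att list of L square row-stochastic matrices, identical size.
#' @param renormalize renormalize rows of (A + I) before each product.
#' @return the rollout matrix R_L.
#' @export
rolloutMatrix <- function(att, renormalize = TRUE) {
  if (length(att) < 1L) stop("rolloutMatrix: need at least one layer")
  Tn <- nrow(att[[1]])
  R <- diag(Tn)
  for (A in att) {
    if (!is.matrix(A) || nrow(A) != ncol(A) || nrow(A) != Tn)
      stop("rolloutMatrix: attention matrices must be square and same size")
    M <- A + diag(Tn)
    if (renormalize) M <- M / rowSums(M)
    R <- M %*% R
  }
  R
}

# head-average an attention array (T, T, H, N) for sample n
headAverageAttention <- function(A, n = 1L) {
  if (is.matrix(A)) return(A)
  d <- dim(A)
  m <- matrix(0, d[1], d[2])
  for (h in seq_len(d[3])) m <- m + A[, , h, n]
  m / d[3]
}

#' Attention rollout saliency map for the ViT branch
#'
#' Builds the rollout matrix from per-layer head-averaged attention,
#' reads the class-token row over the patch tokens, reshapes it to the 3D
#' patch grid and (optionally) upsamples to the input volume shape.
#'
#' @param att list of per-layer attention: (T, T) head-averaged matrices or
#'   (T, T, H, N) arrays as retained by the ViT forward pass.
#' @param grid integer(3), the patch-grid shape; `prod(grid)` must equal
#'   the number of patch tokens (tokens minus the class token).
#' @param shape optional integer(3) output volume shape for upsampling.
#' @param renormalize see [rolloutMatrix()].
#' @param classIndex class label recorded on the map.
#' @return an [AttentionMap] with source "rollout".
#' @export
attentionRollout <- function(att, grid, shape = NULL, renormalize = TRUE,
                             classIndex = 1L) {
  att <- lapply(att, headAverageAttention)
  R <- rolloutMatrix(att, renormalize = renormalize)
  sal <- R[1, -1]
  if (length(sal) != prod(grid))
    stop("attentionRollout: grid does not match token count")
  m <- array(sal, grid)
  if (!is.null(shape)) m <- resizeVolume(m, shape)
  AttentionMap(values = m, source = "rollout", classIndex = classIndex)
}

#' Attention rollout for a fitted model and input volume
#'
#' Runs the ViT branch forward to collect per-layer attention and returns
#' the rollout saliency upsampled to the input shape.
#'
#' @param model a model with a ViT branch.
#' @param x input array (X, Y, Z, C).
#' @param renormalize see [rolloutMatrix()].
#' @return an [AttentionMap].
#' @export
vitRollout <- function(model, x, renormalize = TRUE) {
  if (is.null(model$vit)) stop("vitRollout: model has no ViT branch")
  if (length(dim(x)) == 4L) dim(x) <- c(dim(x), 1L)
  forwardModel(model, x, training = FALSE, retain = TRUE)
  att <- model$vit$attentionMaps()
  attentionRollout(att, grid = model$vit$ng, shape = dim(x)[1:3],
                   renormalize = renormalize)
}

#' Overlay an attention map on a CT slice
#'
#' Blends the grayscale CT slice with a color-mapped, display-normalized
#' attention slice: `alpha = 0` returns the CT slice unchanged, `alpha = 1`
#' the pure colormap.
#'
#' @param map an [AttentionMap].
#' @param v the matching [CTVolume] (same shape).
#' @param slice axial slice index (1-based).
#' @param alpha blend weight of the attention colormap in [0, 1].
#' @param palette a palette name accepted by [grDevices::hcl.colors()].
#' @param file optional PNG output path.
#' @return an (X, Y, 3) RGB array in [0, 1], invisibly if `file` is given.
#' @export
overlaySlice <- function(map, v, slice, alpha = 0.5, palette = "Inferno",
                         file = NULL) {
  stopifnot(is(map, "AttentionMap"), is(v, "CTVolume"))
  d <- dim(v@voxels)
  if (!identical(dim(map@values), d))
    stop("overlaySlice: map and volume shapes differ")
  if (slice < 1L || slice > d[3]) stop("overlaySlice: slice out of range")
  ct <- minMaxNormalize(v@voxels)[, , slice]
  ms <- displayValues(map)[, , slice]
  pal <- grDevices::hcl.colors(256, palette)
  rgbp <- grDevices::col2rgb(pal) / 255
  idx <- pmin(pmax(as.integer(ms * 255) + 1L, 1L), 256L)
  out <- array(0, c(d[1], d[2], 3))
  for (ch in 1:3) {
    colch <- matrix(rgbp[ch, idx], d[1], d[2])
    out[, , ch] <- (1 - alpha) * ct + alpha * colch
  }
  if (!is.null(file)) {
    png::writePNG(aperm(out, c(2, 1, 3)), file)
    return(invisible(out))
  }
  out
}
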