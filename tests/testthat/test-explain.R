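test_that("rollout matches closed forms and the explicit product oracle", {
  # L = 1, uniform attention over n tokens
  n <- 5
  A <- matrix(1 / n, n, n)
  R <- rolloutMatrix(list(A))
  expect_equal(diag(R), rep(1 / (2 * n) + 1 / 2, n))
  expect_equal(R[1, 2], 1 / (2 * n))
  expect_equal(rowSums(R), rep(1, n))
  # identity attention is a fixed point at any depth
  I <- diag(n)
  expect_equal(rolloutMatrix(list(I, I, I)), I)
  # random stochastic matrices, L = 3, against the brute-force product
  set.seed(81)
  for (rep in 1:5) {
    att <- lapply(1:3, function(l) {
      m <- matrix(rexp(n * n), n, n)
      m / rowSums(m)
    })
    R3 <- rolloutMatrix(att)
    oracle <- diag(n)
    for (l in 1:3) {
      M <- att[[l]] + diag(n)
      M <- M / rowSums(M)
      oracle <- M %*% oracle
    }
    expect_lt(max(abs(R3 - oracle)), 1e-10)
    # every intermediate stays row-stochastic
    expect_equal(rowSums(R3), rep(1, n), tolerance = 1e-12)
    # raw-product mode preserves the unnormalized recursion
    raw <- rolloutMatrix(att, renormalize = FALSE)
    oracleRaw <- diag(n)
    for (l in 1:3) oracleRaw <- (att[[l]] + diag(n)) %*% oracleRaw
    expect_lt(max(abs(raw - oracleRaw)), 1e-10)
  }
  expect_error(rolloutMatrix(list(matrix(1, 2, 3))), "square")
})

test_that("attention rollout maps the class-token row onto the patch grid", {
  grid <- c(2L, 2L, 2L)
  n <- prod(grid) + 1L
  A <- matrix(1 / n, n, n)
  am <- attentionRollout(list(A), grid = grid)
  expect_s4_class(am, "AttentionMap")
  expect_equal(dim(am@values), grid)
  expect_equal(as.numeric(am@values), rep(1 / (2 * n), 8))
  up <- attentionRollout(list(A), grid = grid, shape = c(8L, 8L, 8L))
  expect_equal(dim(up@values), c(8L, 8L, 8L))
  expect_error(attentionRollout(list(A), grid = c(3L, 3L, 3L)), "grid")
})

test_that("HiResCAM reproduces the analytic map of a linear scorer", {
  # hand-built model: logit = mean over space of feature channel 1
  conv <- radct:::layerConv3d(1L, 3L, 3L, 1L, 1L)
  gap <- radct:::layerGlobalAvgPool3d()
  sel <- radct:::layerDense(3L, 1L)
  sel$params$W <- matrix(c(1, 0, 0), 1, 3); sel$params$b <- 0
  head <- radct:::layerDense(1L, 1L)
  head$params$W <- matrix(1, 1, 1); head$params$b <- 0
  cfg <- EnsembleConfig(inputChannels = 1L, inputShape = c(8L, 8L, 8L),
                        cnnFilters = c(4L), cnnFeatureDim = 1L,
                        fusion = "cnn_only")
  model <- structure(list(cfg = cfg, cnn = list(conv, gap, sel), vit = NULL,
                          head = head, fusionWidth = 1L,
                          paramEnvs = list(conv, sel, head), seed = 1L),
                     class = "radctModel")
  set.seed(82)
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8, 1, 1))
  cam <- hiResCAM(model, x, classIndex = 1L, layer = 1L)
  A <- conv$out
  S <- prod(dim(A)[1:3])
  # analytic gradient: 1/S on channel 1, 0 elsewhere => map = A[,,,1]/S
  expect_equal(cam@values, A[, , , 1, 1] / S, tolerance = 1e-12)
  expect_equal(conv$dout[, , , 2, 1], array(0, dim(A)[1:3]))
  # zero feature maps give a zero attention map
  conv$params$W <- conv$params$W * 0; conv$params$b <- conv$params$b * 0
  cam0 <- hiResCAM(model, x, classIndex = 1L, layer = 1L)
  expect_true(all(cam0@values == 0))
})

test_that("backprop input gradients match finite differences on a tiny model", {
  cfg <- tinyConfig(fusion = "cnn_only")
  m <- buildModel(cfg, seed = 83)
  set.seed(84)
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8, 1, 1))
  forwardModel(m, x, retain = TRUE)
  radct:::zeroGrads(m$paramEnvs)
  radct:::backwardModel(m, 1)   # gradient of the raw positive-class score
  g <- m$cnn[[1]]$dinput
  idx <- sample(length(x), 6)
  for (i in idx) {
    eps <- 1e-4
    x1 <- x; x1[i] <- x[i] + eps
    x2 <- x; x2[i] <- x[i] - eps
    num <- (forwardModel(m, x1)$logit - forwardModel(m, x2)$logit) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-4)
  }
})

test_that("saliency maps are deterministic and batch-size invariant", {
  cfg <- tinyConfig(channels = 2L)
  m <- buildModel(cfg, seed = 85)
  set.seed(86)
  x <- array(rnorm(8 * 8 * 8 * 2), c(8, 8, 8, 2))
  c1 <- hiResCAM(m, x)@values
  c2 <- hiResCAM(m, x)@values
  expect_identical(c1, c2)
  r1 <- vitRollout(m, x)@values
  r2 <- vitRollout(m, x)@values
  expect_identical(r1, r2)
})

test_that("overlay blending honors alpha extremes", {
  set.seed(87)
  v <- CTVolume(array(rnorm(8 * 8 * 4), c(8, 8, 4)))
  map <- AttentionMap(array(runif(8 * 8 * 4), c(8, 8, 4)), "rollout")
  o0 <- overlaySlice(map, v, 2, alpha = 0)
  ct <- minMaxNormalize(voxels(v))[, , 2]
  expect_equal(o0[, , 1], ct)
  expect_equal(o0[, , 2], ct)
  o1 <- overlaySlice(map, v, 2, alpha = 1)
  pal <- grDevices::col2rgb(grDevices::hcl.colors(256, "Inferno")) / 255
  ms <- displayValues(map)[, , 2]
  idx <- pmin(pmax(as.integer(ms * 255) + 1L, 1L), 256L)
  expect_equal(o1[, , 1], matrix(pal[1, idx], 8, 8))
  expect_error(overlaySlice(map, v, 9), "out of range")
  f <- tempfile(fileext = ".png")
  overlaySlice(map, v, 1, file = f)
  expect_true(file.exists(f))
  unlink(f)
})

test_that("HiResCAM localizes the nodule when it is the only evidence", {
  # nodule-present vs nodule-absent phantoms; a CT-only CNN must use the
  # nodule to discriminate, so its saliency peak should fall inside it
  mk <- function(seed, nod)
    makePhantom(PhantomSpec(class = "focal_nodule", noduleCount = nod,
                            noduleRadius = 5, noduleContrast = 900,
                            backgroundSd = 40, noiseSd = 25, seed = seed))
  train <- lapply(1:24, function(i) mk(500 + i, ifelse(i <= 12, 1L, 0L)))
  lab <- rep(c(1L, 0L), each = 12)
  xs <- lapply(train, function(p) {
    a <- minMaxNormalize(clipWindow(voxels(p$volume)))
    dim(a) <- c(dim(a), 1L)
    a
  })
  fit <- trainModel(xs, lab, reducedConfig(inputChannels = 1L,
                                           fusion = "cnn_only"),
                    reducedTrainSpec(seed = 3L, epochs = 15L))
  hits <- vapply(1:10, function(s) {
    p <- mk(900 + s, 1L)
    a <- minMaxNormalize(clipWindow(voxels(p$volume)))
    dim(a) <- c(dim(a), 1L)
    cam <- hiResCAM(fit$model, a, classIndex = 1L)
    pk <- which(cam@values == max(cam@values), arr.ind = TRUE)[1, ]
    p$noduleMask[pk[1], pk[2], pk[3]]
  }, logical(1))
  expect_gte(sum(hits), 8L)
})
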