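test_that("configuration validity catches inconsistent shapes", {
  expect_error(EnsembleConfig(inputShape = c(250L, 256L, 64L)),
               "divisible")
  expect_error(EnsembleConfig(vitDim = 100L, vitHeads = 7L), "divisible")
  expect_error(EnsembleConfig(cnnFilters = c(32L, 16L)), "ascending")
  expect_error(reducedConfig(inputShape = c(20L, 32L, 16L)), "divisible")
  # the full-scale defaults themselves pass the audit
  cfg <- EnsembleConfig()
  expect_identical(cfg@cnnFilters, c(16L, 32L, 64L, 128L, 256L, 512L))
  expect_identical(cfg@cnnFirstKernel, 3L)
  expect_identical(cfg@cnnDownKernel, 4L)
  expect_identical(c(cfg@cnnFeatureDim, cfg@vitDim), c(768L, 768L))
  expect_identical(c(cfg@vitDepth, cfg@vitHeads, cfg@vitPatchEdge),
                   c(12L, 6L, 16L))
})

test_that("CNN spatial dimensions halve through the stride-2 chain", {
  cfg <- EnsembleConfig(inputChannels = 1L, inputShape = c(32L, 32L, 16L),
                        cnnFilters = c(4L, 8L), cnnFeatureDim = 16L,
                        fusion = "cnn_only")
  m <- buildModel(cfg, seed = 1)
  x <- array(rnorm(32 * 32 * 16), c(32, 32, 16, 1, 1))
  out <- forwardModel(m, x, retain = TRUE)
  expect_length(out$cnnFeatures, 16L)
  # hand-computed conv arithmetic: (d + 2p - k)/s + 1
  shapes <- lapply(m$cnn, function(e) dim(e$out))
  expect_equal(shapes[[1]][1:3], c(32, 32, 16))   # k3 s1 p1 keeps size
  expect_equal(shapes[[4]][1:3], c(16, 16, 8))    # k4 s2 p1 halves
  expect_equal(shapes[[7]][1:3], c(8, 8, 4))
  expect_equal(shapes[[10]][1:2], c(8, 1))        # pooled channels x batch
})

test_that("a bias-free CNN maps zero input to zero pre-pool activations", {
  cfg <- tinyConfig(fusion = "cnn_only")
  m <- buildModel(cfg, seed = 2)
  # zero all biases and batch-norm shifts
  for (e in m$cnn) {
    if (!is.null(e$params$b)) e$params$b <- e$params$b * 0
    if (!is.null(e$params$beta)) e$params$beta <- e$params$beta * 0
  }
  x <- array(0, c(8, 8, 8, 1, 1))
  forwardModel(m, x, retain = TRUE)
  # output of the last conv block (pre-pooling) is exactly zero
  expect_true(all(m$cnn[[length(m$cnn) - 2L]]$out == 0))
})

test_that("ViT token count, attention normalization and output dims", {
  cfg <- tinyConfig(fusion = "vit_only")
  m <- buildModel(cfg, seed = 3)
  x <- array(rnorm(8 * 8 * 8 * 2), c(8, 8, 8, 1, 2))
  dim(x) <- c(8, 8, 8, 1, 2)
  out <- forwardModel(m, x, retain = TRUE)
  expect_equal(dim(out$vitFeatures), c(8L, 2L))
  att <- m$vit$attentionMaps()
  expect_length(att, 2L)                      # one tensor per block
  expect_equal(dim(att[[1]]), c(9, 9, 2, 2))  # (1+2^3) tokens, heads, batch
  for (h in 1:2) for (n in 1:2)
    expect_equal(rowSums(att[[1]][, , h, n]), rep(1, 9), tolerance = 1e-6)
  # patch-count arithmetic for the full-scale geometry
  expect_equal(prod(c(256, 256, 64) %/% 16) + 1, 1025)
})

test_that("classification head width follows the fusion mode", {
  m <- buildModel(tinyConfig(channels = 2L, fusion = "concat"), seed = 4)
  expect_equal(dim(m$head$params$W), c(1L, 12L + 8L))
  m2 <- buildModel(tinyConfig(fusion = "cnn_only"), seed = 4)
  expect_equal(dim(m2$head$params$W), c(1L, 12L))
  # concat at the full-scale feature dims gives a 1536-wide fusion input
  expect_equal(EnsembleConfig()@cnnFeatureDim + EnsembleConfig()@vitDim, 1536L)
  x <- array(rnorm(8 * 8 * 8 * 2), c(8, 8, 8, 2, 1))
  p <- forwardModel(m, x)$prob
  expect_gt(p, 0); expect_lt(p, 1)
})

test_that("forward passes are deterministic for fixed weights", {
  cfg <- tinyConfig(channels = 2L)
  m1 <- buildModel(cfg, seed = 9)
  m2 <- buildModel(cfg, seed = 9)
  x <- array(rnorm(8 * 8 * 8 * 2), c(8, 8, 8, 2, 1))
  expect_identical(forwardModel(m1, x)$logit, forwardModel(m2, x)$logit)
  expect_identical(forwardModel(m1, x)$logit, forwardModel(m1, x)$logit)
})

test_that("permuting patches with their position embeddings fixes the class token", {
  cfg <- tinyConfig(fusion = "vit_only")
  m <- buildModel(cfg, seed = 10)
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8, 1, 1))
  o1 <- forwardModel(m, x)$vitFeatures
  set.seed(101)
  perm <- sample(m$vit$P)
  m$vit$gather <- m$vit$gather[, perm]
  m$vit$params$pos <- m$vit$params$pos[, c(1L, 1L + perm)]
  o2 <- forwardModel(m, x)$vitFeatures
  expect_equal(o1, o2, tolerance = 1e-10)
})

test_that("gradients agree with central finite differences end to end", {
  cfg <- tinyConfig(channels = 2L)
  m <- buildModel(cfg, seed = 11)
  set.seed(111)
  x <- array(rnorm(8 * 8 * 8 * 2 * 2), c(8, 8, 8, 2, 2))
  y <- c(1, 0)
  lossAt <- function() {
    p <- forwardModel(m, x, training = TRUE)$prob
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  out <- forwardModel(m, x, training = TRUE)
  zeroGrads <- get("zeroGrads", asNamespace("radct"))
  backwardModel <- get("backwardModel", asNamespace("radct"))
  zeroGrads(m$paramEnvs)
  backwardModel(m, (out$prob - y) / 2)
  for (e in m$paramEnvs[c(1, 3, 7, length(m$paramEnvs))]) {
    for (nm in names(e$params)) {
      i <- sample(length(e$params[[nm]]), 1L)
      p0 <- e$params[[nm]][i]; eps <- 1e-5
      e$params[[nm]][i] <- p0 + eps; up <- lossAt()
      e$params[[nm]][i] <- p0 - eps; dn <- lossAt()
      e$params[[nm]][i] <- p0
      g <- (up - dn) / (2 * eps)
      expect_equal(e$grads[[nm]][i], g, tolerance = 1e-4)
    }
  }
})

test_that("model checkpoints round-trip weights and running statistics", {
  cfg <- tinyConfig(channels = 2L)
  m <- buildModel(cfg, seed = 21)
  set.seed(22)
  x <- array(rnorm(8 * 8 * 8 * 2 * 2), c(8, 8, 8, 2, 2))
  invisible(forwardModel(m, x, training = TRUE))  # move BN running stats
  p1 <- forwardModel(m, x)$prob
  f <- tempfile(fileext = ".rds")
  saveModel(m, f)
  m2 <- loadModel(f)
  expect_identical(forwardModel(m2, x)$prob, p1)
  expect_identical(m2$cfg, cfg)
  unlink(f)
})
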