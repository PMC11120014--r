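test_that("gray-level quantization follows the floor boundary rule", {
  expect_identical(quantizeGrayLevels(c(0, 0.5, 1), 2), c(0L, 1L, 1L))
  expect_identical(quantizeGrayLevels(array(4, c(2, 2, 2)), 8),
                   array(0L, c(2, 2, 2)))
  expect_error(quantizeGrayLevels(1:3, 1), "G must be")
  expect_error(quantizeGrayLevels(c(1, Inf), 4), "NaN/Inf")
  # against an independent binning oracle, and monotone
  set.seed(31)
  a <- runif(500, -3, 7)
  q <- quantizeGrayLevels(a, 8)
  lo <- min(a); hi <- max(a)
  oracle <- pmin(findInterval(a, seq(lo, hi, length.out = 9),
                              rightmost.closed = TRUE) - 1L, 7L)
  expect_identical(q, oracle)
  ord <- order(a)
  expect_true(all(diff(q[ord]) >= 0))
})

test_that("window GLCMs are symmetric, normalized and match enumeration", {
  # constant window: a single diagonal cell
  q <- array(2L, c(3, 3, 3))
  g <- glcmWindow(q, c(1, 0, 0), 4)
  expect_equal(g[3, 3], 1)
  expect_equal(sum(g), 1)
  # alternating two-level stripes along x vs brute-force pair counts
  q2 <- array(rep(c(0L, 1L), length.out = 27), c(3, 3, 3))
  for (off in list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1))) {
    got <- glcmWindow(q2, off, 2)
    expect_equal(got, naiveGLCM(q2, off, 2))
  }
  # random windows: construction invariants
  set.seed(32)
  for (i in 1:10) {
    qr <- array(sample(0:3, 27, replace = TRUE), c(3, 3, 3))
    g <- glcmWindow(qr, c(1, 0, 0), 4)
    expect_equal(sum(g), 1, tolerance = 1e-12)
    expect_equal(g, t(g))
    expect_equal(g, naiveGLCM(qr, c(1, 0, 0), 4))
  }
  expect_error(glcmWindow(array(0L, c(2, 2, 2)), c(3, 0, 0), 2),
               "no valid pairs")
})

test_that("Haralick statistics match hand values and the loop oracle", {
  # delta distribution p(k,k) = 1
  G <- 5; m <- matrix(0, G, G); m[3, 3] <- 1
  f <- haralickFeatures(m)
  expect_equal(unname(f[c("Energy", "Entropy", "Inertia",
                          "InverseDifferenceMoment", "ClusterShade",
                          "ClusterProminence", "Correlation")]),
               c(1, 0, 0, 1, 0, 0, 0))
  # the marginal-frequency convention gives the oracle's (nonzero) value
  expect_equal(unname(f["HaralickCorrelation"]),
               unname(naiveHaralick(m)["HaralickCorrelation"]))
  # uniform 2x2 GLCM, hand-evaluated sums
  u <- matrix(0.25, 2, 2)
  fu <- haralickFeatures(u)
  expect_equal(unname(fu[c("Energy", "Entropy", "Inertia",
                           "InverseDifferenceMoment")]),
               c(0.25, 2, 0.5, 0.75))
  # uniform marginal: zero marginal-value variance, degenerate rule
  expect_equal(unname(fu["HaralickCorrelation"]), 0)
  # random valid GLCMs against the naive double-loop oracle
  set.seed(33)
  for (i in 1:10) {
    r <- matrix(rexp(64), 8, 8)
    r <- r + t(r)
    r <- r / sum(r)
    expect_equal(haralickFeatures(r), naiveHaralick(r), tolerance = 1e-10)
  }
  expect_error(haralickFeatures(matrix(0.5, 2, 2)), "not normalized")
})

test_that("texture maps equal per-window recomputation at sampled voxels", {
  set.seed(34)
  for (d in list(c(6L, 6L, 6L), c(10L, 8L, 7L))) {
    a <- array(rnorm(prod(d)), d)
    G <- 6L
    tm <- textureMapList(textureMaps(a, TextureSpec(grayLevels = G)))
    q <- quantizeGrayLevels(a, G)
    vox <- rbind(c(3, 3, 3), c(1, 1, 1), d, c(2, d[2] - 1, 3))
    for (r in seq_len(nrow(vox))) {
      oracle <- naiveTextureAtVoxel(q, vox[r, ], G)
      got <- vapply(HARALICK_FEATURES, function(f)
        tm[[f]][vox[r, 1], vox[r, 2], vox[r, 3]], numeric(1))
      expect_equal(unname(got), unname(oracle), tolerance = 1e-8)
    }
  }
})

test_that("six-cube striped phantom matches the oracle at interior voxels", {
  stripes <- array(rep(c(-800, -200), length.out = 6), c(6, 6, 6))
  G <- 4L
  tm <- textureMapList(textureMaps(stripes, TextureSpec(grayLevels = G)))
  q <- quantizeGrayLevels(stripes, G)
  for (v in list(c(2, 2, 2), c(3, 3, 3), c(4, 2, 4), c(2, 4, 3), c(5, 5, 5))) {
    oracle <- naiveTextureAtVoxel(q, v, G)
    got <- vapply(HARALICK_FEATURES, function(f) tm[[f]][v[1], v[2], v[3]],
                  numeric(1))
    expect_equal(unname(got), unname(oracle), tolerance = 1e-10)
  }
})

test_that("constant volumes give Energy 1 and Entropy 0 everywhere", {
  tm <- textureMapList(textureMaps(array(-600, c(5, 5, 5)),
                                   TextureSpec(grayLevels = 16)))
  expect_true(all(tm$Energy == 1))
  expect_true(all(tm$Entropy == 0))
  expect_true(all(tm$InverseDifferenceMoment == 1))
  expect_equal(dim(tm$Correlation), c(5L, 5L, 5L))
  expect_setequal(names(tm), HARALICK_FEATURES)
})

test_that("Energy is at most 1, reaching 1 only for constant windows", {
  set.seed(35)
  a <- array(rnorm(6^3), c(6, 6, 6))
  en <- textureMapList(textureMaps(a, TextureSpec(grayLevels = 4)))$Energy
  expect_true(all(en <= 1 + 1e-12))
  expect_true(all(en < 1))   # continuous noise: no constant window
})

test_that("texture maps are translation-equivariant on interior voxels", {
  set.seed(36)
  a <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  sh <- array(0, c(8, 8, 8))
  sh[2:8, , ] <- a[1:7, , ]   # shift by +1 along x
  spec <- TextureSpec(grayLevels = 5, quantizeRange = range(a))
  m1 <- textureMapList(textureMaps(a, spec))$Entropy
  m2 <- textureMapList(textureMaps(sh, spec))$Entropy
  # compare deep-interior voxels (away from both borders)
  expect_equal(m2[4:7, 3:6, 3:6], m1[3:6, 3:6, 3:6], tolerance = 1e-12)
})

test_that("per-window quantization mode agrees with its direct definition", {
  set.seed(37)
  a <- array(rnorm(4^3), c(4, 4, 4))
  tm <- textureMapList(textureMaps(a, TextureSpec(grayLevels = 4,
                                                  perWindowQuantize = TRUE)))
  v <- c(2, 3, 2)
  w <- replWindow(a, v, 1L)
  oracle <- naiveTextureAtVoxel(quantizeGrayLevels(w, 4), c(2, 2, 2), 4L)
  got <- vapply(HARALICK_FEATURES, function(f) tm[[f]][v[1], v[2], v[3]],
                numeric(1))
  expect_equal(unname(got), unname(oracle), tolerance = 1e-10)
})

test_that("volumes smaller than the window are rejected", {
  expect_error(textureMaps(array(0, c(2, 5, 5)), TextureSpec()), "smaller")
})
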