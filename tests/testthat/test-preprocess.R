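test_that("min-max normalization maps endpoints and degenerates to zero", {
  expect_equal(minMaxNormalize(c(-1, 0, 3)), c(0, 0.25, 1))
  expect_equal(minMaxNormalize(array(7, c(3, 3, 2))), array(0, c(3, 3, 2)))
  expect_error(minMaxNormalize(c(1, NaN)), "NaN")
  # idempotence on random arrays
  set.seed(11)
  for (i in 1:5) {
    a <- array(rnorm(60), c(5, 4, 3))
    n1 <- minMaxNormalize(a)
    expect_equal(minMaxNormalize(n1), n1, tolerance = 1e-12)
    expect_equal(range(n1), c(0, 1))
  }
})

test_that("window clipping pins out-of-range HU to the window edges", {
  expect_equal(clipWindow(-2000), -1000)
  expect_equal(clipWindow(3000), 400)
  expect_equal(clipWindow(c(-500, 0)), c(-500, 0))
})

test_that("clip-then-normalize preserves voxel ordering in the window", {
  set.seed(12)
  a <- rnorm(200, mean = -300, sd = 500)
  n <- minMaxNormalize(clipWindow(a))
  inwin <- a > -1000 & a < 400
  ord <- order(a[inwin])
  expect_true(all(diff(n[inwin][ord]) >= 0))
})

test_that("center crop keeps the central in-plane fraction", {
  a <- array(seq_len(8 * 8 * 2), c(8, 8, 2))
  cc <- centerCrop(a, 0.5)
  expect_equal(dim(cc), c(4L, 4L, 2L))
  expect_equal(cc[1, 1, 1], a[3, 3, 1])
  expect_identical(centerCrop(a, 1), a)
})

test_that("preprocessVolume yields the target shape with clipped values", {
  set.seed(13)
  v <- CTVolume(array(rnorm(64 * 64 * 16, -300, 800), c(64, 64, 16)),
                spacing = c(0.8, 0.8, 2.5), label = 1L)
  spec <- PreprocessSpec(targetShape = c(32L, 32L, 16L))
  out <- preprocessVolume(v, spec)
  expect_equal(dim(out), c(32L, 32L, 16L))
  expect_gte(min(voxels(out)), -1000)
  expect_lte(max(voxels(out)), 400)
  expect_identical(volumeLabel(out), 1L)
  # output shape is target regardless of input shape
  v2 <- CTVolume(array(0, c(17, 23, 9)))
  expect_equal(dim(preprocessVolume(v2, spec)), c(32L, 32L, 16L))
  # constant input stays constant at the clipped value
  v3 <- CTVolume(array(1200, c(16, 16, 8)))
  expect_equal(unique(as.numeric(voxels(preprocessVolume(v3, spec)))), 400)
  expect_error(preprocessVolume(CTVolume(array(0, c(1, 4, 4))), spec),
               "2 voxels")
})

test_that("default preprocessing grid is 256 x 256 x 64", {
  expect_identical(PreprocessSpec()@targetShape, c(256L, 256L, 64L))
  expect_identical(PreprocessSpec()@window, c(-1000, 400))
})

test_that("trilinear resize is exact for constants and linear ramps", {
  expect_equal(resizeVolume(array(3.5, c(6, 5, 4)), c(9, 9, 3)),
               array(3.5, c(9, 9, 3)))
  # a linear ramp along x is reproduced at interior sample points
  a <- array(rep(seq(0, 1, length.out = 16), 16 * 4), c(16, 16, 4))
  r <- resizeVolume(a, c(8, 8, 4))
  expect_equal(r[, 1, 1], a[seq(1, 16, by = 2), 1, 1] + 1 / 30,
               tolerance = 1e-10)
})
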