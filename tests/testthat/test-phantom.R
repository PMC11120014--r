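test_that("phantoms are seed-deterministic and leave the caller's RNG alone", {
  sp <- PhantomSpec(seed = 91L)
  p1 <- makePhantom(sp)
  p2 <- makePhantom(sp)
  expect_identical(voxels(p1$volume), voxels(p2$volume))
  set.seed(7); before <- rnorm(3)
  set.seed(7); invisible(makePhantom(sp)); after <- rnorm(3)
  expect_identical(before, after)
  expect_identical(volumeLabel(p1$volume), 1L)
  expect_identical(volumeLabel(makePhantom(
    PhantomSpec(class = "focal_nodule", seed = 1))$volume), 0L)
})

test_that("degenerate specs give constant backgrounds and fitting errors", {
  sp <- PhantomSpec(class = "focal_nodule", noduleCount = 0L,
                    backgroundSd = 0, noiseSd = 0, seed = 2L)
  p <- makePhantom(sp)
  expect_equal(unique(as.numeric(voxels(p$volume))), -800)
  expect_false(any(p$noduleMask))
  expect_error(PhantomSpec(class = "focal_nodule", noduleRadius = 20,
                           shape = c(16L, 16L, 16L)),
               "do not fit")
})

test_that("focal phantoms contain hyperintense spheres where masked", {
  p <- makePhantom(PhantomSpec(class = "focal_nodule", seed = 3L))
  v <- voxels(p$volume)
  expect_gt(sum(p$noduleMask), 0)
  expect_gt(mean(v[p$noduleMask]), mean(v[!p$noduleMask]) + 300)
})

test_that("cohorts are balanced, reproducible and manifest-consistent", {
  co <- makeCohort(5, seed = 4L)
  expect_length(co$volumes, 10L)
  expect_equal(sum(co$manifest$label), 5L)
  expect_identical(co$manifest$label,
                   vapply(co$volumes, volumeLabel, integer(1)))
  co2 <- makeCohort(5, seed = 4L)
  expect_identical(voxels(co$volumes[[3]]), voxels(co2$volumes[[3]]))
  # manifest round-trips through CSV
  f <- tempfile(fileext = ".csv")
  write.csv(co$manifest, f, row.names = FALSE)
  expect_equal(read.csv(f), co$manifest)
  unlink(f)
})

test_that("volume-mean HaralickCorrelation recovers the label", {
  ts <- TextureSpec(quantizeRange = c(-1000, 400))
  co <- makeCohort(10, seed = 5L)
  lab <- vapply(co$volumes, volumeLabel, integer(1))
  hc <- vapply(co$volumes, function(v)
    mean(textureMapList(textureMaps(clipWindow(voxels(v)), ts))$HaralickCorrelation),
    numeric(1))
  # threshold-free ranking statistic: separation AUC
  auc <- mean(outer(hc[lab == 1], hc[lab == 0], ">"))
  expect_gte(auc, 0.95)
  # accuracy at the midpoint threshold between class means
  thr <- (mean(hc[lab == 1]) + mean(hc[lab == 0])) / 2
  expect_gte(mean((hc > thr) == (lab == 1)), 0.95)
})

test_that("the class margin grows with the texture correlation length", {
  ts <- TextureSpec(quantizeRange = c(-1000, 400))
  meanHC <- function(v)
    mean(textureMapList(textureMaps(clipWindow(voxels(v)), ts))$HaralickCorrelation)
  margin <- function(L, s) {
    co <- makeCohort(3, seed = 200 + s, textureCorrelationLength = L)
    lab <- vapply(co$volumes, volumeLabel, integer(1))
    hc <- vapply(co$volumes, meanHC, numeric(1))
    mean(hc[lab == 1]) - mean(hc[lab == 0])
  }
  M <- vapply(c(0.8, 1.5, 2.5), function(L)
    mean(vapply(1:10, function(s) margin(L, s), numeric(1))), numeric(1))
  expect_true(all(M > 0))
  expect_true(all(diff(M) > 0))
})

test_that("the hard regime shrinks the texture effect size", {
  ts <- TextureSpec(quantizeRange = c(-1000, 400))
  meanHC <- function(v)
    mean(textureMapList(textureMaps(clipWindow(voxels(v)), ts))$HaralickCorrelation)
  gap <- function(regime) {
    co <- makeCohort(4, seed = 6L, regime = regime)
    lab <- vapply(co$volumes, volumeLabel, integer(1))
    hc <- vapply(co$volumes, meanHC, numeric(1))
    mean(hc[lab == 1]) - mean(hc[lab == 0])
  }
  expect_lt(gap("hard"), gap("easy"))
})
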