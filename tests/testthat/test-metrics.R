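test_that("the five metric formulas match hand evaluation", {
  expect_equal(unname(computeMetrics(ConfusionMatrix(10, 10, 0, 0))),
               rep(1, 5))
  m <- computeMetrics(ConfusionMatrix(tp = 8, tn = 6, fp = 4, fn = 2))
  expect_equal(unname(m),
               c(0.8, 0.6, 2 / 3, 0.7, 2 * (2 / 3) * 0.8 / (2 / 3 + 0.8)))
  expect_equal(unname(m["f1"]), 0.72727, tolerance = 1e-4)
  # swapping the positive-class convention swaps sensitivity/specificity
  sw <- computeMetrics(ConfusionMatrix(tp = 6, tn = 8, fp = 2, fn = 4))
  expect_equal(sw[["sensitivity"]], m[["specificity"]])
  expect_equal(sw[["specificity"]], m[["sensitivity"]])
  # undefined denominators are NA; the empty matrix errors
  expect_true(is.na(computeMetrics(ConfusionMatrix(0, 5, 0, 0))[["precision"]]))
  expect_error(computeMetrics(ConfusionMatrix(0, 0, 0, 0)), "empty")
})

test_that("confusion counts partition the evaluated volumes", {
  set.seed(71)
  for (i in 1:5) {
    n <- sample(10:40, 1)
    sc <- runif(n); lab <- rbinom(n, 1, 0.5)
    cm <- confusionFromScores(sc, lab)
    expect_equal(cm@tp + cm@tn + cm@fp + cm@fn, n)
    # independent recomputation from raw prediction/label pairs
    pred <- as.integer(sc >= 0.5)
    expect_equal(cm@tp, sum(pred & lab))
    expect_equal(cm@fp, sum(pred & !lab))
  }
})

test_that("trapezoidal pooled AUC equals the normalized Mann-Whitney U", {
  set.seed(72)
  for (i in 1:10) {
    n1 <- sample(5:30, 1); n0 <- sample(5:30, 1)
    sc <- c(rnorm(n1, 0.3), rnorm(n0))
    lab <- c(rep(1, n1), rep(0, n0))
    auc <- pooledAUC(sc, lab)
    u <- sum(outer(sc[lab == 1], sc[lab == 0],
                   function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(auc, u / (n1 * n0), tolerance = 1e-10)
  }
})

test_that("normalized confusion rates are per-true-class", {
  nc <- normalizedConfusion(ConfusionMatrix(tp = 8, tn = 6, fp = 4, fn = 2))
  expect_equal(unname(nc[1, ]), c(0.8, 0.2))
  expect_equal(unname(nc[2, ]), c(0.4, 0.6))
  expect_equal(unname(rowSums(nc)), c(1, 1))
})

test_that("a label-blind scorer attains chance-level pooled AUC", {
  # permutation null: scores from an untrained model, labels permuted per
  # seed, on a balanced synthetic cohort
  inp <- cohortInputs(10, seed = 73)
  xs <- lapply(seq_along(inp$ct), function(i)
    stackChannels(inp$ct[[i]], inp$rad[[i]]))
  sc <- predictProb(buildModel(reducedConfig(inputChannels = 2L),
                               seed = 73), xs)
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    pooledAUC(sc, sample(inp$labels))
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})
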