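test_that("confidence and uncertainty match direct arithmetic", {
  probs <- c(0.9, 0.7, 0.2, 0.6)   # maxima: 0.9, 0.7, 0.8, 0.6
  expect_equal(ensembleConfidence(probs), 0.75, tolerance = 1e-12)
  expect_equal(ensembleUncertainty(probs), 0.1118034, tolerance = 1e-6)
  # degenerate symmetry
  expect_equal(ensembleConfidence(rep(0.5, 10)), 0.5)
  expect_equal(ensembleUncertainty(rep(0.5, 10)), 0)
  expect_equal(ensembleUncertainty(rep(0.83, 25)), 0)
})

test_that("ensemble statistics equal a brute-force loop on random vectors", {
  bruteConf <- function(p) {
    acc <- 0
    for (pi in p) acc <- acc + max(pi, 1 - pi)
    acc / length(p)
  }
  bruteUnc <- function(p) {
    m <- numeric(length(p))
    for (i in seq_along(p)) m[i] <- max(p[i], 1 - p[i])
    mu <- sum(m) / length(m)
    sqrt(sum((m - mu)^2) / length(m))
  }
  withr::with_seed(11, {
    worst <- 0
    for (i in 1:1000) {
      p <- runif(sample(2:50, 1))
      worst <- max(worst,
                   abs(ensembleConfidence(p) - bruteConf(p)),
                   abs(ensembleUncertainty(p) - bruteUnc(p)))
    }
    expect_lt(worst, 1e-12)
  })
})

test_that("confidence and uncertainty respect their bounds", {
  withr::with_seed(12, {
    for (i in 1:200) {
      p <- runif(sample(2:40, 1))
      cf <- ensembleConfidence(p)
      un <- ensembleUncertainty(p)
      expect_true(cf >= 0.5 && cf <= 1)
      expect_true(un >= 0 && un <= 0.5)
    }
  })
})

test_that("ensembles train 25 deterministic heads sharing one representation", {
  ps <- smallLabeledPairs(50, seed = 2)
  m <- trainEnsemble(ps, "prototype", n = 25, baseSeed = 1)
  expect_identical(nHeads(m), 25L)
  expect_error(trainEnsemble(ps, "prototype", n = 1), "config error")

  pr1 <- ensemblePredict(m, ps[1:10])
  m2 <- trainEnsemble(ps, "prototype", n = 25, baseSeed = 1)
  pr2 <- ensemblePredict(m2, ps[1:10])
  expect_equal(pr1, pr2, tolerance = 1e-12)

  unlabeled <- PairSet(pairIds(ps), unname(sequences(ps)),
                       unname(plastics(ps)), NA)
  expect_error(trainEnsemble(unlabeled, "mlp"), "labeled")
})

test_that("ensemble predictions are consistent with their per-head matrix", {
  ps <- smallLabeledPairs(40, seed = 4)
  m <- trainEnsemble(ps, "prototype", n = 10, baseSeed = 3)
  pr <- ensemblePredict(m, ps[1:8])
  hp <- headProbabilities(pr)
  expect_identical(dim(hp), c(8L, 10L))
  expect_equal(pr$confidence, unname(apply(hp, 1, ensembleConfidence)))
  expect_equal(pr$uncertainty, unname(apply(hp, 1, ensembleUncertainty)))
  expect_equal(pr$meanProb, unname(rowMeans(hp)))
  expect_identical(pr$predictedClass, as.integer(pr$meanProb > 0.5))
  expect_true(all(pr$confidence >= 0.5 & pr$confidence <= 1))
  expect_true(all(pr$uncertainty >= 0 & pr$uncertainty <= 0.5))
})

test_that("threshold filtering is strict and monotone", {
  expect_identical(nrow(filterByThresholds(
    fakePreds(0.95, 0.01), confMin = 0.9, uncMax = 0.05)), 1L)
  expect_identical(nrow(filterByThresholds(
    fakePreds(0.95, 0.01), confMin = 0.99, uncMax = 0.001)), 0L)
  # strict inequalities: a pair at the threshold is excluded
  expect_identical(nrow(filterByThresholds(
    fakePreds(0.9, 0.05), confMin = 0.9, uncMax = 0.1)), 0L)

  withr::with_seed(13, {
    preds <- fakePreds(runif(50, 0.5, 1), runif(50, 0, 0.5))
    grid <- expand.grid(conf = c(NA, 0.6, 0.8, 0.9),
                        unc = c(NA, 0.3, 0.1, 0.05))
    for (i in seq_len(nrow(grid))) {
      for (j in seq_len(nrow(grid))) {
        looseC <- grid$conf[i]; strictC <- grid$conf[j]
        looseU <- grid$unc[i]; strictU <- grid$unc[j]
        dominated <-
          (is.na(looseC) | (!is.na(strictC) && strictC >= looseC)) &&
          (is.na(looseU) | (!is.na(strictU) && strictU <= looseU))
        if (!dominated) next
        keepStrict <- filterByThresholds(preds, strictC, strictU)$pairId
        keepLoose <- filterByThresholds(preds, looseC, looseU)$pairId
        expect_true(all(keepStrict %in% keepLoose))
      }
    }
  })
})

test_that("classification metrics follow the four standard formulas", {
  # 16 correct of 17 evaluated
  m <- computeMetrics(predicted = c(rep(1, 16), 0), truth = rep(1, 17))
  expect_equal(m$accuracy, 0.941, tolerance = 5e-4)

  m2 <- computeMetrics(c(rep(1, 5), rep(0, 5)), c(rep(1, 5), rep(0, 5)))
  expect_equal(m2$precision, 1)
  expect_equal(m2$recall, 1)
  expect_equal(m2$f1, 1)
  expect_equal(m2$accuracy, 1)

  # no predicted positives: degenerate precision, not an error
  m3 <- computeMetrics(rep(0, 4), c(0, 0, 0, 0))
  expect_equal(m3$precision, 0)
  expect_true(m3$degenerate[["precision"]])

  withr::with_seed(14, {
    for (i in 1:20) {
      pred <- sample(0:1, 30, replace = TRUE)
      tr <- sample(0:1, 30, replace = TRUE)
      mt <- computeMetrics(pred, tr)
      expect_equal(mt$accuracy, mean(pred == tr))
      expect_identical(mt$TP + mt$FP + mt$TN + mt$FN, 30L)
      if (!any(mt$degenerate)) {
        expect_equal(mt$f1, 2 / (1 / mt$precision + 1 / mt$recall))
      }
    }
  })
})

test_that("threshold grid reports the unfiltered cell and empty cells", {
  withr::with_seed(15, {
    preds <- fakePreds(runif(30, 0.5, 1), runif(30, 0, 0.3),
                       class = sample(0:1, 30, replace = TRUE))
    truth <- stats::setNames(sample(0:1, 30, replace = TRUE), preds$pairId)
  })
  g <- thresholdGridReport(preds, truth, confGrid = c(NA, 0.7),
                           uncGrid = c(NA, 0.1))
  expect_identical(nrow(g), 4L)  # the (NA, NA) unfiltered cell + 3 others
  unf <- g[is.na(g$confMin) & is.na(g$uncMax), ]
  all <- computeMetrics(preds$predictedClass, truth[preds$pairId])
  expect_equal(unf$accuracy, all$accuracy)
  expect_identical(unf$n, 30L)
  # an impossible cell reports n = 0 with NA metrics
  g2 <- thresholdGridReport(preds, truth, confGrid = 0.999, uncGrid = 1e-6)
  cell <- g2[!is.na(g2$confMin), ]
  expect_identical(cell$n, 0L)
  expect_true(is.na(cell$accuracy))
})
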