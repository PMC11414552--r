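test_that("rank aggregation orders by joint confidence and uncertainty", {
  preds <- fakePreds(conf = c(0.99, 0.95, 0.90), unc = c(0.01, 0.02, 0.05),
                     ids = c("A", "B", "C"))
  rk <- rankPredictions(preds)
  expect_identical(rk$pairId[order(rk$position)], c("A", "B", "C"))
  # ties in both statistics give equal ranking values
  rk2 <- rankPredictions(fakePreds(c(0.9, 0.9, 0.7), c(0.1, 0.1, 0.1)))
  expect_equal(rk2$rankingValue[1], rk2$rankingValue[2])
  # a single prediction ranks 1
  rk3 <- rankPredictions(fakePreds(0.8, 0.1))
  expect_equal(rk3$rankingValue, 1)
  expect_identical(rk3$position, 1L)
  expect_error(rankPredictions(fakePreds(numeric(0), numeric(0))), "empty")
})

test_that("ranking values equal a brute-force rank-of-sum-of-ranks oracle", {
  withr::with_seed(21, {
    worst <- 0
    for (i in 1:1000) {
      n <- sample(3:30, 1)
      conf <- round(runif(n, 0.5, 1), 2)     # rounding forces ties
      unc <- round(runif(n, 0.001, 0.5), 2)
      rk <- rankPredictions(fakePreds(conf, unc))
      oracle <- oracleRank(oracleRank(conf) + oracleRank(1 / unc))
      worst <- max(worst, max(abs(rk$rankingValue - oracle)))
    }
    expect_lt(worst, 1e-12)
  })
})

test_that("zero-uncertainty pairs tie at the best inverse-uncertainty rank", {
  preds <- fakePreds(conf = c(0.9, 0.9, 0.9, 0.8),
                     unc = c(0, 0, 0.1, 0.2),
                     ids = c("z1", "z2", "u1", "u2"))
  rk <- rankPredictions(preds)
  expect_true(all(is.finite(rk$rankingValue)))
  expect_equal(rk$rankingValue[1], rk$rankingValue[2])
  expect_true(all(rk$position[1:2] < rk$position[3]))
})

test_that("dominance: better on both statistics never ranks worse", {
  withr::with_seed(22, {
    for (rep in 1:25) {
      n <- 20
      conf <- round(runif(n, 0.5, 1), 2)
      unc <- round(runif(n, 0, 0.5), 2)
      rk <- rankPredictions(fakePreds(conf, unc))
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (conf[i] >= conf[j] && unc[i] <= unc[j]) {
            expect_gte(rk$rankingValue[i], rk$rankingValue[j])
            if (conf[i] > conf[j] && unc[i] < unc[j]) {
              expect_gt(rk$rankingValue[i], rk$rankingValue[j])
            }
          }
        }
      }
    }
  })
})

test_that("top fractions use k = floor(p * n) with a minimum of one", {
  rk71 <- rankPredictions(fakePreds(runif(71, 0.5, 1), runif(71, 0, 0.5)))
  expect_length(topFraction(rk71, 0.30), 21)  # the top 30% of 71
  expect_length(topFraction(rk71, 0.20), 14)  # the top 20% of 71
  rk100 <- rankPredictions(fakePreds(runif(100, 0.5, 1), runif(100, 0, 0.5)))
  expect_length(topFraction(rk100, 0.10), 10)
  expect_length(topFraction(rk100, 0.001), 1)
  # best-ranked pair comes first
  expect_identical(topFraction(rk71, 0.30)[1],
                   rk71$pairId[rk71$position == 1])
})

test_that("multi-seed runs vote and average per pair", {
  ps <- smallLabeledPairs(40, seed = 5)
  sp <- splitTrainTest(ps, 0.3, seed = 1)
  multi <- runMultiSeed(sp$train, sp$test, seeds = c(4, 4, 4),
                        headKind = "prototype", n = 5)
  # identical seeds: all runs identical, vote equals the single run
  expect_equal(multi$runs[[1]]$rankingValue, multi$runs[[3]]$rankingValue)
  expect_identical(multi$summary$voteClass, multi$runs[[1]]$predictedClass)
  expect_equal(multi$summary$meanConfidence, multi$runs[[2]]$confidence)
  expect_error(
    runMultiSeed(sp$train, sp$test, seeds = c(1, 2), headKind = "prototype",
                 n = 5),
    "odd number")
})

test_that("majority vote and averages follow direct arithmetic", {
  runs <- list(
    fakePreds(c(0.9, 0.9), c(0.1, 0.1), ids = c("a", "b"), class = c(1L, 1L)),
    fakePreds(c(0.8, 0.8), c(0.1, 0.1), ids = c("a", "b"), class = c(1L, 0L)),
    fakePreds(c(1.0, 1.0), c(0.1, 0.1), ids = c("a", "b"), class = c(0L, 1L)),
    fakePreds(c(0.7, 0.7), c(0.1, 0.1), ids = c("a", "b"), class = c(1L, 0L)),
    fakePreds(c(0.6, 0.6), c(0.1, 0.1), ids = c("a", "b"), class = c(0L, 0L)))
  multi <- fakeMultiRun(runs)
  expect_identical(multi$summary$voteClass, c(1L, 0L))  # 3/5 vs 2/5 votes
  expect_equal(multi$summary$meanConfidence, c(0.80, 0.80))
})

test_that("common top lists are intersections bounded by k", {
  mk <- function(ids) {
    n <- length(ids)
    fakePreds(seq(0.99, 0.6, length.out = n), seq(0.01, 0.3, length.out = n),
              ids = ids)
  }
  # five runs whose top-3 sets are {A,B,C},{A,B,D},{A,B,E},{A,B,C},{A,B,F}
  runs <- list(mk(c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J")),
               mk(c("A", "B", "D", "C", "E", "F", "G", "H", "I", "J")),
               mk(c("A", "B", "E", "C", "D", "F", "G", "H", "I", "J")),
               mk(c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J")),
               mk(c("A", "B", "F", "C", "D", "E", "G", "H", "I", "J")))
  multi <- fakeMultiRun(runs)
  rep <- commonTopList(multi, 0.3)
  expect_identical(sort(rep$common), c("A", "B"))
  expect_identical(rep$k, 3L)

  # identical runs: the common set is the full per-run top list
  multi2 <- fakeMultiRun(runs[c(1, 1, 1)])
  rep2 <- commonTopList(multi2, 0.3)
  expect_identical(rep2$size, rep2$k)

  # property: |common| <= k under random configurations
  withr::with_seed(23, {
    for (i in 1:10) {
      rr <- lapply(1:5, function(j) {
        fakePreds(runif(20, 0.5, 1), runif(20, 0, 0.5),
                  ids = sprintf("p%02d", 1:20))
      })
      mi <- fakeMultiRun(rr)
      p <- runif(1, 0.1, 0.9)
      rep <- suppressWarnings(commonTopList(mi, p))
      expect_lte(rep$size, max(1L, floor(p * 20)))
    }
  })

  # labels give accuracy over the common list via the majority vote
  labels <- stats::setNames(rep(1L, 10), LETTERS[1:10])
  rep3 <- commonTopList(multi, 0.3, labels = labels)
  expect_equal(rep3$accuracy, 1)
})

test_that("the ranking matrix has one valid tie-averaged rank row per run", {
  ps <- smallLabeledPairs(30, seed = 6)
  sp <- splitTrainTest(ps, 0.3, seed = 2)
  multi <- runMultiSeed(sp$train, sp$test, seeds = c(1, 2, 3),
                        headKind = "prototype", n = 5)
  m <- rankingHeatmapTable(multi)
  expect_identical(dim(m), c(3L, length(sp$test)))
  n <- ncol(m)
  for (i in 1:3) {
    # tie-averaged ascending ranks always sum to n(n+1)/2
    expect_equal(sum(m[i, ]), n * (n + 1) / 2)
  }
})
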