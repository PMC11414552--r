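# Small blended pool plus synthetic ranked runs, no trained model needed.
makePool <- function(nCand = 400, nTagged = 20, seed = 1) {
  spec <- syntheticSpec(nPairs = nTagged, nUniqueSequences = nTagged,
                        lengthRange = c(60L, 80L), motifCopies = 1L,
                        seed = seed)
  cand <- generateCandidatePool(spec, nCandidates = nCand,
                                truePositiveFraction = 0)$pool
  tagged <- generateExperimentalLike(syntheticSpec(
    nPairs = nTagged, nUniqueSequences = nTagged, positiveFraction = 1,
    lengthRange = c(60L, 80L), motifCopies = 1L, seed = seed + 1))
  blendPool(cand, tagged, seed = seed)
}

# One ranked run driven by a scoring rule over the pool.
scoredRun <- function(pool, scorer) {
  ids <- poolManifest(pool)$pair_id
  sc <- scorer(poolManifest(pool)$tagged)
  rankPredictions(fakePreds(conf = sc$conf, unc = sc$unc, ids = ids))
}
randomScorer <- function(tagged) {
  list(conf = runif(length(tagged), 0.5, 1),
       unc = runif(length(tagged), 0, 0.5))
}
# deterministic: tagged pairs above all candidates, candidate order fixed
oracleScorer <- function(tagged) {
  n <- length(tagged)
  conf <- seq(0.5, 0.9, length.out = n)
  conf[tagged] <- 0.99
  list(conf = conf, unc = rep(0.1, n))
}

test_that("blending masks labels and keeps the manifest out of band", {
  pool <- makePool()
  expect_identical(length(poolPairs(pool)), 420L)
  expect_true(all(is.na(pairLabels(poolPairs(pool)))))
  expect_false(any(taggedFlags(poolPairs(pool))))
  expect_identical(sum(poolManifest(pool)$tagged), 20L)
  # deterministic shuffle
  pool2 <- makePool()
  expect_identical(pairIds(poolPairs(pool)), pairIds(poolPairs(pool2)))

  tagged <- generateExperimentalLike(syntheticSpec(
    nPairs = 5, nUniqueSequences = 5, positiveFraction = 1, seed = 9))
  cand <- generateCandidatePool(
    syntheticSpec(nPairs = 5, nUniqueSequences = 5, seed = 2),
    nCandidates = 10)$pool
  # a non-degradable "tagged" pair violates the contract
  bad <- PairSet(pairIds(tagged), unname(sequences(tagged)),
                 unname(plastics(tagged)), c(1L, 1L, 0L, 1L, 1L))
  expect_error(blendPool(cand, bad, seed = 1), "contract error")
  # empty tagged set is meaningless
  expect_error(blendPool(cand, tagged[integer(0)], seed = 1),
               "at least one tagged")
  # id collisions are refused
  clash <- PairSet(pairIds(cand)[1], unname(sequences(tagged))[1],
                   "PET", 1L)
  expect_error(blendPool(cand, clash, seed = 1), "collision")
})

test_that("initial concentration is tagged over total", {
  pool <- makePool(nCand = 5000, nTagged = 60)
  expect_equal(initialConcentration(pool), 60 / 5060, tolerance = 1e-12)
  pool2 <- makePool(nCand = 20, nTagged = 20)
  expect_equal(initialConcentration(pool2), 0.5)
})

test_that("concentration factors follow the exact and printed conventions", {
  # printed convention reproduces hand-rounded report tables
  expect_equal(concentrationFactor(5 / 102, 60 / 40913, "printed"), 33)
  expect_equal(concentrationFactor(4 / 187, 60 / 40913, "printed"), 14)
  expect_equal(concentrationFactor(3 / 78, 60 / 40913, "printed"), 26)
  expect_equal(concentrationFactor(3 / 80, 60 / 40913, "printed"), 25)
  expect_equal(concentrationFactor(0.3, 0.3), 1)
  # exact factor times initial concentration is the final concentration
  withr::with_seed(31, {
    for (i in 1:50) {
      cf <- runif(1); ci <- runif(1, 0.001, 1)
      expect_equal(concentrationFactor(cf, ci) * ci, cf, tolerance = 1e-12)
    }
  })
})

test_that("a random ranker leaves the tagged concentration unchanged", {
  pool <- makePool(nCand = 400, nTagged = 20)
  concInit <- initialConcentration(pool)
  p <- 0.1
  withr::with_seed(32, {
    finals <- replicate(200, {
      run <- scoredRun(pool, randomScorer)
      top <- topFraction(run, p)
      sum(top %in% poolManifest(pool)$pair_id[poolManifest(pool)$tagged]) /
        length(top)
    })
  })
  se <- stats::sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - concInit), 3 * se + 1e-12)
})

test_that("a perfect ranker concentrates tagged pairs to the analytic bound", {
  pool <- makePool(nCand = 400, nTagged = 20)
  concInit <- initialConcentration(pool)
  runs <- replicate(3, scoredRun(pool, oracleScorer), simplify = FALSE)
  for (p in c(0.02, 0.05, 0.25)) {
    rep <- blendingAssessment(pool, runs, pList = p)
    k <- max(1, floor(p * 420))
    expected <- min(1, 20 / k)
    expect_equal(rep$rows$concFinal, expected, tolerance = 1e-12)
    expect_equal(rep$rows$factorExact * rep$concInit, rep$rows$concFinal,
                 tolerance = 1e-12)
  }
})

test_that("blending assessment reports per-fraction enrichment rows", {
  pool <- makePool(nCand = 200, nTagged = 10)
  runs <- replicate(3, scoredRun(pool, oracleScorer), simplify = FALSE)
  rep <- blendingAssessment(pool, runs, pList = c(0.05, 0.2))
  expect_s3_class(rep, "BlendingReport")
  expect_identical(nrow(rep$rows), 2L)
  expect_true(all(rep$rows$concFinal >= 0 & rep$rows$concFinal <= 1))
  expect_true(all(rep$rows$factorExact >= 0))
  expect_identical(
    rep$rows$factorPrinted,
    vapply(seq_len(2), function(i) {
      concentrationFactor(rep$rows$concFinal[i], rep$concInit, "printed")
    }, numeric(1)))
})

test_that("model top-list intersection reports the tagged breakdown", {
  pool <- makePool(nCand = 100, nTagged = 8)
  ids <- poolManifest(pool)$pair_id
  taggedIds <- ids[poolManifest(pool)$tagged]
  # two "models" whose common top lists share a known subset
  mkRun <- function(topIds) {
    conf <- ifelse(ids %in% topIds, 0.99, 0.6)
    rankPredictions(fakePreds(conf, rep(0.1, length(ids)), ids = ids))
  }
  listA <- c(taggedIds[1:3], ids[!ids %in% taggedIds][1:9])   # 12 ids
  listB <- c(taggedIds[1:3], ids[!ids %in% taggedIds][6:14])  # 12 ids
  mA <- fakeMultiRun(list(mkRun(listA), mkRun(listA), mkRun(listA)))
  mB <- fakeMultiRun(list(mkRun(listB), mkRun(listB), mkRun(listB)))
  comb <- intersectModelTopLists(list(mA, mB), p = 12 / 108, pool = pool)
  expect_setequal(comb$common, intersect(listA, listB))
  expect_identical(comb$taggedInList, 3L)
  expect_identical(comb$nCandidates, comb$size - 3L)
  # identical models intersect to either list
  comb2 <- intersectModelTopLists(list(mA, mA), p = 12 / 108, pool = pool)
  expect_setequal(comb2$common, listA)
})

test_that("pool predictions cannot depend on the manifest", {
  pool <- makePool(nCand = 30, nTagged = 5)
  train <- smallLabeledPairs(40, seed = 8)
  model <- trainEnsemble(train, "prototype", n = 5, baseSeed = 1)
  pr <- ensemblePredict(model, poolPairs(pool))
  # the PairSet handed to the model carries neither labels nor flags
  expect_true(all(is.na(pairLabels(poolPairs(pool)))))
  expect_false(any(taggedFlags(poolPairs(pool))))
  # permuting the manifest changes nothing the model saw
  shuffled <- pool
  shuffled@manifest <- pool@manifest[rev(seq_len(nrow(pool@manifest))), ]
  pr2 <- ensemblePredict(model, poolPairs(shuffled))
  expect_identical(pr, pr2)
})
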