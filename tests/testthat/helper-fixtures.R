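# Shared fixtures built in code; no data files.

# A tiny hand-written PairSet covering labels, NA labels and tagged flags.
tinyPairs <- function() {
  PairSet(
    pairId = c("p1", "p2", "p3", "p4"),
    sequence = c("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
                 "GHSQGALATAAYMKTAYIAKQR",
                 "ACDEFGHIKLMNPQRSTVWY",
                 "MKKLVVLGAGGVGKSALTIQ"),
    plastic = c("PET", "PLA", "PCL", "PET"),
    label = c(1L, 0L, NA, 1L),
    tagged = c(TRUE, FALSE, FALSE, FALSE))
}

# The 20 canonical amino-acid letters.
AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

# Random valid amino-acid sequence.
randomSeq <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# A small labeled PairSet from the generator (fast default for pipeline
# tests: modest size, strong signal).
smallLabeledPairs <- function(n = 60, seed = 1) {
  generateExperimentalLike(syntheticSpec(
    nPairs = n, nUniqueSequences = n, seed = seed))
}

# A prediction frame with chosen confidence/uncertainty, for ranking and
# filtering tests that need no trained model.
fakePreds <- function(conf, unc, ids = NULL, class = NULL) {
  n <- length(conf)
  data.frame(
    pairId = if (is.null(ids)) sprintf("p%03d", seq_len(n)) else ids,
    plastic = rep("PET", n),
    meanProb = conf,
    predictedClass = if (is.null(class)) rep(1L, n) else class,
    confidence = conf,
    uncertainty = unc,
    stringsAsFactors = FALSE)
}

# Minimal MultiRunResult from a list of prediction frames.
fakeMultiRun <- function(runs, vote = NULL) {
  runs <- lapply(runs, rankPredictions)
  ids <- runs[[1]]$pairId
  classMat <- vapply(runs, function(r) r$predictedClass[match(ids, r$pairId)],
                     integer(length(ids)))
  if (is.null(dim(classMat))) classMat <- matrix(classMat, nrow = 1)
  structure(list(
    runs = runs,
    summary = data.frame(
      pairId = ids, plastic = runs[[1]]$plastic,
      voteClass = if (is.null(vote)) as.integer(rowMeans(classMat) > 0.5)
                  else vote,
      meanConfidence = rowMeans(vapply(
        runs, function(r) r$confidence[match(ids, r$pairId)],
        numeric(length(ids)))),
      meanUncertainty = rowMeans(vapply(
        runs, function(r) r$uncertainty[match(ids, r$pairId)],
        numeric(length(ids)))),
      stringsAsFactors = FALSE),
    seeds = seq_along(runs), headKind = "fake"),
    class = "MultiRunResult")
}

# Independent average-tie ascending rank (no base::rank), for rank oracles.
oracleRank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}
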