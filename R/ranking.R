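#' Rank predictions by joint confidence and uncertainty
#'
#' Rank-of-sum-of-ranks aggregation: with `R` the ascending average-tie rank
#' function, the ranking value is `R(R(confidence) + R(1/uncertainty))`, so
#' pairs with higher confidence and lower uncertainty obtain larger ranking
#' values (better). `R(1/uncertainty)` is computed as the rank of
#' `-uncertainty`, which is the identical ordering, stays finite for
#' zero-uncertainty pairs and leaves them tied at the best inverse-
#' uncertainty rank. The 1-based `position` column (1 = best) orders by
#' descending ranking value with lexicographic pair-id tie-break so runs are
#' reproducible.
#'
#' @param preds prediction `data.frame` from [ensemblePredict()] (any data
#'   frame with `pairId`, `confidence`, `uncertainty` columns works).
#' @return The input with `rankingValue` and `position` columns added.
#' @export
rankPredictions <- function(preds) {
  if (nrow(preds) == 0L) stop("cannot rank an empty prediction set")
  if (any(!is.finite(preds$confidence)) || any(!is.finite(preds$uncertainty))) {
    stop("confidence and uncertainty must be finite")
  }
  rc <- rank(preds$confidence, ties.method = "average")
  ru <- rank(-preds$uncertainty, ties.method = "average")
  rv <- rank(rc + ru, ties.method = "average")
  preds$rankingValue <- rv
  ord <- order(-rv, preds$pairId)
  preds$position <- integer(nrow(preds))
  preds$position[ord] <- seq_len(nrow(preds))
  preds
}

#' Train/predict/rank across multiple seeds
#'
#' Runs one full ensemble cycle per seed (train on `train`, predict and rank
#' `test`), then combines the runs: per-pair majority-vote class and mean
#' confidence/uncertainty across runs. An odd number of seeds is required
#' when voting so the vote cannot tie.
#'
#' @param train labeled [PairSet].
#' @param test [PairSet] to predict (labels optional).
#' @param seeds integer vector of base seeds (default `1:5`).
#' @param headKind,n,embedder,featureSet,headConfig passed to
#'   [trainEnsemble()].
#' @param vote take the majority vote (default `TRUE`; requires an odd
#'   number of seeds).
#' @return Object of class `"MultiRunResult"`: list with `runs` (one ranked
#'   prediction frame per seed), `summary` (per-pair vote class, mean
#'   confidence, mean uncertainty), `seeds` and `headKind`.
#' @export
runMultiSeed <- function(train, test, seeds = 1:5,
                         headKind = c("mlp", "prototype"), n = 25L,
                         embedder = surrogateEmbedder(), featureSet = "all",
                         headConfig = list(), vote = TRUE) {
  headKind <- match.arg(headKind)
  if (length(seeds) < 1L) stop("at least one seed required")
  if (vote && length(seeds) %% 2L == 0L) {
    stop("config error: majority voting needs an odd number of seeds")
  }
  runs <- lapply(seeds, function(s) {
    model <- trainEnsemble(train, headKind = headKind, n = n, baseSeed = s,
                           embedder = embedder, featureSet = featureSet,
                           headConfig = headConfig)
    rankPredictions(ensemblePredict(model, test))
  })
  names(runs) <- paste0("seed", seeds)
  ids <- runs[[1L]]$pairId
  classMat <- vapply(runs, function(r) r$predictedClass[match(ids, r$pairId)],
                     integer(length(ids)))
  confMat <- vapply(runs, function(r) r$confidence[match(ids, r$pairId)],
                    numeric(length(ids)))
  uncMat <- vapply(runs, function(r) r$uncertainty[match(ids, r$pairId)],
                   numeric(length(ids)))
  if (is.null(dim(classMat))) {
    classMat <- matrix(classMat, nrow = 1L)
    confMat <- matrix(confMat, nrow = 1L)
    uncMat <- matrix(uncMat, nrow = 1L)
  }
  summary <- data.frame(
    pairId = ids,
    plastic = runs[[1L]]$plastic,
    voteClass = if (vote) {
      as.integer(rowMeans(classMat) > 0.5)
    } else {
      NA_integer_
    },
    meanConfidence = rowMeans(confMat),
    meanUncertainty = rowMeans(uncMat),
    stringsAsFactors = FALSE)
  structure(list(runs = runs, summary = summary, seeds = seeds,
                 headKind = headKind),
            class = "MultiRunResult")
}

#' @export
print.MultiRunResult <- function(x, ...) {
  cat(sprintf("MultiRunResult: %d runs (%s heads) over %d pairs; seeds: %s\n",
              length(x$runs), x$headKind, nrow(x$summary),
              paste(x$seeds, collapse = ", ")))
  invisible(x)
}

#' Top fraction of a ranked prediction set
#'
#' Returns the `k = max(1, floor(p * n))` best-ranked pair ids. Boundary
#' ties were already resolved deterministically (lexicographic pair id) when
#' positions were assigned in [rankPredictions()].
#'
#' @param ranked output of [rankPredictions()].
#' @param p top fraction in (0, 1].
#' @return Character vector of `k` pair ids, best first.
#' @examples
#' # floor(0.30 * 71) = 21, floor(0.20 * 71) = 14
#' @export
topFraction <- function(ranked, p) {
  stopifnot(p > 0, p <= 1)
  k <- max(1L, floor(p * nrow(ranked)))
  ranked$pairId[order(ranked$position)][seq_len(k)]
}

#' Common top list across runs
#'
#' Intersection of the per-run top-`p` lists of a [runMultiSeed()] result:
#' the stability measure of the framework. When every common pair carries a
#' ground-truth label, the majority-vote accuracy over the common list is
#' reported.
#'
#' @param multi a `"MultiRunResult"` with at least 2 runs.
#' @param p top fraction.
#' @param labels optional binary labels named by pair id.
#' @return Object of class `"TopListReport"`: list with `p`, `k`,
#'   `perRunTop`, `common`, `size`, `accuracy` (or `NA`), `nUnlabeled`.
#' @export
commonTopList <- function(multi, p, labels = NULL) {
  stopifnot(inherits(multi, "MultiRunResult"))
  if (length(multi$runs) < 2L) stop("need at least 2 runs")
  tops <- lapply(multi$runs, topFraction, p = p)
  common <- Reduce(intersect, tops)
  if (length(common) == 0L) {
    warning("no pairs common to all per-run top lists at p = ", p)
  }
  accuracy <- NA_real_
  nUnlabeled <- NA_integer_
  if (!is.null(labels) && length(common)) {
    lb <- labels[common]
    nUnlabeled <- sum(is.na(lb))
    if (nUnlabeled == 0L) {
      vote <- multi$summary$voteClass[match(common, multi$summary$pairId)]
      accuracy <- mean(vote == lb)
    }
  }
  structure(list(p = p,
                 k = max(1L, as.integer(floor(p * nrow(multi$summary)))),
                 perRunTop = tops, common = common, size = length(common),
                 accuracy = accuracy, nUnlabeled = nUnlabeled),
            class = "TopListReport")
}

#' @export
print.TopListReport <- function(x, ...) {
  cat(sprintf("TopListReport: top %.1f%% (k = %d), %d common across %d runs",
              100 * x$p, x$k, x$size, length(x$perRunTop)))
  if (!is.na(x$accuracy)) cat(sprintf(", accuracy %.3f", x$accuracy))
  cat("\n")
  invisible(x)
}

#' Ranking matrix across runs
#'
#' Ranking values of every pair in every run, for heatmap-style export:
#' one row per run, one column per pair id (fixed order).
#'
#' @param multi a `"MultiRunResult"`.
#' @return Numeric matrix (runs x pairs).
#' @export
rankingHeatmapTable <- function(multi) {
  stopifnot(inherits(multi, "MultiRunResult"))
  ids <- sort(multi$summary$pairId)
  m <- matrix(NA_real_, length(multi$runs), length(ids),
              dimnames = list(names(multi$runs), ids))
  for (i in seq_along(multi$runs)) {
    r <- multi$runs[[i]]
    m[i, ] <- r$rankingValue[match(ids, r$pairId)]
  }
  m
}
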