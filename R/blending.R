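#' BlendedPool: candidates blended with masked known degraders
#'
#' The blending assessment hides ground-truth degradable pairs ("tagged")
#' inside an unlabeled candidate pool. The merged `pool` PairSet carries no
#' labels and no tagged flags — the model never sees them — while the
#' out-of-band `manifest` records which pair ids are tagged, for evaluation
#' only.
#'
#' @slot pool [PairSet] of all pairs, unlabeled, deterministically shuffled.
#' @slot manifest `data.frame` with columns `pair_id`, `tagged`, `origin`.
#' @slot seed integer shuffle seed.
#' @aliases BlendedPool-class
#' @export
setClass("BlendedPool",
  representation(pool = "PairSet", manifest = "data.frame", seed = "integer"))

setValidity("BlendedPool", function(object) {
  if (length(object@pool) != nrow(object@manifest)) {
    return("manifest must cover every pool pair")
  }
  if (!any(object@manifest$tagged)) {
    return("a blended pool needs at least one tagged pair")
  }
  if (any(!is.na(object@pool@label)) || any(object@pool@tagged)) {
    return("pool pairs must carry no labels or tagged flags")
  }
  TRUE
})

#' @describeIn BlendedPool summary display.
#' @param object a `BlendedPool`.
#' @export
setMethod("show", "BlendedPool", function(object) {
  nt <- sum(object@manifest$tagged)
  cat(sprintf(
    "BlendedPool: %d pairs (%d candidates + %d tagged), initial concentration %.4f%%\n",
    length(object@pool), length(object@pool) - nt, nt,
    100 * initialConcentration(object)))
})

#' Blend tagged degradable pairs into a candidate pool
#'
#' @param candidates unlabeled [PairSet] (the homolog-style candidate pool).
#' @param tagged [PairSet] of ground-truth degradable pairs (every label
#'   must be 1); their labels are masked in the merged pool.
#' @param seed shuffle seed (same seed, same order).
#' @return A [BlendedPool-class].
#' @examples
#' spec <- syntheticSpec(nPairs = 20, nUniqueSequences = 20, seed = 1)
#' cand <- generateCandidatePool(spec, nCandidates = 50,
#'                               truePositiveFraction = 0.2)$pool
#' tg <- generateExperimentalLike(syntheticSpec(nPairs = 10,
#'   nUniqueSequences = 10, positiveFraction = 1, seed = 2))
#' blendPool(cand, tg, seed = 1)
#' @export
blendPool <- function(candidates, tagged, seed = 1L) {
  stopifnot(is(candidates, "PairSet"), is(tagged, "PairSet"))
  if (length(tagged) == 0L) {
    stop("contract error: blending needs at least one tagged pair")
  }
  if (anyNA(tagged@label) || any(tagged@label != 1L)) {
    stop("contract error: every tagged pair must be labeled degradable")
  }
  clash <- intersect(candidates@pairId, tagged@pairId)
  if (length(clash)) {
    stop("pair id collision between candidates and tagged set: ", clash[1L])
  }
  ids <- c(candidates@pairId, tagged@pairId)
  seqs <- c(candidates@sequence, tagged@sequence)
  plas <- c(candidates@plastic, tagged@plastic)
  isTagged <- c(rep(FALSE, length(candidates)), rep(TRUE, length(tagged)))
  ord <- withSeed(seed, sample(length(ids)))
  pool <- PairSet(pairId = ids[ord], sequence = seqs[ord],
                  plastic = plas[ord], label = NA, tagged = FALSE,
                  metadata = list(blendSeed = seed))
  manifest <- data.frame(
    pair_id = ids[ord], tagged = isTagged[ord],
    origin = ifelse(isTagged[ord], "tagged", "candidate"),
    stringsAsFactors = FALSE)
  new("BlendedPool", pool = pool, manifest = manifest,
      seed = as.integer(seed))
}

#' @export
setGeneric("poolPairs", function(x) standardGeneric("poolPairs"))
#' @describeIn BlendedPool the merged, unlabeled [PairSet] (model input).
#' @param x a `BlendedPool`.
#' @export
setMethod("poolPairs", "BlendedPool", function(x) x@pool)

#' @export
setGeneric("poolManifest", function(x) standardGeneric("poolManifest"))
#' @describeIn BlendedPool the out-of-band tagged manifest.
#' @export
setMethod("poolManifest", "BlendedPool", function(x) x@manifest)

#' Initial tagged-pair concentration of a blended pool
#'
#' Number of tagged pairs divided by the total pool size.
#'
#' @param pool a [BlendedPool-class].
#' @return Proportion in (0, 1].
#' @examples
#' # 60 tagged in 40853 candidates: 60 / 40913 = 0.001466... (0.15%)
#' @export
initialConcentration <- function(pool) {
  stopifnot(is(pool, "BlendedPool"))
  sum(pool@manifest$tagged) / nrow(pool@manifest)
}

#' Concentration factor of an enrichment
#'
#' Ratio of final to initial tagged-pair concentration. `"exact"` divides
#' the unrounded proportions. `"printed"` reproduces hand-reported tables:
#' both concentrations are first expressed as percentages rounded half-up to
#' 2 decimals, divided, and the ratio rounded half-up to an integer.
#'
#' @param concFinal final concentration (proportion).
#' @param concInit initial concentration (proportion).
#' @param convention `"exact"` or `"printed"`.
#' @return Numeric factor.
#' @examples
#' concentrationFactor(0.049, 0.0014666, "printed")  # 33
#' @export
concentrationFactor <- function(concFinal, concInit,
                                convention = c("exact", "printed")) {
  convention <- match.arg(convention)
  if (convention == "exact") {
    concFinal / concInit
  } else {
    roundHalfUp(roundHalfUp(100 * concFinal, 2) /
                  roundHalfUp(100 * concInit, 2))
  }
}

# Candidate top list of one run: the k = floor(p * pool size) best-ranked
# pairs among those predicted degradable (a shortlist of confident
# non-degradable predictions would be useless for mining; published top
# lists consist of degradable predictions only).
.topDegradable <- function(run, p) {
  k <- max(1L, floor(p * nrow(run)))
  deg <- run[run$predictedClass == 1L, , drop = FALSE]
  if (nrow(deg) == 0L) return(character())
  deg$pairId[order(deg$position)][seq_len(min(k, nrow(deg)))]
}

#' Blending assessment: tagged-pair enrichment in top lists
#'
#' For each top fraction `p`, takes the common-across-runs candidate top
#' list of the pool predictions (the `floor(p * pool size)` best-ranked
#' pairs predicted degradable, intersected across runs), counts the tagged
#' pairs it contains, and reports the final concentration together with the
#' exact and printed-convention concentration factors, plus whether every
#' tagged pair in the list was predicted degradable.
#'
#' @param pool the [BlendedPool-class] that was predicted.
#' @param multi a `"MultiRunResult"` from [runMultiSeed()] over
#'   `poolPairs(pool)`, or a list of ranked prediction frames.
#' @param pList top fractions (default `c(0.005, 0.01)`).
#' @return Object of class `"BlendingReport"`: list with `concInit` and a
#'   `rows` data.frame (`p`, `listSize`, `taggedInList`, `concFinal`,
#'   `factorExact`, `factorPrinted`, `allTaggedPredictedDegradable`).
#' @export
blendingAssessment <- function(pool, multi, pList = c(0.005, 0.01)) {
  stopifnot(is(pool, "BlendedPool"), length(pList) >= 1L)
  if (inherits(multi, "MultiRunResult")) {
    runs <- multi$runs
    votes <- multi$summary
  } else {
    runs <- multi
    votes <- NULL
  }
  poolIds <- pool@manifest$pair_id
  if (!all(vapply(runs, function(r) all(poolIds %in% r$pairId), logical(1)))) {
    stop("every run must cover every pool pair")
  }
  taggedIds <- pool@manifest$pair_id[pool@manifest$tagged]
  concInit <- initialConcentration(pool)
  rows <- lapply(pList, function(p) {
    tops <- lapply(runs, .topDegradable, p = p)
    common <- Reduce(intersect, tops)
    if (length(common) == 0L) {
      warning("empty common top list at p = ", p)
      return(data.frame(p = p, listSize = 0L, taggedInList = 0L,
                        concFinal = NA_real_, factorExact = NA_real_,
                        factorPrinted = NA_real_,
                        allTaggedPredictedDegradable = NA))
    }
    taggedIn <- sum(common %in% taggedIds)
    concFinal <- taggedIn / length(common)
    allDeg <- if (taggedIn == 0L) {
      TRUE
    } else if (!is.null(votes)) {
      all(votes$voteClass[match(intersect(common, taggedIds),
                                votes$pairId)] == 1L)
    } else {
      NA
    }
    data.frame(p = p, listSize = length(common), taggedInList = taggedIn,
               concFinal = concFinal,
               factorExact = concentrationFactor(concFinal, concInit),
               factorPrinted = concentrationFactor(concFinal, concInit,
                                                   "printed"),
               allTaggedPredictedDegradable = allDeg)
  })
  structure(list(concInit = concInit, rows = do.call(rbind, rows)),
            class = "BlendingReport")
}

#' @export
print.BlendingReport <- function(x, ...) {
  cat(sprintf("BlendingReport (initial concentration %.4f%%):\n",
              100 * x$concInit))
  print(x$rows, row.names = FALSE)
  invisible(x)
}

#' Intersect the common top lists of several models
#'
#' Pairs ranked in the common top-`p` list by every model (i.e. common
#' across all runs of all models), with the tagged/candidate breakdown when
#' the pool is supplied.
#'
#' @param multiList list of `"MultiRunResult"` objects over the same pool.
#' @param p top fraction.
#' @param pool optional [BlendedPool-class] for the tagged breakdown.
#' @return List with `common`, `size`, `taggedInList`, `nCandidates`.
#' @export
intersectModelTopLists <- function(multiList, p, pool = NULL) {
  stopifnot(length(multiList) >= 2L)
  ids <- lapply(multiList, function(m) sort(m$summary$pairId))
  if (!all(vapply(ids[-1L], identical, logical(1), ids[[1L]]))) {
    stop("models were not run on the same pool")
  }
  perModel <- lapply(multiList, function(m) {
    Reduce(intersect, lapply(m$runs, .topDegradable, p = p))
  })
  common <- Reduce(intersect, perModel)
  taggedIn <- NA_integer_
  if (!is.null(pool)) {
    taggedIds <- pool@manifest$pair_id[pool@manifest$tagged]
    taggedIn <- sum(common %in% taggedIds)
  }
  list(common = common, size = length(common), taggedInList = taggedIn,
       nCandidates = if (is.na(taggedIn)) NA_integer_
                     else length(common) - taggedIn)
}
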