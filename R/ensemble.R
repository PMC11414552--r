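#' EnsembleModel: a deep ensemble of classification heads
#'
#' All heads share one feature representation of the inputs (embedder +
#' feature set + training-data scaler); they differ only by their training
#' seed, derived deterministically from `baseSeed` (head i uses
#' `baseSeed + i`). MLP heads differ through their random initial weights;
#' prototype heads differ through a per-head bootstrap resample of the
#' training rows. The spread of the per-head probabilities is the source of
#' the confidence and uncertainty estimates.
#'
#' @slot heads list of [ClassifierHead-class] objects (N >= 2, default 25).
#' @slot headKind `"mlp"` or `"prototype"`.
#' @slot baseSeed integer base seed.
#' @slot embedder embedder object shared by all heads.
#' @slot featureSet feature-subset name (see [featureMatrix()]).
#' @slot scaler biophysical-block z-score scaler fit on the training data.
#' @aliases EnsembleModel-class
#' @export
setClass("EnsembleModel",
  representation(heads = "list", headKind = "character",
                 baseSeed = "integer", embedder = "list",
                 featureSet = "character", scaler = "list"))

setValidity("EnsembleModel", function(object) {
  if (length(object@heads) < 2L) return("an ensemble needs at least 2 heads")
  TRUE
})

#' @describeIn EnsembleModel summary display.
#' @param object an `EnsembleModel`.
#' @export
setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf(
    "EnsembleModel: %d %s heads, base seed %d, embedder %s, features '%s'\n",
    length(object@heads), object@headKind, object@baseSeed,
    object@embedder$spec$name, object@featureSet))
})

#' @export
setGeneric("nHeads", function(x) standardGeneric("nHeads"))
#' @describeIn EnsembleModel number of classification heads.
#' @param x an `EnsembleModel`.
#' @export
setMethod("nHeads", "EnsembleModel", function(x) length(x@heads))

#' Train a deep ensemble on a labeled PairSet
#'
#' Featurizes the training pairs once, fits the z-score scaler (embedding
#' and biophysical blocks) on them, then trains `n` heads whose seeds are
#' `baseSeed + 1 .. baseSeed + n`. For prototype heads the per-head seed
#' drives a bootstrap resample of the training rows (enabled here by
#' default), which is what makes the heads diverse; MLP heads differ
#' through their random initial weights.
#'
#' @param train labeled [PairSet] with both classes present.
#' @param headKind `"mlp"` or `"prototype"`.
#' @param n number of heads (default 25; must be >= 2).
#' @param baseSeed integer base seed.
#' @param embedder shared embedder object (default [surrogateEmbedder()]).
#' @param featureSet feature subset, see [featureMatrix()].
#' @param headConfig hyperparameter list passed to the head trainer; for
#'   prototype ensembles `bootstrap` defaults to `TRUE` here so that head
#'   seeds generate diversity.
#' @return A trained [EnsembleModel-class].
#' @examples
#' ps <- generateExperimentalLike(syntheticSpec(nPairs = 60, seed = 1))
#' m <- trainEnsemble(ps, "prototype", n = 5, baseSeed = 1)
#' m
#' @export
trainEnsemble <- function(train, headKind = c("mlp", "prototype"), n = 25L,
                          baseSeed = 1L, embedder = surrogateEmbedder(),
                          featureSet = "all", headConfig = list()) {
  headKind <- match.arg(headKind)
  if (n < 2L) stop("config error: an ensemble needs at least 2 heads")
  stopifnot(is(train, "PairSet"))
  labels <- train@label
  if (anyNA(labels)) stop("training set must be fully labeled")
  m <- featureMatrix(train, embedder = embedder, featureSet = featureSet)
  scaler <- .fitScaler(m)
  m <- .applyScaler(m, scaler)
  if (headKind == "prototype" && is.null(headConfig$bootstrap)) {
    headConfig$bootstrap <- TRUE
  }
  trainer <- if (headKind == "mlp") trainMLPHead else trainPrototypeHead
  heads <- lapply(seq_len(n), function(i) {
    tryCatch(
      trainer(m, labels, seed = as.integer(baseSeed) + i,
              config = headConfig),
      error = function(e) {
        stop("training of head ", i, " failed: ", conditionMessage(e))
      })
  })
  new("EnsembleModel", heads = heads, headKind = headKind,
      baseSeed = as.integer(baseSeed), embedder = embedder,
      featureSet = featureSet, scaler = scaler)
}

#' Ensemble confidence of a per-head probability vector
#'
#' Mean over heads of the predicted-class probability
#' `max(f_i(x), 1 - f_i(x))`. Always in \[0.5, 1\].
#'
#' @param probs numeric vector of per-head probabilities of the degradable
#'   class, each in \[0, 1\].
#' @return Scalar confidence.
#' @export
ensembleConfidence <- function(probs) {
  mean(pmax(probs, 1 - probs))
}

#' Ensemble uncertainty of a per-head probability vector
#'
#' Population (divide-by-N) standard deviation of the per-head
#' predicted-class probabilities `max(f_i(x), 1 - f_i(x))`. Zero exactly
#' when all heads agree on that probability; never exceeds 0.5.
#'
#' @inheritParams ensembleConfidence
#' @return Scalar uncertainty.
#' @export
ensembleUncertainty <- function(probs) {
  m <- pmax(probs, 1 - probs)
  sqrt(mean((m - mean(m))^2))
}

#' Predict a PairSet with a trained ensemble
#'
#' Each pair receives the N per-head probabilities, the ensemble class
#' (degradable iff the mean probability exceeds 0.5; a tie at exactly 0.5 is
#' called non-degradable), and the confidence and uncertainty statistics of
#' [ensembleConfidence()] and [ensembleUncertainty()].
#'
#' @param model a trained [EnsembleModel-class].
#' @param pairs a [PairSet] (labels not required).
#' @return `data.frame` with columns `pairId`, `plastic`, `meanProb`,
#'   `predictedClass` (1/0), `confidence`, `uncertainty`; the per-head
#'   probability matrix (pairs x heads) is attached as attribute
#'   `"headProbs"` and available via [headProbabilities()].
#' @export
ensemblePredict <- function(model, pairs) {
  stopifnot(is(model, "EnsembleModel"), is(pairs, "PairSet"))
  m <- featureMatrix(pairs, embedder = model@embedder,
                     featureSet = model@featureSet)
  m <- .applyScaler(m, model@scaler)
  hp <- vapply(model@heads, predictProba, numeric(nrow(m)), features = m)
  if (is.null(dim(hp))) hp <- matrix(hp, nrow = 1L)
  rownames(hp) <- pairs@pairId
  meanProb <- rowMeans(hp)
  out <- data.frame(
    pairId = pairs@pairId,
    plastic = pairs@plastic,
    meanProb = meanProb,
    predictedClass = as.integer(meanProb > 0.5),
    confidence = apply(hp, 1L, ensembleConfidence),
    uncertainty = apply(hp, 1L, ensembleUncertainty),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "headProbs") <- hp
  out
}

#' Per-head probability matrix of an ensemble prediction
#'
#' @param preds result of [ensemblePredict()].
#' @return Numeric matrix (pairs x heads).
#' @export
headProbabilities <- function(preds) {
  attr(preds, "headProbs")
}

#' Filter predictions by confidence and uncertainty thresholds
#'
#' Retains exactly the pairs with confidence strictly above `confMin` and
#' uncertainty strictly below `uncMax`; an `NA` threshold imposes no
#' constraint. Tightening either threshold always yields a subset of the
#' looser selection.
#'
#' @param preds prediction `data.frame` from [ensemblePredict()].
#' @param confMin confidence threshold (retain `confidence > confMin`), or
#'   `NA` for none.
#' @param uncMax uncertainty threshold (retain `uncertainty < uncMax`), or
#'   `NA` for none.
#' @return The retained rows (possibly none).
#' @export
filterByThresholds <- function(preds, confMin = NA, uncMax = NA) {
  keep <- rep(TRUE, nrow(preds))
  if (!is.na(confMin)) keep <- keep & preds$confidence > confMin
  if (!is.na(uncMax)) keep <- keep & preds$uncertainty < uncMax
  out <- preds[keep, , drop = FALSE]
  hp <- attr(preds, "headProbs")
  if (!is.null(hp)) attr(out, "headProbs") <- hp[keep, , drop = FALSE]
  out
}

#' Binary classification metrics
#'
#' Confusion counts and accuracy, precision, recall and F1 score, with the
#' degradable class as positive. A zero denominator (e.g. no predicted
#' positives) reports the affected metric as 0 and raises the corresponding
#' `degenerate` flag instead of failing, so sparse threshold-grid cells stay
#' reportable.
#'
#' @param predicted binary vector of predicted classes (1 = degradable).
#' @param truth binary vector of ground-truth labels, same length.
#' @return Object of class `"MetricsReport"`: a list with `TP`, `FP`, `TN`,
#'   `FN`, `n`, `accuracy`, `precision`, `recall`, `f1` and a named logical
#'   `degenerate` vector.
#' @examples
#' computeMetrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
computeMetrics <- function(predicted, truth) {
  predicted <- as.integer(predicted)
  truth <- as.integer(truth)
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length")
  }
  if (length(predicted) == 0L || anyNA(truth)) {
    stop("metrics need at least one labeled pair")
  }
  TP <- sum(predicted == 1L & truth == 1L)
  FP <- sum(predicted == 1L & truth == 0L)
  TN <- sum(predicted == 0L & truth == 0L)
  FN <- sum(predicted == 0L & truth == 1L)
  precision <- if (TP + FP > 0L) TP / (TP + FP) else 0
  recall <- if (TP + FN > 0L) TP / (TP + FN) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  structure(list(
    TP = TP, FP = FP, TN = TN, FN = FN, n = length(predicted),
    accuracy = (TP + TN) / length(predicted),
    precision = precision, recall = recall, f1 = f1,
    degenerate = c(precision = TP + FP == 0L, recall = TP + FN == 0L,
                   f1 = precision + recall == 0)),
    class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("MetricsReport: n=%d TP=%d FP=%d TN=%d FN=%d\n",
              x$n, x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("  accuracy=%.3f precision=%.3f recall=%.3f F1=%.3f%s\n",
              x$accuracy, x$precision, x$recall, x$f1,
              if (any(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Accuracy across a confidence/uncertainty threshold grid
#'
#' Evaluates [computeMetrics()] on the pairs retained by every combination
#' of confidence and uncertainty thresholds, including the unfiltered cell
#' (`NA`, `NA`). Cells that retain no pairs report `n = 0` and `NA` metrics.
#' The default grids follow the framework's evaluation layout.
#'
#' @param preds prediction `data.frame` from [ensemblePredict()].
#' @param truth binary labels named by pair id, or aligned with `preds`.
#' @param confGrid confidence thresholds; `NA` means unfiltered.
#' @param uncGrid uncertainty thresholds; `NA` means unfiltered.
#' @return `data.frame` with one row per grid cell: `confMin`, `uncMax`,
#'   `n`, confusion counts and the four metrics.
#' @export
thresholdGridReport <- function(preds, truth,
                                confGrid = c(NA, 0.80, 0.85, 0.90, 0.95, 0.99),
                                uncGrid = c(NA, 0.10, 0.05, 0.02, 0.01)) {
  if (!length(confGrid) || !length(uncGrid)) stop("empty threshold grid")
  if (!is.null(names(truth))) truth <- truth[preds$pairId]
  truth <- as.integer(truth)
  cells <- unique(rbind(data.frame(confMin = NA_real_, uncMax = NA_real_),
                        expand.grid(confMin = confGrid, uncMax = uncGrid)))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    keep <- filterByThresholds(preds, cells$confMin[i], cells$uncMax[i])
    if (nrow(keep) == 0L) {
      return(data.frame(confMin = cells$confMin[i], uncMax = cells$uncMax[i],
                        n = 0L, TP = NA, FP = NA, TN = NA, FN = NA,
                        accuracy = NA, precision = NA, recall = NA, f1 = NA))
    }
    mt <- computeMetrics(keep$predictedClass,
                         truth[match(keep$pairId, preds$pairId)])
    data.frame(confMin = cells$confMin[i], uncMax = cells$uncMax[i],
               n = mt$n, TP = mt$TP, FP = mt$FP, TN = mt$TN, FN = mt$FN,
               accuracy = mt$accuracy, precision = mt$precision,
               recall = mt$recall, f1 = mt$f1)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
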