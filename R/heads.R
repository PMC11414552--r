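#' ClassifierHead: one trained binary classification head
#'
#' Wraps the trained parameters of a single ensemble head together with its
#' kind, training seed, input dimension and configuration. Heads are pure
#' after training: [predictProba()] on identical inputs returns identical
#' probabilities.
#'
#' @slot kind `"mlp"` or `"prototype"`.
#' @slot fit opaque fitted object (an [nnet::nnet] fit, or a prototype list
#'   with class means, projection and temperature).
#' @slot seed integer training seed.
#' @slot dim integer input feature dimension.
#' @slot config list of hyperparameters used.
#' @slot trainingLoss numeric final training loss.
#' @aliases ClassifierHead-class
#' @export
setClass("ClassifierHead",
  representation(kind = "character", fit = "ANY", seed = "integer",
                 dim = "integer", config = "list", trainingLoss = "numeric"))

setValidity("ClassifierHead", function(object) {
  if (!object@kind %in% c("mlp", "prototype")) {
    return("kind must be 'mlp' or 'prototype'")
  }
  TRUE
})

#' @describeIn ClassifierHead summary display.
#' @param object a `ClassifierHead`.
#' @export
setMethod("show", "ClassifierHead", function(object) {
  cat(sprintf("ClassifierHead(kind = %s, dim = %d, seed = %d, loss = %.4g)\n",
              object@kind, object@dim, object@seed, object@trainingLoss))
})

.checkTrainingInput <- function(features, labels) {
  if (!is.matrix(features)) stop("features must be a matrix")
  if (any(!is.finite(features))) stop("data error: non-finite feature values")
  if (length(labels) != nrow(features)) {
    stop("labels must match feature rows")
  }
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be binary (0/1) with no missing values")
  }
  if (length(unique(labels)) < 2L) {
    stop("training error: both classes must be present in the training set")
  }
  labels
}

#' Train a multilayer-perceptron head
#'
#' Single-hidden-layer feed-forward network (logistic output, cross-entropy
#' loss, weight decay) fitted with [nnet::nnet]. Initial weights are drawn
#' under `seed`, so heads trained with different seeds generally differ while
#' retraining with the same `(data, seed, config)` is bit-reproducible.
#'
#' @param features numeric matrix (pairs x features), typically 82 columns.
#' @param labels binary vector (1 = degradable); both classes required.
#' @param seed integer training seed.
#' @param config list of hyperparameters: `size` (hidden units, default 8),
#'   `decay` (L2 penalty, default 1e-2), `maxit` (default 200).
#' @return A [ClassifierHead-class] of kind `"mlp"`.
#' @export
trainMLPHead <- function(features, labels, seed = 1L, config = list()) {
  labels <- .checkTrainingInput(features, labels)
  cfg <- modifyList(list(size = 8L, decay = 1e-2, maxit = 200L), config)
  fit <- withSeed(seed, nnet(
    x = features, y = labels, size = cfg$size, decay = cfg$decay,
    maxit = cfg$maxit, entropy = TRUE, trace = FALSE,
    MaxNWts = (ncol(features) + 2L) * cfg$size + 1000L))
  new("ClassifierHead", kind = "mlp", fit = fit, seed = as.integer(seed),
      dim = ncol(features), config = cfg, trainingLoss = fit$value)
}

#' Train a prototype head
#'
#' Prototypical-network classifier: each class is represented by the mean of
#' its (optionally projected) feature vectors, and a query's class
#' probability is the softmax over classes of the negative squared Euclidean
#' distance to the prototypes. With `projDim = NULL` (default) prototypes
#' live in the input feature space; a numeric `projDim` applies a seed-fixed
#' random linear map to that dimension first. With `bootstrap = TRUE` the
#' class means are computed on a seed-resampled bootstrap of the training
#' rows — the mechanism by which prototype ensemble heads differ, making the
#' ensemble spread reflect the sampling error of the prototypes.
#'
#' @inheritParams trainMLPHead
#' @param config list: `projDim` (`NULL` for identity, or target dimension),
#'   `temperature` (softmax temperature; the default `NULL` uses the
#'   prototype-space dimension, i.e. distances are compared per dimension,
#'   which keeps probabilities off the saturation plateau in
#'   high-dimensional feature spaces without changing the class decision),
#'   `bootstrap` (default `FALSE`).
#' @return A [ClassifierHead-class] of kind `"prototype"`.
#' @export
trainPrototypeHead <- function(features, labels, seed = 1L, config = list()) {
  labels <- .checkTrainingInput(features, labels)
  cfg <- modifyList(list(projDim = NULL, temperature = NULL,
                         bootstrap = FALSE), config)
  if (isTRUE(cfg$bootstrap)) {
    idx <- withSeed(seed, c(
      sample(which(labels == 0L), replace = TRUE),
      sample(which(labels == 1L), replace = TRUE)))
    features <- features[idx, , drop = FALSE]
    labels <- labels[idx]
  }
  proj <- if (is.null(cfg$projDim)) {
    NULL
  } else {
    .projectionMatrix(ncol(features), as.integer(cfg$projDim), seed)
  }
  z <- if (is.null(proj)) features else features %*% proj
  protos <- rbind(colMeans(z[labels == 0L, , drop = FALSE]),
                  colMeans(z[labels == 1L, , drop = FALSE]))
  fit <- list(prototypes = protos, projection = proj,
              temperature = if (is.null(cfg$temperature)) ncol(z)
                            else cfg$temperature)
  head <- new("ClassifierHead", kind = "prototype", fit = fit,
              seed = as.integer(seed), dim = ncol(features), config = cfg,
              trainingLoss = NA_real_)
  p <- predictProba(head, features)
  head@trainingLoss <- -mean(ifelse(labels == 1L, log(pmax(p, 1e-12)),
                                    log(pmax(1 - p, 1e-12))))
  head
}

#' Predicted probability of degradability
#'
#' @param head a trained [ClassifierHead-class].
#' @param features numeric matrix with the head's input dimension.
#' @return Numeric vector in \[0, 1\]: probability of the degradable class
#'   for each row.
#' @export
setGeneric("predictProba", function(head, features) {
  standardGeneric("predictProba")
})

#' @describeIn predictProba dispatch on the head kind.
#' @export
setMethod("predictProba", "ClassifierHead", function(head, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  if (ncol(features) != head@dim) {
    stop("dimension error: head expects ", head@dim, " features, got ",
         ncol(features))
  }
  p <- if (head@kind == "mlp") {
    as.numeric(predict(head@fit, features))
  } else {
    f <- head@fit
    z <- if (is.null(f$projection)) features else features %*% f$projection
    d0 <- rowSums(sweep(z, 2L, f$prototypes[1L, ])^2)
    d1 <- rowSums(sweep(z, 2L, f$prototypes[2L, ])^2)
    # softmax over negative squared distances at the given temperature
    1 / (1 + exp((d1 - d0) / f$temperature))
  }
  pmin(pmax(p, 0), 1)
})
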