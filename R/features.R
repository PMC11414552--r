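#' One-hot encode a plastic type
#'
#' @param plastic one code from [plasticVocabulary()].
#' @return Named binary vector of length 11 with a single 1 at the
#'   vocabulary index of `plastic`.
#' @examples
#' oneHotPlastic("PET")
#' @export
oneHotPlastic <- function(plastic) {
  vocab <- plasticVocabulary()
  idx <- match(plastic, vocab)
  if (is.na(idx)) {
    stop("unknown plastic code '", plastic, "'; valid codes: ",
         paste(vocab, collapse = ", "))
  }
  setNames(as.numeric(seq_along(vocab) == idx), paste0("plastic_", vocab))
}

#' Assemble the 82-length feature vector
#'
#' Concatenates the three blocks in their fixed order: sequence embedding
#' (30), biophysical descriptors (41), one-hot plastic type (11).
#'
#' @param embedding numeric vector of length 30.
#' @param bio numeric vector of length 41 (see [biophysicalFeatures()]).
#' @param plastic numeric vector of length 11 (see [oneHotPlastic()]).
#' @return Named numeric vector of length 82.
#' @export
assembleFeatures <- function(embedding, bio, plastic) {
  if (length(embedding) != 30L) {
    stop("dimension error: embedding block must have length 30, got ",
         length(embedding))
  }
  if (length(bio) != 41L) {
    stop("dimension error: biophysical block must have length 41, got ",
         length(bio))
  }
  if (length(plastic) != 11L) {
    stop("dimension error: plastic block must have length 11, got ",
         length(plastic))
  }
  out <- c(as.numeric(embedding), as.numeric(bio), as.numeric(plastic))
  names(out) <- c(paste0("emb_", 1:30), biophysicalFeatureNames(),
                  paste0("plastic_", plasticVocabulary()))
  out
}

# Column indices of each block in the full 82-column matrix.
.featureBlocks <- function() {
  list(embedding = 1:30, biophysical = 31:71, plastic = 72:82)
}

#' Compute the feature matrix of a PairSet
#'
#' One row per enzyme/plastic pair: embedding (30), biophysical (41),
#' one-hot plastic (11). `featureSet` drops one block for ablation-style
#' runs without altering the values of the remaining blocks.
#'
#' @param x a [PairSet].
#' @param embedder an embedder object ([surrogateEmbedder()] or
#'   [plmEmbedder()]).
#' @param featureSet `"all"`, `"no_embedding"`, `"no_biophysical"` or
#'   `"no_plastic"`.
#' @return Numeric matrix (pairs x features) with pair ids as row names.
#' @export
featureMatrix <- function(x, embedder = surrogateEmbedder(),
                          featureSet = c("all", "no_embedding",
                                         "no_biophysical", "no_plastic")) {
  featureSet <- match.arg(featureSet)
  stopifnot(is(x, "PairSet"))
  if (length(x) == 0L) stop("empty PairSet")
  emb <- embedder$embed(x@sequence)
  if (ncol(emb) != 30L) {
    stop("dimension error: embedder must emit 30 dimensions")
  }
  bio <- t(vapply(x@sequence, biophysicalFeatures, numeric(41L)))
  oh <- t(vapply(x@plastic, oneHotPlastic, numeric(11L)))
  m <- cbind(emb, bio, oh)
  colnames(m) <- c(paste0("emb_", 1:30), biophysicalFeatureNames(),
                   paste0("plastic_", plasticVocabulary()))
  rownames(m) <- x@pairId
  drop <- switch(featureSet,
                 all = integer(),
                 no_embedding = .featureBlocks()$embedding,
                 no_biophysical = .featureBlocks()$biophysical,
                 no_plastic = .featureBlocks()$plastic)
  if (length(drop)) m <- m[, -drop, drop = FALSE]
  m
}

#' Export a feature matrix as TSV
#'
#' @param m matrix from [featureMatrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFeatureMatrix <- function(m, path) {
  df <- data.frame(pair_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Z-score scaler for the embedding and biophysical blocks, fit on training
# data only. Without it the unit-norm embedding block (per-dimension scale
# ~1/sqrt(30)) contributes almost nothing to Euclidean distances next to the
# wide-ranging biophysical descriptors. The one-hot block passes through.
.fitScaler <- function(m) {
  cols <- intersect(c(paste0("emb_", 1:30), biophysicalFeatureNames()),
                    colnames(m))
  center <- colMeans(m[, cols, drop = FALSE])
  scale <- apply(m[, cols, drop = FALSE], 2L, sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  list(cols = cols, center = center, scale = scale)
}

.applyScaler <- function(m, scaler) {
  if (is.null(scaler) || length(scaler$cols) == 0L) return(m)
  m[, scaler$cols] <- sweep(
    sweep(m[, scaler$cols, drop = FALSE], 2L, scaler$center, "-"),
    2L, scaler$scale, "/")
  m
}
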