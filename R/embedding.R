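# All sequence embedders used in the 82-length assembly emit 30 dimensions.
.EMBED_DIM <- 30L
.KMER_BASIS <- 2048L

# Per-seed projection matrices are expensive to regenerate; memoise them.
.projCache <- new.env(parent = emptyenv())

.projectionMatrix <- function(nrow, ncol, seed) {
  key <- paste(nrow, ncol, seed, sep = "_")
  if (is.null(.projCache[[key]])) {
    .projCache[[key]] <- withSeed(seed,
      matrix(rnorm(nrow * ncol), nrow, ncol) / sqrt(ncol))
  }
  .projCache[[key]]
}

# Hashed 3-mer count profile of one sequence over a fixed 2048-bin basis.
# Sequences shorter than 3 residues fall back to single-residue counts so the
# contract (non-empty sequence -> finite unit vector) still holds.
.kmerCounts <- function(sequence) {
  res <- match(strsplit(sequence, "", fixed = TRUE)[[1L]], .AA_ALPHABET) - 1L
  n <- length(res)
  idx <- if (n >= 3L) {
    (res[1:(n - 2)] * 400L + res[2:(n - 1)] * 20L + res[3:n]) %% .KMER_BASIS
  } else {
    res %% .KMER_BASIS
  }
  tabulate(idx + 1L, .KMER_BASIS)
}

#' Deterministic surrogate sequence embedder
#'
#' Stand-in for a protein-language-model encoder: the sequence's 3-mer count
#' profile, hashed onto a fixed 2048-bin basis, is projected to 30 dimensions
#' by a seed-fixed random Gaussian projection and L2-normalized. The map is a
#' pure function of `(sequence, seed)` and preserves locality: sequences that
#' share most of their 3-mers receive nearby embeddings.
#'
#' @param sequence one amino-acid string (non-empty, canonical alphabet).
#' @param seed integer seed fixing the projection; part of the embedder
#'   identity.
#' @return Numeric vector of length 30 with unit L2 norm.
#' @seealso [surrogateEmbedder()] for the pipeline-facing embedder object.
#' @export
surrogateEmbed <- function(sequence, seed = 1L) {
  msg <- .checkSequences(sequence)
  if (!is.null(msg)) stop(msg)
  proj <- .projectionMatrix(.KMER_BASIS, .EMBED_DIM, seed)
  v <- as.numeric(crossprod(proj, .kmerCounts(sequence)))
  v / sqrt(sum(v^2))
}

#' Embedder objects
#'
#' An embedder bundles an `EmbedderSpec` (name, dimension = 30, determinism
#' flag, description) with an `embed(sequences)` function returning an
#' `n x 30` matrix. Downstream code depends only on this contract, so
#' surrogate and external protein-language-model embedders are
#' interchangeable.
#'
#' @param seed projection seed for the surrogate embedder.
#' @return A list with elements `spec` and `embed`.
#' @examples
#' emb <- surrogateEmbedder(seed = 1)
#' dim(emb$embed(c("MKTAYIAKQR", "GHSQGALATA")))
#' @export
surrogateEmbedder <- function(seed = 1L) {
  force(seed)
  list(
    spec = list(name = sprintf("surrogate-kmer3-s%d", seed),
                dimension = .EMBED_DIM, deterministic = TRUE,
                description = "hashed 3-mer profile, seed-fixed random projection, L2-normalized"),
    embed = function(sequences) {
      t(vapply(sequences, surrogateEmbed, numeric(.EMBED_DIM), seed = seed))
    }
  )
}

#' Adapter embedder for external protein language models
#'
#' Contract for plugging a real encoder into the pipeline. `adapter` must be
#' a function mapping one sequence to a matrix of per-residue hidden states
#' (positions x hidden size); the reducer mean-pools over positions and
#' applies a seed-fixed linear projection to 30 dimensions. Results are
#' memoised by sequence so repeated queries never re-invoke the adapter.
#' When no adapter is supplied a capability error instructs the caller to
#' use [surrogateEmbedder()] instead; no partial output is produced.
#'
#' @param adapter function(sequence) -> numeric matrix, or `NULL`.
#' @param name label recorded in the embedder spec.
#' @param projectionSeed seed of the pooling projection (part of the
#'   embedder identity).
#' @param maxLength residue limit of the encoder; longer sequences are
#'   truncated with a warning.
#' @return An embedder object (see [surrogateEmbedder()]).
#' @export
plmEmbedder <- function(adapter, name = "plm-adapter", projectionSeed = 1L,
                        maxLength = 1022L) {
  if (is.null(adapter) || !is.function(adapter)) {
    stop("capability error: no protein-language-model adapter available; ",
         "use surrogateEmbedder() instead")
  }
  cache <- new.env(parent = emptyenv())
  embedOne <- function(sequence) {
    if (!is.null(cache[[sequence]])) return(cache[[sequence]])
    s <- sequence
    if (nchar(s) > maxLength) {
      warning("sequence truncated to adapter limit of ", maxLength,
              " residues")
      s <- substr(s, 1L, maxLength)
    }
    hidden <- adapter(s)
    if (is.null(dim(hidden))) hidden <- matrix(hidden, nrow = 1L)
    pooled <- colMeans(hidden)
    proj <- .projectionMatrix(length(pooled), .EMBED_DIM, projectionSeed)
    cache[[sequence]] <- as.numeric(crossprod(proj, pooled))
    cache[[sequence]]
  }
  list(
    spec = list(name = sprintf("%s-s%d", name, projectionSeed),
                dimension = .EMBED_DIM, deterministic = TRUE,
                description = "external encoder, mean-pooled, seed-fixed projection to 30"),
    embed = function(sequences) {
      t(vapply(sequences, embedOne, numeric(.EMBED_DIM)))
    }
  )
}
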