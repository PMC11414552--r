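# Background amino-acid frequencies (UniProt-like averages), fixed so
# generated sequences are reproducible without any download.
.BACKGROUND_FREQS <- c(
  A = 8.25, C = 1.38, D = 5.45, E = 6.75, F = 3.86, G = 7.07, H = 2.27,
  I = 5.96, K = 5.84, L = 9.66, M = 2.42, N = 4.06, P = 4.70, Q = 3.93,
  R = 5.53, S = 6.56, T = 5.34, V = 6.87, W = 1.08, Y = 2.92) / 100

# Residue-frequency bias of the simulated degrader family: degradable
# sequences enrich the motif-core and active-site-style residues, the way a
# real hydrolase family shares compositional character beyond its catalytic
# signature.
.FAMILY_BOOST <- c(W = 3, H = 2.5, S = 1.8, Q = 1.8, C = 2, G = 1.5, T = 1.3)

.familyFreqs <- function(bias) {
  boost <- setNames(rep(1, 20L), names(.BACKGROUND_FREQS))
  boost[names(.FAMILY_BOOST)] <- .FAMILY_BOOST
  fam <- .BACKGROUND_FREQS * boost
  fam <- fam / sum(fam)
  (1 - bias) * .BACKGROUND_FREQS + bias * fam
}

#' Per-plastic degradation motifs of the synthetic generator
#'
#' Each plastic type has a fixed 6-mer motif planted into degradable
#' sequences: a shared 4-residue catalytic-style core (`WHSQ`, echoing the
#' conserved serine-hydrolase signature of real polyesterases) plus a
#' 2-residue plastic-specific flank. The shared core makes the degradable
#' class coherent enough for prototype heads, while the flank ties each
#' motif to its plastic.
#'
#' @return Named character vector of 11 motifs.
#' @export
plasticMotifs <- function() {
  flanks <- c(PET = "ET", PU = "PK", PCL = "CL", PLA = "LA", PES = "ES",
              PEF = "EF", PE = "PE", PHB = "HG", PHV = "HV", PBS = "GS",
              PBSA = "GA")
  setNames(paste0("WHSQ", flanks), names(flanks))
}

#' Specification of a synthetic enzyme/plastic dataset
#'
#' Defines the shape and signal of generated data. The defaults emulate the
#' experimentally characterized dataset the framework targets: 236 pairs
#' built from 171 unique sequences over the 11 plastic types with a
#' 200:36 degradable:non-degradable imbalance. Degradable pairs carry their
#' plastic's motif (`motifCopies` planted copies, each residue corrupted
#' with probability `noiseRate`); `noiseRate = 0` guarantees an intact motif
#' and a learnable signal, `noiseRate = 1` erases it.
#'
#' @param nPairs number of enzyme/plastic pairs (default 236).
#' @param nUniqueSequences number of distinct sequences (default 171);
#'   the remaining pairs reuse sequences with other plastics.
#' @param lengthRange sequence length range in residues (default 100-300).
#' @param plasticWeights sampling weights over [plasticVocabulary()]
#'   (default uniform).
#' @param positiveFraction fraction of degradable pairs (default 200/236).
#' @param motifs named per-plastic motif set (default [plasticMotifs()]).
#' @param motifCopies planted copies per degradable pair (default 4).
#' @param familyBias strength of the degrader-family composition bias in
#'   (0, 1): background residues of degradable sequences are drawn from a
#'   mixture of the global background table and a family-enriched table
#'   (default 0.5). Attenuated by `noiseRate` together with the motifs.
#' @param noiseRate signal corruption level in \[0, 1\]: each planted motif
#'   residue is replaced by a background draw with this probability, and the
#'   family bias is scaled by `1 - noiseRate`, so `noiseRate = 1` leaves
#'   degradable and non-degradable sequences statistically identical.
#' @param seed generation seed.
#' @return Object of class `"SyntheticSpec"` (validated list).
#' @export
syntheticSpec <- function(nPairs = 236L, nUniqueSequences = 171L,
                          lengthRange = c(100L, 300L), plasticWeights = NULL,
                          positiveFraction = 200 / 236,
                          motifs = plasticMotifs(), motifCopies = 4L,
                          familyBias = 0.5, noiseRate = 0, seed = 7L) {
  vocab <- plasticVocabulary()
  if (is.null(plasticWeights)) {
    plasticWeights <- setNames(rep(1, length(vocab)), vocab)
  }
  stopifnot(nPairs >= 1L, nUniqueSequences >= 1L,
            nUniqueSequences <= nPairs,
            positiveFraction >= 0, positiveFraction <= 1,
            familyBias >= 0, familyBias <= 1,
            noiseRate >= 0, noiseRate <= 1,
            all(vocab %in% names(motifs)),
            length(lengthRange) == 2L, lengthRange[1L] <= lengthRange[2L])
  if (max(nchar(motifs)) * motifCopies * 2L > lengthRange[1L]) {
    stop("spec error: motifs do not fit into the minimum sequence length")
  }
  structure(list(nPairs = as.integer(nPairs),
                 nUniqueSequences = as.integer(nUniqueSequences),
                 lengthRange = as.integer(lengthRange),
                 plasticWeights = plasticWeights,
                 positiveFraction = positiveFraction, motifs = motifs,
                 motifCopies = as.integer(motifCopies),
                 familyBias = familyBias,
                 noiseRate = noiseRate, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

.randomSequence <- function(len, freqs = .BACKGROUND_FREQS) {
  paste(sample(names(freqs), len, replace = TRUE, prob = freqs),
        collapse = "")
}

# Corrupted motif residues are re-drawn from the background table, so at
# noiseRate = 1 a "planted" motif is indistinguishable from background.
.corruptMotif <- function(motif, noiseRate) {
  if (noiseRate <= 0) return(motif)
  res <- strsplit(motif, "", fixed = TRUE)[[1L]]
  hit <- runif(length(res)) < noiseRate
  res[hit] <- sample(names(.BACKGROUND_FREQS), sum(hit), replace = TRUE,
                     prob = .BACKGROUND_FREQS)
  paste(res, collapse = "")
}

# Implant motifs at non-overlapping positions, overwriting background
# residues. `motifs` is a character vector (one entry per copy to plant).
.implantMotifs <- function(sequence, motifs, noiseRate) {
  n <- nchar(sequence)
  occupied <- rep(FALSE, n)
  for (motif in motifs) {
    w <- nchar(motif)
    starts <- sample(n - w + 1L)
    for (s in starts) {
      span <- s:(s + w - 1L)
      if (!any(occupied[span])) {
        substr(sequence, s, s + w - 1L) <- .corruptMotif(motif, noiseRate)
        occupied[span] <- TRUE
        break
      }
    }
  }
  sequence
}

#' Generate a labeled experimental-style dataset
#'
#' Builds `nPairs` labeled enzyme/plastic pairs from `nUniqueSequences`
#' background sequences (drawn from a fixed UniProt-like residue frequency
#' table). Degradable pairs have their plastic's motif planted at random
#' non-overlapping positions; non-degradable pairs carry no motif for their
#' plastic. Generation is deterministic given the spec seed.
#'
#' @param spec a [syntheticSpec()].
#' @return A labeled [PairSet]; the spec is recorded in its metadata.
#' @examples
#' ps <- generateExperimentalLike(syntheticSpec(nPairs = 50, seed = 1))
#' labelCounts(ps)
#' @export
generateExperimentalLike <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  withSeed(spec$seed, {
    nU <- spec$nUniqueSequences
    n <- spec$nPairs
    nPos <- roundHalfUp(n * spec$positiveFraction)
    # sequences are reused across plastics within a class only (a degrader
    # either belongs to the simulated family or not), so labels stay
    # coherent at the sequence level
    nUPos <- if (nPos == 0L) 0L else max(1L, min(nPos, roundHalfUp(nU * nPos / n)))
    nUNeg <- nU - nUPos
    if (n - nPos > 0L && nUNeg == 0L) {
      nUPos <- nUPos - 1L
      nUNeg <- 1L
    }
    drawIdx <- function(nPairs, ids) {
      if (!length(ids) || !nPairs) return(integer())
      c(ids, if (nPairs > length(ids)) {
        sample(ids, nPairs - length(ids), replace = TRUE)
      })
    }
    seqIdx <- c(drawIdx(nPos, seq_len(nUPos)),
                drawIdx(n - nPos, nUPos + seq_len(nUNeg)))
    label <- rep(c(1L, 0L), c(nPos, n - nPos))
    ord <- sample(n)
    seqIdx <- seqIdx[ord]
    label <- label[ord]
    vocab <- plasticVocabulary()
    plastic <- sample(vocab, n, replace = TRUE,
                      prob = spec$plasticWeights[vocab])
    # avoid duplicated (sequence, plastic) pairs where possible
    for (tries in 1:20) {
      dup <- duplicated(paste(seqIdx, plastic))
      if (!any(dup)) break
      plastic[dup] <- sample(vocab, sum(dup), replace = TRUE,
                             prob = spec$plasticWeights[vocab])
    }
    lens <- sample(seq(spec$lengthRange[1L], spec$lengthRange[2L]), nU,
                   replace = TRUE)
    # family sequences: biased background plus planted motifs
    bias <- spec$familyBias * (1 - spec$noiseRate)
    famFreqs <- .familyFreqs(bias)
    isFam <- seq_len(nU) <= nUPos
    seqs <- vapply(seq_len(nU), function(u) {
      .randomSequence(lens[u], if (isFam[u]) famFreqs else .BACKGROUND_FREQS)
    }, character(1))
    # plant all motifs owed to each unique sequence in one pass
    for (u in seq_len(nU)) {
      pos <- which(seqIdx == u & label == 1L)
      if (!length(pos)) next
      motifs <- rep(unname(spec$motifs[plastic[pos]]),
                    each = spec$motifCopies)
      seqs[u] <- .implantMotifs(seqs[u], motifs, spec$noiseRate)
    }
    PairSet(pairId = sprintf("pair%04d", seq_len(n)),
            sequence = seqs[seqIdx], plastic = plastic, label = label,
            metadata = list(generator = "experimental-like", spec = spec))
  })
}

#' Generate an unlabeled candidate pool with hidden truth
#'
#' Emulates a prescreened homolog pool: `nCandidates` unlabeled pairs of
#' which a hidden fraction carries the degradation motif of its plastic.
#' The truth lives only in the returned manifest, never in the pool
#' `PairSet`, so it cannot leak into predictions.
#'
#' @param spec a [syntheticSpec()] (length range, motifs, noise and seed are
#'   used; the pair counts are taken from the arguments below).
#' @param nCandidates pool size.
#' @param truePositiveFraction hidden fraction of motif-bearing candidates.
#' @return List with `pool` (unlabeled [PairSet]) and `manifest`
#'   (`data.frame`: `pair_id`, `motif_bearing`, `plastic`).
#' @export
generateCandidatePool <- function(spec, nCandidates,
                                  truePositiveFraction = 0.1) {
  stopifnot(inherits(spec, "SyntheticSpec"), nCandidates >= 1L,
            truePositiveFraction >= 0, truePositiveFraction <= 1)
  withSeed(spec$seed + 1L, {
    n <- as.integer(nCandidates)
    vocab <- plasticVocabulary()
    plastic <- sample(vocab, n, replace = TRUE,
                      prob = spec$plasticWeights[vocab])
    nPos <- round(n * truePositiveFraction)
    bearing <- logical(n)
    bearing[sample(n, nPos)] <- TRUE
    lens <- sample(seq(spec$lengthRange[1L], spec$lengthRange[2L]), n,
                   replace = TRUE)
    famFreqs <- .familyFreqs(spec$familyBias * (1 - spec$noiseRate))
    seqs <- vapply(seq_len(n), function(i) {
      .randomSequence(lens[i],
                      if (bearing[i]) famFreqs else .BACKGROUND_FREQS)
    }, character(1))
    for (i in which(bearing)) {
      seqs[i] <- .implantMotifs(
        seqs[i], rep(unname(spec$motifs[plastic[i]]), spec$motifCopies),
        spec$noiseRate)
    }
    ids <- sprintf("cand%05d", seq_len(n))
    list(pool = PairSet(pairId = ids, sequence = seqs, plastic = plastic,
                        label = NA,
                        metadata = list(generator = "candidate-pool",
                                        spec = spec)),
         manifest = data.frame(pair_id = ids, motif_bearing = bearing,
                               plastic = plastic, stringsAsFactors = FALSE))
  })
}
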