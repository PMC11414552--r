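#' Percent similarity between two sequences
#'
#' Smith-Waterman local alignment (BLOSUM62, gap open 11, gap extend 1 —
#' the classic protein-alignment defaults), identities counted in the single
#' best-scoring alignment, and
#' `percent similarity = 100 * identities / length of the shorter sequence`
#' with the full unaligned length of the shorter input as denominator. The
#' two inputs are ordered canonically before aligning, so the result is
#' symmetric by construction.
#'
#' @param a,b non-empty amino-acid strings.
#' @param queryId,subjectId identifiers echoed in the result.
#' @return Object of class `"AlignmentResult"`: list with `queryId`,
#'   `subjectId`, `identicalResidues`, `smallerLength`, `percentSimilarity`
#'   and the alignment `score`.
#' @examples
#' percentSimilarity("ACDEFGHIKL", "ACDEFGHIKV")$percentSimilarity  # 90
#' @export
percentSimilarity <- function(a, b, queryId = "query", subjectId = "subject") {
  for (s in c(a, b)) {
    msg <- .checkSequences(s)
    if (!is.null(msg)) stop(msg)
  }
  # canonical input order makes traceback tie-breaking symmetric
  swap <- a > b
  aln <- pairwiseAlignment(
    AAString(if (swap) b else a), AAString(if (swap) a else b),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  ident <- nmatch(aln)
  smaller <- min(nchar(a), nchar(b))
  structure(list(queryId = queryId, subjectId = subjectId,
                 identicalResidues = ident, smallerLength = smaller,
                 percentSimilarity = 100 * ident / smaller,
                 score = Biostrings::score(aln)),
            class = "AlignmentResult")
}

#' @export
print.AlignmentResult <- function(x, ...) {
  cat(sprintf("AlignmentResult: %s vs %s: %d identities / %d = %.1f%%\n",
              x$queryId, x$subjectId, x$identicalResidues, x$smallerLength,
              x$percentSimilarity))
  invisible(x)
}

#' Maximum similarity of each query against a reference set
#'
#' For every sequence in `topList`, the maximum percent similarity against
#' all `reference` sequences, plus a binned histogram of those maxima
#' (default 10-point bins over 0-100).
#'
#' @param topList [PairSet] (or named character vector) of query sequences.
#' @param reference [PairSet] (or named character vector) of reference
#'   sequences.
#' @param binWidth histogram bin width in percent (default 10).
#' @return List with `perQuery` (`data.frame`: `query_id`,
#'   `best_subject_id`, `identities`, `smaller_length`,
#'   `percent_similarity`) and `histogram` (`data.frame`: `bin_low`,
#'   `bin_high`, `count`).
#' @export
similarityProfile <- function(topList, reference, binWidth = 10) {
  asSeqs <- function(x) {
    if (is(x, "PairSet")) {
      s <- sequences(x)
      s[!duplicated(s)]
    } else {
      if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
      x
    }
  }
  qs <- asSeqs(topList)
  rs <- asSeqs(reference)
  if (!length(qs) || !length(rs)) stop("both sequence sets must be non-empty")
  rows <- lapply(seq_along(qs), function(i) {
    best <- NULL
    for (j in seq_along(rs)) {
      r <- percentSimilarity(qs[[i]], rs[[j]], names(qs)[i], names(rs)[j])
      if (is.null(best) || r$percentSimilarity > best$percentSimilarity) {
        best <- r
      }
    }
    data.frame(query_id = best$queryId, best_subject_id = best$subjectId,
               identities = best$identicalResidues,
               smaller_length = best$smallerLength,
               percent_similarity = best$percentSimilarity,
               stringsAsFactors = FALSE)
  })
  perQuery <- do.call(rbind, rows)
  lo <- seq(0, 100 - binWidth, by = binWidth)
  hist <- data.frame(
    bin_low = lo, bin_high = lo + binWidth,
    count = vapply(lo, function(b) {
      hi <- b + binWidth
      sum(perQuery$percent_similarity >= b &
            (perQuery$percent_similarity < hi |
               (hi == 100 & perQuery$percent_similarity <= 100)))
    }, numeric(1)))
  list(perQuery = perQuery, histogram = hist)
}
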