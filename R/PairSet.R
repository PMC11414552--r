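#' Plastic-type vocabulary
#'
#' The eleven plastic substrate codes supported by the framework, in the
#' fixed order that defines the one-hot encoding index: PET, PU, PCL, PLA,
#' PES (poly(ethylene succinate)), PEF (poly(ethylene furanoate)), PE,
#' PHB, PHV, PBS, PBSA. The order is part of the feature-vector contract
#' and never changes between runs.
#'
#' @return Character vector of length 11.
#' @examples
#' plasticVocabulary()
#' @export
plasticVocabulary <- function() {
  c("PET", "PU", "PCL", "PLA", "PES", "PEF", "PE", "PHB", "PHV", "PBS", "PBSA")
}

# Canonical replacements for ambiguous residue codes under the "map" policy.
.AMBIGUOUS_MAP <- c(X = "A", B = "N", Z = "Q", U = "C")

.checkSequences <- function(sequence) {
  if (any(!nzchar(sequence))) {
    return("sequences must be non-empty")
  }
  bad <- grepl(paste0("[^", paste(.AA_ALPHABET, collapse = ""), "]"), sequence)
  if (any(bad)) {
    return(sprintf(
      "invalid residue in sequence(s) %s: only the 20 canonical amino-acid letters are allowed",
      paste(head(which(bad), 5L), collapse = ", ")))
  }
  NULL
}

#' PairSet: a dataset of enzyme/plastic pairs
#'
#' `PairSet` is the central container of the package: each record pairs one
#' amino-acid sequence with one plastic-type code, an optional binary
#' ground-truth label (1 = degradable, 0 = non-degradable, `NA` = unknown),
#' and a `tagged` flag used by the blending assessment. The same sequence may
#' appear in several records with different plastics.
#'
#' @slot pairId character, unique record identifiers.
#' @slot sequence character, amino-acid sequences over the 20-letter alphabet.
#' @slot plastic character, codes from [plasticVocabulary()].
#' @slot label integer, 1/0/`NA`.
#' @slot tagged logical, blending-assessment flag; `TRUE` requires a label.
#' @slot metadata list, free-form provenance (source file, generator spec).
#'
#' @aliases PairSet-class
#' @export
setClass("PairSet",
  representation(
    pairId   = "character",
    sequence = "character",
    plastic  = "character",
    label    = "integer",
    tagged   = "logical",
    metadata = "list"
  ),
  prototype(metadata = list())
)

setValidity("PairSet", function(object) {
  n <- length(object@pairId)
  if (length(object@sequence) != n || length(object@plastic) != n ||
      length(object@label) != n || length(object@tagged) != n) {
    return("all record slots must have the same length")
  }
  if (n == 0L) return(TRUE)
  if (anyDuplicated(object@pairId)) {
    return("pair identifiers must be unique")
  }
  msg <- .checkSequences(object@sequence)
  if (!is.null(msg)) return(msg)
  badp <- !(object@plastic %in% plasticVocabulary())
  if (any(badp)) {
    return(sprintf("unknown plastic code '%s' (record %d); valid codes: %s",
                   object@plastic[which(badp)[1L]], which(badp)[1L],
                   paste(plasticVocabulary(), collapse = ", ")))
  }
  if (!all(object@label %in% c(0L, 1L, NA_integer_))) {
    return("labels must be 1, 0 or NA")
  }
  if (any(object@tagged & is.na(object@label))) {
    return("tagged records must carry a ground-truth label")
  }
  TRUE
})

#' Construct a PairSet
#'
#' @param pairId unique identifiers.
#' @param sequence amino-acid sequences. Ambiguity codes (X, B, Z, U) are
#'   rejected under the default policy; `residuePolicy = "map"` replaces them
#'   with canonical stand-ins (X->A, B->N, Z->Q, U->C) before validation.
#' @param plastic plastic-type codes, see [plasticVocabulary()].
#' @param label 1/0/`NA` ground truth (degradable / non-degradable / unknown).
#' @param tagged logical blending flag (default all `FALSE`).
#' @param metadata optional provenance list.
#' @param residuePolicy `"reject"` (default) or `"map"`.
#' @return A validated `PairSet`.
#' @examples
#' ps <- PairSet(pairId = c("a", "b"),
#'               sequence = c("MKTAYIAKQR", "GHSQGALATA"),
#'               plastic = c("PET", "PLA"), label = c(1L, NA))
#' ps
#' @export
PairSet <- function(pairId, sequence, plastic, label = NA,
                    tagged = FALSE, metadata = list(),
                    residuePolicy = c("reject", "map")) {
  residuePolicy <- match.arg(residuePolicy)
  sequence <- toupper(as.character(sequence))
  if (residuePolicy == "map") {
    for (code in names(.AMBIGUOUS_MAP)) {
      sequence <- gsub(code, .AMBIGUOUS_MAP[[code]], sequence, fixed = TRUE)
    }
  }
  n <- length(pairId)
  label <- suppressWarnings(as.integer(label))
  new("PairSet",
      pairId   = as.character(pairId),
      sequence = sequence,
      plastic  = as.character(plastic),
      label    = rep_len(label, n),
      tagged   = rep_len(as.logical(tagged), n),
      metadata = metadata)
}

#' @describeIn PairSet number of enzyme/plastic pairs.
#' @param x a `PairSet`.
#' @export
setMethod("length", "PairSet", function(x) length(x@pairId))

#' @export
setGeneric("pairIds", function(x) standardGeneric("pairIds"))
#' @describeIn PairSet record identifiers.
#' @export
setMethod("pairIds", "PairSet", function(x) x@pairId)

#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @describeIn PairSet named character vector of sequences.
#' @export
setMethod("sequences", "PairSet",
          function(x) setNames(x@sequence, x@pairId))

#' @export
setGeneric("plastics", function(x) standardGeneric("plastics"))
#' @describeIn PairSet named character vector of plastic codes.
#' @export
setMethod("plastics", "PairSet", function(x) setNames(x@plastic, x@pairId))

#' @export
setGeneric("pairLabels", function(x) standardGeneric("pairLabels"))
#' @describeIn PairSet named integer vector of labels (1/0/NA).
#' @export
setMethod("pairLabels", "PairSet", function(x) setNames(x@label, x@pairId))

#' @export
setGeneric("taggedFlags", function(x) standardGeneric("taggedFlags"))
#' @describeIn PairSet named logical vector of blending flags.
#' @export
setMethod("taggedFlags", "PairSet", function(x) setNames(x@tagged, x@pairId))

#' @describeIn PairSet subset records by index, logical mask or pair id.
#' @param i index vector.
#' @param j,drop,... ignored (matrix-style arguments are not used).
#' @export
setMethod("[", "PairSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) {
    i <- match(i, x@pairId)
    if (anyNA(i)) stop("unknown pair id(s) in subset")
  }
  initialize(x,
             pairId = x@pairId[i], sequence = x@sequence[i],
             plastic = x@plastic[i], label = x@label[i],
             tagged = x@tagged[i], metadata = x@metadata)
})

#' @describeIn PairSet summary display.
#' @param object a `PairSet`.
#' @export
setMethod("show", "PairSet", function(object) {
  cnt <- labelCounts(object)
  cat(sprintf(
    "PairSet with %d enzyme/plastic pairs (%d unique sequences, %d plastic types)\n",
    length(object), length(unique(object@sequence)),
    length(unique(object@plastic))))
  cat(sprintf("  degradable: %d  non-degradable: %d  unlabeled: %d  tagged: %d\n",
              cnt[["degradable"]], cnt[["non_degradable"]],
              cnt[["unlabeled"]], sum(object@tagged)))
})

#' Label counts of a PairSet
#'
#' @param x a `PairSet`.
#' @return Named integer vector with entries `degradable`, `non_degradable`
#'   and `unlabeled`.
#' @export
labelCounts <- function(x) {
  stopifnot(is(x, "PairSet"))
  c(degradable     = sum(x@label == 1L, na.rm = TRUE),
    non_degradable = sum(x@label == 0L, na.rm = TRUE),
    unlabeled      = sum(is.na(x@label)))
}

#' Convert a PairSet to a data.frame
#'
#' @param x a `PairSet`.
#' @param row.names,optional,... passed through for S3 compatibility; unused.
#' @return `data.frame` with columns `pair_id`, `sequence`, `plastic`,
#'   `label`, `tagged`.
#' @export
as.data.frame.PairSet <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(pair_id = x@pairId, sequence = x@sequence, plastic = x@plastic,
             label = x@label, tagged = x@tagged, stringsAsFactors = FALSE)
}
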