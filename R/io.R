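#' Read an enzyme/plastic pair table
#'
#' Reads a CSV (or TSV) pair table with mandatory header columns `pair_id`,
#' `sequence`, `plastic`, `label` and an optional `tagged` column. Empty
#' `label` cells become `NA` (unlabeled); `tagged` accepts 1/0. Row order is
#' preserved.
#'
#' @param path path to the table.
#' @param format `"csv"` (default) or `"tsv"`.
#' @param residuePolicy passed to [PairSet()].
#' @return A validated [PairSet].
#' @seealso [writePairs()], [readFastaWithSidecar()]
#' @export
readPairs <- function(path, format = c("csv", "tsv"),
                      residuePolicy = c("reject", "map")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- if (format == "csv") {
    read.csv(path, colClasses = "character", check.names = FALSE)
  } else {
    read.delim(path, colClasses = "character", check.names = FALSE)
  }
  required <- c("pair_id", "sequence", "plastic", "label")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "))
  }
  label <- df$label
  label[!nzchar(trimws(label))] <- NA
  tagged <- if ("tagged" %in% names(df)) {
    tg <- df$tagged
    tg[!nzchar(trimws(tg))] <- "0"
    as.integer(tg) == 1L
  } else {
    FALSE
  }
  PairSet(pairId = df$pair_id, sequence = df$sequence, plastic = df$plastic,
          label = label, tagged = tagged,
          metadata = list(source = path, format = format),
          residuePolicy = residuePolicy)
}

#' Write an enzyme/plastic pair table
#'
#' Writes the standard pair table consumed by [readPairs()]; a write/read
#' round trip reproduces all record fields exactly.
#'
#' @param x a [PairSet].
#' @param path output path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writePairs <- function(x, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  stopifnot(is(x, "PairSet"))
  df <- as.data.frame(x)
  df$label <- ifelse(is.na(df$label), "", as.character(df$label))
  df$tagged <- as.integer(df$tagged)
  write.table(df, path, sep = if (format == "csv") "," else "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read pairs from a FASTA file plus a sidecar table
#'
#' FASTA carries the sequences; the sidecar table (CSV/TSV with header
#' `pair_id`, `seq_id`, `plastic`, optional `label` and `tagged`) defines one
#' enzyme/plastic pair per row, keyed to FASTA record ids through `seq_id`.
#' A sequence may be referenced by several rows (one enzyme tested against
#' several plastics).
#'
#' @param fasta path to a FASTA file of amino-acid sequences.
#' @param sidecar path to the sidecar table.
#' @param format sidecar format, `"csv"` or `"tsv"`.
#' @param residuePolicy passed to [PairSet()].
#' @return A [PairSet] with one record per sidecar row.
#' @export
readFastaWithSidecar <- function(fasta, sidecar, format = c("csv", "tsv"),
                                 residuePolicy = c("reject", "map")) {
  format <- match.arg(format)
  aa <- readAAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    stop("format error: duplicate FASTA id '", ids[duplicated(ids)][1L], "'")
  }
  seqs <- setNames(as.character(aa), ids)
  df <- if (format == "csv") {
    read.csv(sidecar, colClasses = "character", check.names = FALSE)
  } else {
    read.delim(sidecar, colClasses = "character", check.names = FALSE)
  }
  required <- c("pair_id", "seq_id", "plastic")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("schema error: missing sidecar column(s) ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    warning("empty sidecar: returning an empty PairSet")
    return(PairSet(character(), character(), character(), integer(),
                   logical(), metadata = list(fasta = fasta)))
  }
  orphan <- !(df$seq_id %in% ids)
  if (any(orphan)) {
    stop("lookup error: sidecar row ", which(orphan)[1L],
         " references absent FASTA id '", df$seq_id[which(orphan)[1L]], "'")
  }
  label <- if ("label" %in% names(df)) {
    lb <- df$label; lb[!nzchar(trimws(lb))] <- NA; lb
  } else {
    NA
  }
  tagged <- if ("tagged" %in% names(df)) {
    tg <- df$tagged; tg[!nzchar(trimws(tg))] <- "0"; as.integer(tg) == 1L
  } else {
    FALSE
  }
  PairSet(pairId = df$pair_id, sequence = unname(seqs[df$seq_id]),
          plastic = df$plastic, label = label, tagged = tagged,
          metadata = list(fasta = fasta, sidecar = sidecar),
          residuePolicy = residuePolicy)
}

#' Split a PairSet into training and testing sets
#'
#' Uniform random split at a fixed seed. The test-set size is
#' `round-half-up(n * testFraction)`, the rule consistent with a 7:3 split of
#' 236 pairs yielding 71 test pairs. The split is unstratified by default;
#' `stratify = TRUE` splits within each label stratum instead.
#'
#' @param x a non-empty [PairSet].
#' @param testFraction proportion held out, in (0, 1); default 0.3.
#' @param seed integer RNG seed; same seed, same split.
#' @param stratify stratify by label (default `FALSE`).
#' @return `list(train = PairSet, test = PairSet)`; disjoint, union = input.
#' @examples
#' ps <- generateExperimentalLike(syntheticSpec(nPairs = 40, seed = 1))
#' sp <- splitTrainTest(ps, 0.3, seed = 1)
#' c(train = length(sp$train), test = length(sp$test))
#' @export
splitTrainTest <- function(x, testFraction = 0.3, seed = 1L,
                           stratify = FALSE) {
  stopifnot(is(x, "PairSet"))
  n <- length(x)
  if (n == 0L) stop("dataset is empty")
  if (!(testFraction > 0 && testFraction < 1)) {
    stop("testFraction must be in (0, 1)")
  }
  nTest <- roundHalfUp(n * testFraction)
  if (nTest == 0L || nTest == n) {
    stop("degenerate split: test size would be ", nTest, " of ", n)
  }
  testIdx <- withSeed(seed, {
    if (stratify) {
      strata <- split(seq_len(n), addNA(factor(x@label)))
      idx <- unlist(lapply(strata, function(s) {
        k <- roundHalfUp(length(s) * testFraction)
        sample(s, min(k, length(s)))
      }), use.names = FALSE)
      # stratum-wise rounding can drift from the global target by a record
      if (length(idx) > nTest) idx <- idx[seq_len(nTest)]
      if (length(idx) < nTest) {
        idx <- c(idx, sample(setdiff(seq_len(n), idx), nTest - length(idx)))
      }
      idx
    } else {
      sample(n, nTest)
    }
  })
  testIdx <- sort(testIdx)
  list(train = x[setdiff(seq_len(n), testIdx)], test = x[testIdx])
}
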