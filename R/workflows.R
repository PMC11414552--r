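#' End-to-end training and evaluation workflow
#'
#' Splits a labeled dataset 7:3 (round-half-up test size), runs the ensemble
#' across the given seeds, and produces the standard evaluation artifacts:
#' per-run and mean metrics, the accuracy grid over confidence/uncertainty
#' thresholds (averaged over runs), the cross-run ranking matrix, and
#' common-top-list stability reports.
#'
#' @param data labeled [PairSet].
#' @param headKind `"mlp"` or `"prototype"`.
#' @param nHeads ensemble size (default 25).
#' @param seeds base seeds for the runs (default `1:5`).
#' @param testFraction held-out fraction (default 0.3).
#' @param splitSeed seed of the train/test split.
#' @param topFractions stability top fractions (default `c(0.2, 0.3)`).
#' @param embedder,headConfig passed to [trainEnsemble()].
#' @param confGrid,uncGrid passed to [thresholdGridReport()].
#' @param outputDir optional directory; when given, predictions, the grid
#'   and the ranking matrix are written as TSV with the seeds recorded.
#' @return List with `split`, `multi`, `perRunMetrics`, `meanMetrics`,
#'   `grid`, `topReports`, `rankingMatrix`.
#' @export
trainEvalWorkflow <- function(data, headKind = c("mlp", "prototype"),
                              nHeads = 25L, seeds = 1:5,
                              testFraction = 0.3, splitSeed = 1L,
                              topFractions = c(0.2, 0.3),
                              embedder = surrogateEmbedder(),
                              headConfig = list(),
                              confGrid = c(NA, 0.80, 0.85, 0.90, 0.95, 0.99),
                              uncGrid = c(NA, 0.10, 0.05, 0.02, 0.01),
                              outputDir = NULL) {
  headKind <- match.arg(headKind)
  sp <- splitTrainTest(data, testFraction, seed = splitSeed)
  labels <- pairLabels(sp$test)
  multi <- runMultiSeed(sp$train, sp$test, seeds = seeds,
                        headKind = headKind, n = nHeads,
                        embedder = embedder, headConfig = headConfig)
  perRun <- lapply(multi$runs, function(r) {
    computeMetrics(r$predictedClass, labels[r$pairId])
  })
  meanMetrics <- colMeans(do.call(rbind, lapply(perRun, function(m) {
    c(accuracy = m$accuracy, precision = m$precision, recall = m$recall,
      f1 = m$f1)
  })))
  grids <- lapply(multi$runs, thresholdGridReport, truth = labels,
                  confGrid = confGrid, uncGrid = uncGrid)
  grid <- grids[[1L]][, c("confMin", "uncMax")]
  grid$meanN <- rowMeans(vapply(grids, `[[`, numeric(nrow(grid)), "n"))
  grid$meanAccuracy <- rowMeans(
    vapply(grids, `[[`, numeric(nrow(grid)), "accuracy"), na.rm = TRUE)
  topReports <- lapply(topFractions, function(p) {
    commonTopList(multi, p, labels = labels)
  })
  names(topReports) <- paste0("top", topFractions)
  rankingMatrix <- rankingHeatmapTable(multi)
  out <- list(split = sp, multi = multi, perRunMetrics = perRun,
              meanMetrics = meanMetrics, grid = grid,
              topReports = topReports, rankingMatrix = rankingMatrix,
              seeds = seeds, headKind = headKind)
  if (!is.null(outputDir)) .writeEvalArtifacts(out, outputDir)
  out
}

.writeEvalArtifacts <- function(res, outputDir) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# headKind=%s seeds=%s", res$headKind,
                 paste(res$seeds, collapse = ","))
  for (nm in names(res$multi$runs)) {
    f <- file.path(outputDir, paste0("predictions_", nm, ".tsv"))
    writeLines(hdr, f)
    suppressWarnings(write.table(res$multi$runs[[nm]], f, sep = "\t",
                                 row.names = FALSE, quote = FALSE,
                                 append = TRUE))
  }
  f <- file.path(outputDir, "threshold_grid.tsv")
  writeLines(hdr, f)
  suppressWarnings(write.table(res$grid, f, sep = "\t", row.names = FALSE,
                               quote = FALSE, append = TRUE))
  f <- file.path(outputDir, "ranking_matrix.tsv")
  writeLines(c(hdr, "# larger ranking value = better"), f)
  suppressWarnings(write.table(
    data.frame(run = rownames(res$rankingMatrix), res$rankingMatrix,
               check.names = FALSE),
    f, sep = "\t", row.names = FALSE, quote = FALSE, append = TRUE))
  invisible(outputDir)
}

#' Candidate mining workflow with blending assessment
#'
#' Trains on the full labeled dataset, predicts a blended candidate pool
#' across seeds with one or two head kinds, and reports tagged-pair
#' enrichment per model plus the intersection candidate list when two
#' models are used.
#'
#' @param train labeled [PairSet] used for training.
#' @param pool a [BlendedPool-class].
#' @param headKinds one or both of `"mlp"`, `"prototype"`.
#' @param nHeads ensemble size (default 25).
#' @param seeds base seeds (default `1:5`).
#' @param pList top fractions for the blending report
#'   (default `c(0.005, 0.01)`).
#' @param embedder,headConfig passed to [trainEnsemble()].
#' @return List with per-model `reports` (class `"BlendingReport"`),
#'   per-model `multis`, and `combined` (intersection list, `NULL` for a
#'   single model).
#' @export
mineCandidates <- function(train, pool, headKinds = c("mlp", "prototype"),
                           nHeads = 25L, seeds = 1:5,
                           pList = c(0.005, 0.01),
                           embedder = surrogateEmbedder(),
                           headConfig = list()) {
  stopifnot(is(pool, "BlendedPool"))
  headKinds <- match.arg(headKinds, several.ok = TRUE)
  multis <- lapply(headKinds, function(kind) {
    runMultiSeed(train, poolPairs(pool), seeds = seeds, headKind = kind,
                 n = nHeads, embedder = embedder, headConfig = headConfig)
  })
  names(multis) <- headKinds
  reports <- lapply(multis, function(m) blendingAssessment(pool, m, pList))
  combined <- NULL
  if (length(multis) >= 2L) {
    combined <- lapply(pList, function(p) {
      intersectModelTopLists(multis, p, pool = pool)
    })
    names(combined) <- paste0("top", pList)
  }
  list(reports = reports, multis = multis, combined = combined)
}
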