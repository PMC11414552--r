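# Independent quadratic Gotoh local-alignment score oracle (BLOSUM62,
# affine gaps; the first gap residue costs open + extend). Used to verify
# the alignment route in the similarity module on short sequences.
swScoreOracle <- function(a, b, open = 11, ext = 1) {
  B62 <- get(utils::data("BLOSUM62", package = "Biostrings",
                         envir = environment()), envir = environment())
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
      s <- B62[A[i - 1], B[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + s, X[i - 1, j - 1] + s,
                     Y[i - 1, j - 1] + s)
      best <- max(best, M[i, j])
    }
  }
  best
}
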