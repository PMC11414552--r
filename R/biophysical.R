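# Residue category sets used by the global descriptors. Aromaticity follows
# the classic F/W/Y definition; the aromatic-fraction descriptor additionally
# counts the histidine ring so the two columns are not duplicates.
.AA_SETS <- list(
  positive    = c("K", "R", "H"),
  negative    = c("D", "E"),
  aromatic    = c("F", "W", "Y", "H"),
  aliphatic   = c("A", "V", "L", "I"),
  polar       = c("S", "T", "N", "Q", "Y", "C"),
  hydrophobic = c("A", "C", "F", "I", "L", "M", "V"),
  tiny        = c("A", "C", "G", "S", "T"),
  helix       = c("V", "I", "Y", "F", "W", "L"),
  turn        = c("N", "P", "G", "S"),
  sheet       = c("E", "M", "A", "L")
)

# EMBOSS pK values for the Henderson-Hasselbalch charge model.
.PK_POSITIVE <- c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5)
.PK_NEGATIVE <- c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

.netCharge <- function(counts, pH) {
  pos <- sum(c(1, counts[c("K", "R", "H")]) /
               (1 + 10^(pH - .PK_POSITIVE)))
  neg <- sum(c(1, counts[c("D", "E", "C", "Y")]) /
               (1 + 10^(.PK_NEGATIVE - pH)))
  pos - neg
}

.isoelectricPoint <- function(counts, tol = 1e-4) {
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (.netCharge(counts, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Sliding-window mean of the Vihinen per-residue flexibility scale.
# Window 9; sequences shorter than the window use one window over all
# available positions.
.flexProfile <- function(res, window = 9L) {
  v <- .AA_FLEXIBILITY[res]
  n <- length(v)
  if (n <= window) return(mean(v))
  cs <- cumsum(c(0, v))
  (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
}

#' Names of the 41 biophysical descriptors
#'
#' @return Character vector of length 41 in feature-vector order: the 20
#'   amino-acid composition fractions (alphabetical) followed by 21
#'   whole-sequence descriptors.
#' @export
biophysicalFeatureNames <- function() {
  c(paste0("comp_", .AA_ALPHABET),
    "length", "mol_weight", "isoelectric_point", "aromaticity",
    "instability_index", "gravy", "net_charge_pH7",
    "frac_positive", "frac_negative", "frac_aromatic", "frac_aliphatic",
    "frac_polar", "frac_hydrophobic", "frac_tiny",
    "helix_frac", "turn_frac", "sheet_frac",
    "ext_coef_reduced", "ext_coef_cystine",
    "flex_mean", "flex_sd")
}

#' Compute the 41 biophysical descriptors of a sequence
#'
#' Deterministic physicochemical summary of one amino-acid sequence: the 20
#' composition fractions (which sum to 1), sequence length, average molecular
#' weight, isoelectric point (Henderson-Hasselbalch bisection, EMBOSS pK set),
#' aromaticity (F+W+Y fraction), Guruprasad instability index, GRAVY
#' (mean Kyte-Doolittle hydropathy), net charge at pH 7, seven residue-class
#' fractions, helix/turn/sheet propensity fractions, molar extinction
#' coefficients at 280 nm (reduced and cystine-bridged), and the mean and
#' standard deviation of a window-9 Vihinen flexibility profile.
#'
#' @param sequence one amino-acid string over the 20 canonical letters.
#' @return Named numeric vector of length 41 (see
#'   [biophysicalFeatureNames()]); all values finite.
#' @examples
#' biophysicalFeatures("ACDEFGHIKLMNPQRSTVWY")[c("comp_A", "length", "gravy")]
#' @export
biophysicalFeatures <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  msg <- .checkSequences(sequence)
  if (!is.null(msg)) stop(msg)
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(res)
  counts <- setNames(tabulate(factor(res, levels = .AA_ALPHABET), 20L),
                     .AA_ALPHABET)
  comp <- counts / n

  instability <- if (n >= 2L) {
    idx <- cbind(res[-n], res[-1L])
    (10 / (n - 1)) * sum(.AA_DIWV[idx])
  } else {
    0
  }
  flex <- .flexProfile(res)
  fracs <- vapply(.AA_SETS, function(s) sum(comp[s]), numeric(1))

  out <- c(
    comp,
    length            = n,
    mol_weight        = sum(counts * .AA_RESIDUE_MASS) + .WATER_MASS,
    isoelectric_point = .isoelectricPoint(counts),
    aromaticity       = sum(comp[c("F", "W", "Y")]),
    instability_index = instability,
    gravy             = sum(comp * .AA_HYDROPATHY),
    net_charge_pH7    = .netCharge(counts, 7),
    frac_positive     = fracs[["positive"]],
    frac_negative     = fracs[["negative"]],
    frac_aromatic     = fracs[["aromatic"]],
    frac_aliphatic    = fracs[["aliphatic"]],
    frac_polar        = fracs[["polar"]],
    frac_hydrophobic  = fracs[["hydrophobic"]],
    frac_tiny         = fracs[["tiny"]],
    helix_frac        = fracs[["helix"]],
    turn_frac         = fracs[["turn"]],
    sheet_frac        = fracs[["sheet"]],
    ext_coef_reduced  = 5500 * counts[["W"]] + 1490 * counts[["Y"]],
    ext_coef_cystine  = 5500 * counts[["W"]] + 1490 * counts[["Y"]] +
                        125 * (counts[["C"]] %/% 2L),
    flex_mean         = mean(flex),
    flex_sd           = if (length(flex) > 1L) sd(flex) else 0
  )
  names(out) <- biophysicalFeatureNames()
  out
}
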