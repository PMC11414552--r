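---
title: "Screening enzyme/plastic pairs with ensemble confidence and uncertainty"
author: "plastizyme authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening enzyme/plastic pairs with ensemble confidence and uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastizyme)
```

## The problem

Enzymatic depolymerization is one of the few scalable routes for recycling
polyester-type plastics, but experimentally characterized plastic-degrading
enzymes are rare: a curated literature collection yields on the order of a
couple of hundred enzyme/plastic pairs with trustworthy degradable /
non-degradable calls, against which homology searches return tens of
thousands of uncharacterized candidate sequences. The practical question is
not "can we classify?" but "which few dozen candidates are worth taking to
the bench?" — a ranking and enrichment problem under severe label scarcity.

`plastizyme` addresses that question with a deliberately small pipeline:

1. encode each enzyme/plastic pair as an 82-length feature vector;
2. classify with an ensemble of `N = 25` independently seeded binary heads
   (a multilayer perceptron or a prototype classifier);
3. summarize the ensemble spread per pair as *confidence* and
   *uncertainty*;
4. rank pairs jointly by the two statistics, repeat over 5 seeds, and keep
   only the top-ranked pairs common to all runs;
5. validate the whole machine with a *blending assessment*: hide known
   degraders inside an unlabeled pool and measure how strongly the top
   list concentrates them.

## Data model

A `PairSet` holds records of (sequence, plastic, optional label, tagged
flag). Eleven plastic-type codes are supported, in the fixed order
`r paste(plasticVocabulary(), collapse = ", ")`; the order defines the
one-hot index and never changes. The same sequence may appear in several
records (one enzyme tested against several plastics), which is exactly how
experimental datasets in this area are structured. Ambiguous residues
(X/B/Z/U) are rejected by default; an explicit `residuePolicy = "map"`
replaces them with canonical stand-ins, since silent coercion of sequence
data is a classic source of irreproducibility.

Train/test splitting is uniform at a fixed seed with a round-half-up test
size — the only rounding rule consistent with a 7:3 split of 236 pairs
producing 71 test pairs. Stratified splitting is available but off by
default. Note that splitting happens at the *pair* level: because some
sequences carry several pairs, a test pair can share its sequence with a
training pair. This mirrors the usual study design in the field, and it
means test accuracy partially reflects sequence memorization; the
synthetic-data section below shows how we quantify that.

## Featurization

The 82-length vector is the concatenation of three blocks, in fixed order:

* **Embedding (30).** A sequence-level summary vector. Real protein
  language models are attached through an adapter contract
  (`plmEmbedder()`: per-residue hidden states, mean-pooled, then a
  seed-fixed linear projection to 30 — the reducer is part of the embedder
  identity, since no standard 30-length pLM summary exists). The default
  is a deterministic surrogate (`surrogateEmbedder()`): hashed 3-mer
  counts over a 2048-bin basis, random-projected to 30 dimensions and
  L2-normalized. It is a pure function of (sequence, seed), preserves
  locality (one substitution moves the embedding slightly), and makes the
  entire pipeline testable without model weights. It is *not* a pLM and
  we make no claim of equivalence.
* **Biophysical descriptors (41).** Twenty amino-acid composition
  fractions (which must sum to 1) plus 21 whole-sequence descriptors:
  length, average molecular weight, isoelectric point (bisection on the
  Henderson–Hasselbalch charge with the EMBOSS pK set), aromaticity
  (F+W+Y), the Guruprasad instability index, GRAVY, net charge at pH 7,
  seven residue-class fractions (positive, negative, aromatic-ring,
  aliphatic, polar, hydrophobic, tiny), helix/turn/sheet propensity
  fractions, molar extinction coefficients at 280 nm (reduced and
  cystine-bridged), and the mean and standard deviation of a window-9
  Vihinen flexibility profile. All scale constants are literature tables
  embedded in the package. The published feature sets in this area defer
  to prior work that is not fully specified; this set is our documented
  stand-in with the same size and character, and the tested contract is
  the count (41), determinism, and the composition-sum invariant.
* **One-hot plastic (11).** A single 1 at the vocabulary index.

Feature subsets (`no_embedding`, `no_biophysical`, `no_plastic`) can be
masked out for ablation-style runs without perturbing the other blocks.

**Scaling.** At training time a z-score scaler is fit on the training
rows and applied to the embedding and biophysical blocks; the one-hot
block passes through. Standardizing the embedding block as well as the
biophysical one is a deliberate design choice: the surrogate embedding is
L2-normalized, so its per-dimension scale (~`1/sqrt(30)`) would otherwise
contribute only a few percent of any Euclidean distance, and the
distance-based prototype head would be structurally unable to use the
sequence-signal block.

## Classification heads

**MLP.** A single-hidden-layer feed-forward network (8 hidden units,
logistic output, cross-entropy loss, weight decay 0.01, at most 200
BFGS iterations), fitted with `nnet`. At a few hundred training pairs a
deeper network adds fitting cost and variance but no measurable accuracy;
all values are config-overridable. Seeded random initialization makes
retraining bit-reproducible and different seeds give different heads.

**Prototype.** Each class is summarized by the mean feature vector of its
training members; a query's probability is the softmax over classes of the
negative squared Euclidean distance to the two prototypes. The softmax
temperature defaults to the prototype-space dimension, i.e. distances are
compared per dimension. This matters numerically: with temperature 1 in a
z-scored 82-dimensional space, distance differences are O(100) and the
probabilities saturate to exactly 0 or 1, collapsing confidence and
uncertainty to constants and reducing the ranking to an id-order
tie-break. The temperature choice does not affect the predicted class
(that is always "nearer prototype"), and in a 1-dimensional toy space it
reduces to the textbook temperature-1 softmax.

Ties at probability exactly 0.5 are called non-degradable (conservative).

## Ensemble confidence and uncertainty

An ensemble holds `N = 25` heads sharing one feature representation, with
head seeds derived as `baseSeed + i`. For an input `x` with per-head
degradable probabilities `f_i(x)`:

* predicted class: degradable iff `mean(f_i(x)) > 0.5`;
* confidence: `mean_i max(f_i(x), 1 - f_i(x))` — always in [0.5, 1];
* uncertainty: the population (divide-by-N) standard deviation of those
  per-head maxima — in [0, 0.5], zero exactly when all heads agree.

*Where head diversity comes from.* MLP heads differ through their random
initial weights. A prototype head, however, is a deterministic function of
the training set — identical heads would make every uncertainty zero. We
therefore train each prototype head on a per-seed stratified bootstrap
resample of the training rows, so the ensemble spread estimates the
sampling error of the class means. We considered the alternative of giving
each head a seed-fixed random projection (16–64 dimensions): it produces
spread but costs accuracy at every dimension we tested, because the
projection noise moves the decision boundary rather than reflecting
genuine estimation uncertainty.

Predictions can be filtered by thresholds (retain strictly
`confidence > c` and `uncertainty < u`), and `thresholdGridReport()`
evaluates the metrics over a grid of such cells, including the unfiltered
cell. Tightening either threshold provably retains a subset of the looser
selection. Accuracy, precision, recall and F1 use the standard confusion
formulas with degradable as the positive class; zero-denominator cells
report 0 with a degeneracy flag instead of failing, so sparse grid cells
stay reportable.

## Ranking, stability, and the blending assessment

Pairs are ranked by the rank-of-sum-of-ranks statistic
`R(R(confidence) + R(1/uncertainty))`, where `R` is the ascending
average-tie rank. Larger is better, and the statistic provably respects
dominance (higher confidence with lower uncertainty never ranks worse).
`R(1/uncertainty)` is computed as the rank of `-uncertainty`: the same
ordering for positive uncertainties, finite for zero-uncertainty pairs,
which end up tied at the best inverse-uncertainty rank. Report positions
break remaining ties by pair id so runs are byte-reproducible.

A multi-seed run repeats train/predict/rank over (by default) five seeds,
takes a per-pair majority vote (odd seed counts enforced) and averages
confidence and uncertainty. Stability is measured by the *common top
list*: the intersection of the per-run top-`p` lists, with
`k = floor(p * n)` (minimum 1) — the rule consistent with published
top-30% and top-20% list sizes of 21 and 14 for 71 test pairs.

The blending assessment hides ground-truth degradable pairs ("tagged")
inside an unlabeled candidate pool. The merged pool carries no labels and
no flags — the tagged manifest lives out of band, and a test asserts that
predictions are invariant to it. After multi-seed prediction of the pool,
the *candidate top list* at fraction `p` consists of the
`k = floor(p * pool size)` best-ranked pairs **among those predicted
degradable**, intersected across runs. The class restriction is
deliberate: confidence is symmetric (`max(f, 1-f)`), so a pool dominated
by confident negatives would otherwise fill the top list with pairs that
are useless for mining; published top lists in this area consist of
degradable predictions only. Enrichment is then:

* initial concentration = tagged / pool size;
* final concentration = tagged-in-list / list size;
* concentration factor = final / initial.

The factor is reported twice: exact, and in a "printed" convention that
first rounds both concentrations half-up to two decimals as percentages
and then rounds the ratio half-up to an integer — the convention needed to
reproduce hand-rounded report tables (e.g. 4.90 / 0.15 → 33). A
random-scoring ranker leaves the concentration at its initial value
(checked by simulation against a 3-standard-error band), and a perfect
ranker reaches `min(1, tagged / k)` (checked analytically).

## Sequence similarity

`percentSimilarity()` computes
`100 * identities / length of the shorter sequence` from a Smith–Waterman
local alignment (BLOSUM62, gap open 11, gap extend 1 — classic protein
alignment defaults, via `Biostrings::pairwiseAlignment`), identities taken
from the single best-scoring alignment. The two inputs are ordered
canonically before aligning so the result is symmetric by construction.
The full unaligned length of the shorter input is the denominator, which
means a perfect substring match scores 100 regardless of the longer
sequence. Alignment scores are verified against an independent quadratic
Gotoh dynamic-programming oracle on short sequences in the test suite.
Exact agreement with BLAST HSP identity counts is not claimed.

## The synthetic-data generator

No experimental dataset is shipped, so the generator *defines* the study
conditions used by tests and the acceptance script. Its defaults emulate
the published dataset shape: 236 pairs from 171 unique sequences over 11
plastics with a 200:36 degradable:non-degradable imbalance, sequence
lengths 100–300.

The class signal has two components, both governed by one noise dial:

* **Per-plastic motifs.** Each plastic has a fixed 6-mer motif — a shared
  4-residue catalytic-style core (`WHSQ`, echoing the conserved
  serine-hydrolase signature of real polyesterases) plus a 2-residue
  plastic-specific flank. Degradable pairs carry 4 planted copies at
  non-overlapping positions.
* **Family composition bias.** Background residues of degradable
  sequences are drawn from a mixture of a fixed UniProt-like frequency
  table and a family-enriched table (`familyBias = 0.5`), the way a real
  hydrolase family shares compositional character beyond its catalytic
  signature. A lone 6-mer in a 200-residue sequence is simply too weak a
  signal once features are standardized; the family bias is what makes
  the degradable class *coherent*, which a prototype classifier requires.

`noiseRate` corrupts each planted motif residue with a background draw
and scales the family bias by `1 - noiseRate`, so `noiseRate = 1` leaves
the two classes statistically identical. Sequence reuse (236 pairs from
171 sequences) happens within a class: a simulated enzyme either belongs
to the degrader family or it does not. Allowing a sequence to be
degradable for one plastic and non-degradable for another would plant the
family signal in nominal negatives and put a hard ceiling under every
accuracy contract; real datasets do contain such enzymes, which is a
recognized limit of this generator.

These defaults were chosen once, to satisfy the design contract that the
clean-signal condition (`noiseRate = 0`) is clearly learnable by **both**
heads (test accuracy at least 0.95), and are exercised by the acceptance
suite at exactly that contract. What passing these tests shows is that
the pipeline machinery — featurization, ensembles, ranking, blending —
is correct and well-calibrated on separable data; it does *not* show that
real enzyme/plastic data are this separable, and published accuracies on
real data (roughly 0.78–0.87 unfiltered) should not be compared with the
synthetic numbers.

The candidate-pool generator (`generateCandidatePool()`) produces
unlabeled pools in which a hidden fraction of sequences carries the
motif/family signal; the truth manifest is written separately and used
only for evaluation.

## Numerical choices and degenerate inputs

* Round-half-up (not banker's rounding) wherever published tables are
  reproduced: test-set sizes and the printed concentration convention.
* Probability clamping to [0, 1] after head prediction guards against
  floating-point excursions from `nnet`.
* Sequences shorter than the 9-residue flexibility window use a single
  window over all available positions; sequences shorter than 3 residues
  fall back to single-residue counts in the surrogate embedder.
* Empty filtered sets, empty common top lists and zero-denominator
  metrics are reported (with warnings/flags), never raised as errors,
  because grid evaluation legitimately produces them.
* Ensemble determinism is exact: retraining with the same data, seed and
  config reproduces predictions to 1e-12 or better.

## Problem sizes

The test suite and the acceptance script run the full pipeline at the
published dataset shape (236 pairs, 25 heads, 5 seeds) and the blending
assessment on a 2,060-pair pool (2,000 candidates + 60 tagged); the
published pool arithmetic (40,913 pairs) is reproduced with short
sequences where only counts and concentrations matter. These sizes were
chosen as the smallest at which every contract of the design is
exercised at full ensemble width.

## Known limitations

* The surrogate embedder captures k-mer composition, not context; real
  pLM embeddings attach via `plmEmbedder()` but are not evaluated here.
* The 41-descriptor set is a documented stand-in, not a reproduction of
  any particular published feature table.
* The generator's within-class sequence reuse and single degrader family
  are simplifications; per-plastic specificity of real enzymes is much
  richer than one flank residue pair.
* Blending factors on synthetic pools depend on how many true positives
  the pool contains and are not comparable in magnitude to published
  factors on prescreened homolog pools.
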