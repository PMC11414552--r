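# plastizyme

Ensemble screening of plastic-degrading enzyme candidates, with per-pair
confidence and uncertainty estimation.

## The problem

Characterized plastic-degrading enzymes are scarce — curated literature
collections hold a few hundred enzyme/plastic pairs with reliable
degradable / non-degradable calls — while homology searches return tens of
thousands of uncharacterized candidates. Testing candidates at the bench is
expensive, so the useful computational output is not a bare classification
but a short, *stable*, *high-confidence* ranked list of enzyme/plastic
pairs worth experimental follow-up.

`plastizyme` implements that screening pipeline for 11 plastic substrate
types (PET, PU, PCL, PLA, PES, PEF, PE, PHB, PHV, PBS, PBSA):

* **Encoding.** Each enzyme/plastic pair becomes an 82-length feature
  vector: a 30-length sequence embedding (deterministic surrogate included;
  real protein-language-model encoders attach via an adapter contract),
  41 biophysical descriptors, and an 11-bit one-hot plastic type.
* **Classification.** Binary heads — a multilayer perceptron
  (via `nnet`) or a prototypical-network head (class-mean prototypes,
  softmax over negative squared distances).
* **Confidence and uncertainty.** An ensemble of N = 25 seeded heads.
  For per-head degradable probabilities `f_i(x)`:

      confidence(x)  = (1/N) Σ_i max(f_i(x), 1 − f_i(x))
      uncertainty(x) = population SD of those per-head maxima

* **Ranking and stability.** Pairs are ranked by the rank-of-sum-of-ranks
  statistic `R(R(confidence) + R(1/uncertainty))` (ascending average-tie
  ranks; larger = better), the model is rerun over 5 seeds with majority
  voting, and the top-`p` lists common to all runs form the stable top
  list (`k = floor(p·n)`).
* **Blending assessment.** Known degradable pairs are masked ("tagged")
  and hidden in an unlabeled candidate pool; enrichment of the top list is
  the concentration factor `[conc]_final / [conc]_init`, with a
  printed-rounding convention available for reproducing hand-rounded
  report tables.
* **Similarity.** Smith–Waterman percent similarity
  (`100 · identities / shorter length`, BLOSUM62, gap open 11 / extend 1)
  between candidate lists and reference enzymes.
* **Synthetic data.** A generator of experimental-style datasets (236
  pairs from 171 sequences, 200:36 imbalance) and candidate pools with a
  planted, noise-dialable motif + family-composition signal, so every
  stage is testable offline.

## Worked example

```r
library(plastizyme)

ps <- generateExperimentalLike(syntheticSpec(seed = 7))
ps
#> PairSet with 236 enzyme/plastic pairs (171 unique sequences, 11 plastic types)
#>   degradable: 200  non-degradable: 36  unlabeled: 0  tagged: 0

sp <- splitTrainTest(ps, 0.3, seed = 1)          # 165 train / 71 test
model <- trainEnsemble(sp$train, "prototype", n = 25, baseSeed = 1)
model
#> EnsembleModel: 25 prototype heads, base seed 1, embedder surrogate-kmer3-s1, features 'all'

preds <- ensemblePredict(model, sp$test)
head(preds[order(-preds$confidence), ], 3)
#>      pairId plastic  meanProb predictedClass confidence uncertainty
#> 56 pair0187     PHB 0.8994639              1  0.8994639  0.01219894
#> 29 pair0103     PHB 0.8641035              1  0.8641035  0.01397298
#> 55 pair0182     PCL 0.8466306              1  0.8466306  0.01411146

computeMetrics(preds$predictedClass, pairLabels(sp$test)[preds$pairId])
#> MetricsReport: n=71 TP=60 FP=0 TN=11 FN=0
#>   accuracy=1.000 precision=1.000 recall=1.000 F1=1.000

rk <- rankPredictions(preds)
top <- topFraction(rk, 0.20)                     # floor(0.20 × 71) = 14 pairs
mean(rk$predictedClass[match(top, rk$pairId)] == pairLabels(sp$test)[top])
#> [1] 1
```

The three most confident test pairs are degradable calls with uncertainty
near 0.01; on this clean synthetic dataset the prototype ensemble
classifies all 71 held-out pairs correctly, and the top-20% ranked list
(14 pairs) is perfect. Multi-seed workflows (`trainEvalWorkflow()`),
candidate mining with blending (`blendPool()`, `mineCandidates()`) and
similarity profiling (`similarityProfile()`) build on these pieces; a thin
command-line wrapper ships in `inst/scripts/plastizyme`.

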