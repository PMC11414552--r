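Package: plastizyme
Title: Ensemble Screening of Plastic-Degrading Enzyme Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts enzymatic degradation of plastics from protein sequence.
    Enzyme/plastic pairs are encoded as 82-length feature vectors (a 30-length
    sequence embedding, 41 biophysical descriptors, and an 11-bit one-hot
    plastic type), classified with multilayer-perceptron or prototype heads,
    and scored by a 25-head deep ensemble that yields per-pair confidence and
    uncertainty. Predictions are rank-aggregated, checked for stability across
    random seeds, and candidate enrichment is quantified with a blending
    assessment that hides known degraders inside an unlabeled candidate pool.
    Includes a synthetic motif-based data generator so every stage is testable
    without external sequence databases, and a Smith-Waterman percent
    similarity module for comparing candidate lists against reference enzymes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    nnet,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
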