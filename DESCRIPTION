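Package: lightattn
Title: Light-Attention Aggregation for Protein Subcellular Location Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein subcellular location from per-residue protein
    language model embeddings using a light-attention aggregation mechanism:
    two 1D convolutions over the length dimension produce per-channel
    attention coefficients and values, the coefficients are softmax-normalized
    over sequence length, and the attention-weighted values are concatenated
    with max-pooled values before a small feed-forward classifier. Includes
    ablation variants of the architecture, a mean-pool feed-forward baseline,
    nearest-neighbour annotation transfer under L1 embedding distance, a full
    training protocol (Adam, early stopping on validation loss, optional
    class-balanced loss), multi-class evaluation metrics (Q10, K-category
    Matthews correlation, macro F1, confusion matrices, distribution-matched
    resampling), and a synthetic embedding generator with position-localized
    class signal so the whole pipeline is testable on a CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
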