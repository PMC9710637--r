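# lightattn

Predicting protein subcellular location from per-residue protein language
model (pLM) embeddings with a **light-attention** aggregation architecture.

## The problem

A protein of `L` residues, embedded by a pLM, is a matrix
`x ∈ R^(d_in × L)` — one `d_in`-dimensional vector per residue, with `L`
ranging from tens to tens of thousands. Classifying a protein into one of
ten subcellular compartments (nucleus, cytoplasm, extracellular space,
mitochondrion, cell membrane, endoplasmic reticulum, plastid, Golgi
apparatus, lysosome/vacuole, peroxisome) requires collapsing this
variable-length matrix into a fixed-size representation. Mean pooling — the
standard baseline — averages over length and thereby dilutes short,
position-specific sorting signals (N-terminal targeting peptides,
C-terminal retention motifs) by a factor of roughly `motif_length / L`.
Light attention learns *where to look* instead.

## The model

Two 1D convolutions over the length dimension (filter size `s`, weights
`W^(e), W^(v) ∈ R^(s × d_in × d_out)`, zero padding so that positions
outside `[1, L]` contribute zero vectors) produce attention coefficients
and values:

    e_ij = b_i + Σ_k Σ_l W^(e)_{l,k,i} · x_{k, j+l-⌈s/2⌉}        e, v ∈ R^(d_out × L)

The coefficients are softmax-normalized **over the length dimension**,
independently per feature channel:

    α_ij = exp(e_ij) / Σ_l exp(e_il)

and pooled with the values; the result is concatenated with the
per-channel maximum of `v` and classified by a small feed-forward network
`f` with a softmax output:

    x'_i = Σ_j α_ij · v_ij,      p(c | x) = softmax_c( f(x' ⊕ v^max) )

Each channel carries its own attention distribution, runtime is linear in
`L`, and the output is independent of sequence length. At the published
operating point (`s = 9`, `d_in = d_out = 1024`, 10 classes) the model has
18,942,314 trainable parameters (~19 million).

The package also implements the architecture's ablation variants
(`la_no_softmax`, `la_no_maxpool`, `attention_from_v`, `conv_adapool`,
`query_attention`), the mean-pool FNN baseline, embedding-based annotation
transfer (EAT; 1-nearest-neighbour under L1 distance), the training
protocol (Adam, early stopping on validation loss, optional class-balanced
loss, optional decoupled weight decay, full seed control), ten-class
metrics (Q10, K-category Matthews correlation, macro-F1, confusion
matrices, multi-seed error estimates, distribution-matched resampling),
and a synthetic embedding generator whose class signal is a short motif at
a sequence terminus — so every component is testable on one CPU, without
GPUs or external datasets.

## Worked example

Generate a synthetic dataset (2000 proteins, 10 classes with a skewed
prevalence, lengths 30–1000, N-terminal motifs, reduced width
`d_in = 32`), train light attention and the mean-pool baseline, and
compare:

```r
library(lightattn)

sc <- synthetic_config(d_in = 32, n_proteins = 2000, seed = 11)
ds <- generate_dataset(sc)
sp <- dataset_splits(ds)   # stratified 70/15/15

la_fit <- la_train(
  la_model(la_config(variant = "la", s = 9, d_in = 32, d_out = 32,
                     hidden = 32, n_classes = 10)),
  sp$train, sp$validation,
  train_config(learning_rate = 1e-3, batch_size = 64, patience = 10,
               max_epochs = 30, seed = 5, weight_decay = 3e-1))

fnn_fit <- la_train(
  la_model(la_config(variant = "fnn", d_in = 32, hidden = 32,
                     n_classes = 10)),
  sp$train, sp$validation,
  train_config(learning_rate = 1e-3, batch_size = 64, patience = 20,
               max_epochs = 150, seed = 5, weight_decay = 3e-1))

truth <- sp$test$labels
eval_report(predict(la_fit$model, sp$test$embeddings), truth)
#> evaluation over 301 proteins
#>   Q10      54.8%
#>   MCC      0.432
#>   macro F1 0.236

100 * mean(predict(fnn_fit$model, sp$test$embeddings)$predicted_class == truth)
#> [1] 33.2                                  # mean-pool FNN test Q10
100 * max(table(truth)) / length(truth)
#> [1] 27.6                                  # majority baseline
oracle_bayes_accuracy(sc, n_mc = 1000, seed = 3)
#> [1] 100                                   # matched-filter (Bayes) oracle
```

The ordering — oracle ≫ light attention > mean pooling > majority — is the
package's core claim at desk scale: attention recovers the localized motif
that pooling dilutes. The trained model's attention confirms it looks at
the right place: the mean attention mass on the 9-residue motif window of
held-out proteins is 0.044, against a uniform expectation of 0.029.

```r
mean(vapply(sp$test$embeddings,
            function(x) attention_mass(la_fit$model, x, 1:9), 0))
#> [1] 0.044
```

Real data flows through the same interfaces: `parse_location_fasta()`
reads DeepLoc-dialect annotated FASTA (`>accession Class-Flag [test]`),
`read_embeddings()`/`write_embeddings()` handle keyed per-protein
embedding containers, and `cmd_train()`/`cmd_predict()`/`cmd_evaluate()`
(or the `inst/cli/lightattn.R` script with subcommands `simulate`,
`train`, `predict`, `evaluate`, `eat`) bind them into the full workflow.

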