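# Independent naive-loop implementations of the aggregation math, used as
# oracles against the vectorized code paths. Kept deliberately dumb: direct
# index-by-index translation of the definitions.

# Centered cross-correlation with zero padding, as a triple loop.
naive_conv <- function(x, W, b) {
  # W: s x d_in x d_out tensor
  s <- dim(W)[1]; d_in <- dim(W)[2]; d_out <- dim(W)[3]
  L <- ncol(x)
  p <- s %/% 2
  out <- matrix(0, d_out, L)
  for (i in seq_len(d_out)) {
    for (j in seq_len(L)) {
      acc <- b[i]
      for (l in seq_len(s)) {
        jj <- j + l - 1 - p
        if (jj >= 1 && jj <= L) {
          for (k in seq_len(d_in)) acc <- acc + W[l, k, i] * x[k, jj]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Per-row softmax as an explicit loop.
naive_softmax_rows <- function(e) {
  a <- e
  for (i in seq_len(nrow(e))) a[i, ] <- exp(e[i, ]) / sum(exp(e[i, ]))
  a
}

# Attention pooling as an explicit double loop.
naive_attention_pool <- function(alpha, v) {
  out <- numeric(nrow(alpha))
  for (i in seq_len(nrow(alpha)))
    for (j in seq_len(ncol(alpha)))
      out[i] <- out[i] + alpha[i, j] * v[i, j]
  out
}

# Random conv weight tensor with matching bias.
random_conv_weights <- function(s, d_in, d_out) {
  list(W = array(rnorm(s * d_in * d_out), c(s, d_in, d_out)),
       b = rnorm(d_out))
}

# A tiny labeled embedding set: n proteins, two well-separated classes with a
# class-specific constant offset (linearly separable even after pooling).
tiny_separable_set <- function(n, d_in = 6, classes = c("Nucleus", "Cytoplasm"),
                               lengths = 4:12, offset = 3) {
  emb <- list(); lab <- character(n)
  for (i in seq_len(n)) {
    ci <- ((i - 1) %% length(classes)) + 1
    L <- sample(lengths, 1)
    x <- matrix(rnorm(d_in * L, sd = 0.3), d_in, L)
    x[ci, ] <- x[ci, ] + offset
    emb[[i]] <- x
    lab[i] <- classes[ci]
  }
  names(emb) <- sprintf("T%04d", seq_len(n))
  list(embeddings = emb, labels = setNames(lab, names(emb)))
}
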