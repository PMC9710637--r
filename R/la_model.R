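#' Light-attention model configuration
#'
#' Architecture hyperparameters for the light-attention (LA) classifier and
#' its ablation variants. The LA forward pass is: two 1D convolutions over the
#' length dimension of a per-residue embedding matrix `x` (d_in x L) produce
#' attention coefficients `e` and values `v` (both d_out x L); `e` is
#' softmax-normalized over length independently per feature channel to
#' attention weights `alpha`; the pooled representation `x' = sum_j
#' alpha[,j] * v[,j]` is concatenated with the per-channel maximum `v^max` and
#' passed through a two-layer feed-forward classifier to class probabilities.
#'
#' @param variant one of `"la"` (full architecture), `"la_no_softmax"`
#'   (`x'` replaced by the per-channel mean of the coefficients `e`),
#'   `"la_no_maxpool"` (classifier consumes `x'` only), `"attention_from_v"`
#'   (coefficients computed by a convolution over `v` instead of over `x`),
#'   `"conv_adapool"` (convolution stack with kernels 3/9/15, adaptive average
#'   pooling of the length dimension to 5 positions, then the classifier),
#'   `"query_attention"` (single-head attention with one learned query vector,
#'   model width `d_in`), or `"fnn"` (mean pooling over length followed by the
#'   classifier — the baseline).
#' @param s odd convolution filter size (default 9).
#' @param d_in input embedding width (rows of `x`).
#' @param d_out number of attention/value channels (default 1024).
#' @param hidden classifier hidden width (default 32).
#' @param n_classes number of output classes (default 10).
#' @param dropout dropout rate between the classifier layers, in [0, 1)
#'   (default 0.25; active during training only).
#' @return an object of class `la_config`.
#' @export
la_config <- function(variant = "la", s = 9L, d_in = 1024L, d_out = 1024L,
                      hidden = 32L, n_classes = 10L, dropout = 0.25) {
  variant <- match.arg(variant, c("la", "la_no_softmax", "la_no_maxpool",
                                  "attention_from_v", "conv_adapool",
                                  "query_attention", "fnn"))
  s <- as.integer(s); d_in <- as.integer(d_in); d_out <- as.integer(d_out)
  hidden <- as.integer(hidden); n_classes <- as.integer(n_classes)
  stopifnot(s >= 1L, s %% 2L == 1L, d_in >= 1L, d_out >= 1L, hidden >= 1L,
            n_classes >= 2L, dropout >= 0, dropout < 1)
  structure(list(variant = variant, s = s, d_in = d_in, d_out = d_out,
                 hidden = hidden, n_classes = n_classes, dropout = dropout),
            class = "la_config")
}

# Width of the classifier input for each variant.
classifier_input_width <- function(cfg) {
  switch(cfg$variant,
    la = , la_no_softmax = , attention_from_v = 2L * cfg$d_out,
    la_no_maxpool = cfg$d_out,
    conv_adapool = 15L * cfg$d_out,   # 3 kernel sizes x d_out channels x 5 positions
    query_attention = cfg$d_in,
    fnn = cfg$d_in
  )
}

# He-normal init for a weight matrix with given fan-in.
init_mat <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

# Initialize all trainable parameters for a config. Convolution weights are
# stored flattened as (s*d_in) x d_out matrices with row index k + (l-1)*d_in
# (embedding dim k fastest within tap l), matching the unfold layout.
# Attention-coefficient weights start at zero so every attention distribution
# is exactly uniform at initialization: the model begins as (convolved) mean
# pooling and must learn to deviate from it.
init_params <- function(cfg, seed) {
  set.seed(seed)
  p <- list()
  if (cfg$variant %in% c("la", "la_no_softmax", "la_no_maxpool", "attention_from_v")) {
    fi <- cfg$s * cfg$d_in
    p$W_e <- matrix(0, fi, cfg$d_out); p$b_e <- numeric(cfg$d_out)
    p$W_v <- init_mat(fi, cfg$d_out, fi); p$b_v <- numeric(cfg$d_out)
    if (cfg$variant == "attention_from_v") {
      # coefficient conv runs over v, so its fan-in is s*d_out
      fe <- cfg$s * cfg$d_out
      p$W_e <- matrix(0, fe, cfg$d_out)
    }
    if (cfg$variant == "la_no_softmax")
      # no softmax: e feeds the classifier directly, so it needs signal
      p$W_e <- init_mat(fi, cfg$d_out, fi)
  } else if (cfg$variant == "conv_adapool") {
    for (k in c(3L, 9L, 15L)) {
      fi <- k * cfg$d_in
      p[[paste0("W_k", k)]] <- init_mat(fi, cfg$d_out, fi)
      p[[paste0("b_k", k)]] <- numeric(cfg$d_out)
    }
  } else if (cfg$variant == "query_attention") {
    d <- cfg$d_in
    p$W_k <- init_mat(d, d, d); p$b_k <- numeric(d)
    p$W_q <- init_mat(d, d, d); p$b_q <- numeric(d)  # value projection
    p$q   <- numeric(d)  # zero query: attention starts uniform
  }
  ci <- classifier_input_width(cfg)
  p$W1 <- init_mat(cfg$hidden, ci, ci);          p$b1 <- numeric(cfg$hidden)
  p$W2 <- init_mat(cfg$n_classes, cfg$hidden, cfg$hidden)
  p$b2 <- numeric(cfg$n_classes)
  p
}

#' Construct a light-attention model
#'
#' Creates a model object with freshly initialized parameters. Parameters are
#' re-initialized from the training seed by [la_train()], so the constructor
#' seed only matters for untrained use.
#'
#' @param config an [la_config()].
#' @param vocab ordered class vocabulary; length must equal
#'   `config$n_classes`.
#' @param seed integer seed for weight initialization.
#' @return an object of class `la_model` with elements `config`, `params`,
#'   `vocab`.
#' @export
la_model <- function(config, vocab = class_vocabulary(config$n_classes), seed = 1L) {
  stopifnot(inherits(config, "la_config"), length(vocab) == config$n_classes)
  structure(list(config = config, params = init_params(config, seed),
                 vocab = vocab), class = "la_model")
}

#' @export
print.la_model <- function(x, ...) {
  cat(sprintf("light-attention model (variant '%s')\n", x$config$variant))
  cat(sprintf("  s=%d  d_in=%d  d_out=%d  hidden=%d  classes=%d\n",
              x$config$s, x$config$d_in, x$config$d_out, x$config$hidden,
              x$config$n_classes))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Total number of trainable scalars of a model or configuration: for the full
#' LA architecture, both convolutions with biases plus the two-layer
#' classifier.
#'
#' @param x an `la_model` or `la_config`.
#' @return integer-valued count.
#' @export
count_parameters <- function(x) {
  params <- if (inherits(x, "la_model")) x$params
            else if (inherits(x, "la_config")) init_params(x, seed = 1L)
            else stop("need an la_model or la_config")
  sum(vapply(params, length, 0L))
}

# --- convolution primitives -------------------------------------------------

# Unfold a d x L matrix into an (s*d) x L matrix of sliding windows with zero
# padding of floor(s/2) columns on each side: positions outside [1, L] are
# zero vectors. Row index k + (l-1)*d holds x[k, j + l - 1 - floor(s/2)].
unfold_same <- function(x, s) {
  d <- nrow(x); L <- ncol(x); p <- s %/% 2L
  if (s == 1L) return(x)
  xpad <- matrix(0, d, L + 2L * p)
  xpad[, (p + 1L):(p + L)] <- x
  U <- matrix(0, s * d, L)
  for (l in seq_len(s))
    U[((l - 1L) * d + 1L):(l * d), ] <- xpad[, l:(l + L - 1L), drop = FALSE]
  U
}

# Adjoint of unfold_same: scatter an (s*d) x L gradient back to d x L.
fold_same <- function(dU, s, d, L) {
  p <- s %/% 2L
  if (s == 1L) return(dU)
  dxpad <- matrix(0, d, L + 2L * p)
  for (l in seq_len(s)) {
    cols <- l:(l + L - 1L)
    dxpad[, cols] <- dxpad[, cols] + dU[((l - 1L) * d + 1L):(l * d), , drop = FALSE]
  }
  dxpad[, (p + 1L):(p + L), drop = FALSE]
}

# Accept conv weights as an s x d_in x d_out tensor or pre-flattened
# (s*d_in) x d_out matrix; return the flattened form.
flatten_conv_weights <- function(W, s, d_in, d_out) {
  if (length(dim(W)) == 3L) {
    stopifnot(dim(W)[1] == s, dim(W)[2] == d_in, dim(W)[3] == d_out)
    matrix(aperm(W, c(2L, 1L, 3L)), s * d_in, d_out)
  } else {
    W <- as.matrix(W)
    stopifnot(nrow(W) == s * d_in, ncol(W) == d_out)
    W
  }
}

#' Same-length 1D convolution over the length dimension
#'
#' Computes the coefficient (or value) matrix of the light-attention
#' architecture: a centered cross-correlation of the per-residue embedding
#' `x` with an `s x d_in x d_out` filter bank, zero-padded so the output has
#' the same number of columns `L` as the input. Columns outside `[1, L]` are
#' treated as zero vectors. Used identically for the attention coefficients
#' `e` (with `W^(e)`) and the values `v` (with `W^(v)`).
#'
#' @param x `d_in x L` embedding matrix.
#' @param W filter tensor `s x d_in x d_out` (or the equivalent flattened
#'   `(s*d_in) x d_out` matrix).
#' @param b length-`d_out` bias vector.
#' @return `d_out x L` matrix.
#' @export
conv_coefficients <- function(x, W, b) {
  stopifnot(is.matrix(x), all(is.finite(x)))
  dims <- dim(W)
  if (length(dims) == 3L) {
    if (dims[2] != nrow(x))
      stop(sprintf("d_in mismatch: x has %d rows, W expects %d",
                   nrow(x), dims[2]), call. = FALSE)
    s <- dims[1]; d_out <- dims[3]
    Wm <- flatten_conv_weights(W, s, nrow(x), d_out)
  } else {
    Wm <- as.matrix(W)
    if (nrow(Wm) %% nrow(x) != 0L)
      stop("d_in mismatch between x and flattened W", call. = FALSE)
    s <- nrow(Wm) %/% nrow(x); d_out <- ncol(Wm)
  }
  stopifnot(length(b) == d_out)
  crossprod(Wm, unfold_same(x, s)) + b
}

# Row-wise max; fast path via max.col.
row_max <- function(m) m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]

#' Softmax attention weights over the length dimension
#'
#' Normalizes coefficient rows to attention distributions: for each feature
#' channel `i` independently, `alpha[i, j] = exp(e[i, j]) / sum_l exp(e[i, l])`
#' over unmasked positions. Masked positions receive exactly 0 (they are
#' excluded from the normalization as if their logit were `-Inf`).
#'
#' @param e `d_out x L` coefficient matrix.
#' @param mask optional logical length-`L` vector, `TRUE` for real positions.
#' @return `d_out x L` matrix whose rows sum to 1 over unmasked positions.
#' @export
attention_weights <- function(e, mask = NULL) {
  stopifnot(is.matrix(e))
  if (!is.null(mask)) {
    stopifnot(length(mask) == ncol(e))
    if (!any(mask)) stop("all positions masked", call. = FALSE)
    e[, !mask] <- -Inf
  }
  ex <- exp(e - row_max(e))
  ex[is.na(ex)] <- 0  # exp(-Inf - -Inf) guards for fully masked-but-checked rows
  ex / rowSums(ex)
}

#' Attention-weighted pooling
#'
#' Collapses the length dimension by the per-channel weighted sum
#' `x'[i] = sum_j alpha[i, j] * v[i, j]`, yielding a fixed-size representation
#' independent of sequence length.
#'
#' @param alpha `d_out x L` attention weights.
#' @param v `d_out x L` value matrix.
#' @return length-`d_out` vector.
#' @export
attention_pool <- function(alpha, v) {
  if (!identical(dim(alpha), dim(v)))
    stop("shape mismatch between alpha and v", call. = FALSE)
  rowSums(alpha * v)
}

#' Per-channel maximum over unmasked positions
#'
#' @param v `d_out x L` value matrix.
#' @param mask optional logical length-`L` vector, `TRUE` for real positions.
#' @return length-`d_out` vector `v^max`.
#' @export
max_pool_values <- function(v, mask = NULL) {
  stopifnot(is.matrix(v))
  if (!is.null(mask)) {
    stopifnot(length(mask) == ncol(v))
    if (!any(mask)) stop("all positions masked", call. = FALSE)
    v <- v[, mask, drop = FALSE]
  }
  row_max(v)
}

# --- encoder forward/backward ----------------------------------------------

# Forward pass of the aggregation stage for one protein. Returns the
# classifier input h and (if keep_cache) everything backward needs.
encoder_forward <- function(params, cfg, x, keep_cache = FALSE, mask = NULL) {
  if (nrow(x) != cfg$d_in)
    stop(sprintf("d_in mismatch: embedding has %d rows, model expects %d",
                 nrow(x), cfg$d_in), call. = FALSE)
  L <- ncol(x)
  cache <- NULL
  if (cfg$variant %in% c("la", "la_no_softmax", "la_no_maxpool", "attention_from_v")) {
    U <- unfold_same(x, cfg$s)
    v <- crossprod(params$W_v, U) + params$b_v
    if (cfg$variant == "attention_from_v") {
      Uv <- unfold_same(v, cfg$s)
      e <- crossprod(params$W_e, Uv) + params$b_e
    } else {
      Uv <- NULL
      e <- crossprod(params$W_e, U) + params$b_e
    }
    if (cfg$variant == "la_no_softmax") {
      if (is.null(mask)) {
        xp <- rowMeans(e); alpha <- NULL
      } else {
        xp <- rowSums(e[, mask, drop = FALSE]) / sum(mask); alpha <- NULL
      }
    } else {
      alpha <- attention_weights(e, mask)
      xp <- attention_pool(alpha, v)
    }
    if (cfg$variant == "la_no_maxpool") {
      h <- xp; imax <- NULL
    } else {
      vm <- if (is.null(mask)) v else {
        vmm <- v; vmm[, !mask] <- -Inf; vmm
      }
      imax <- max.col(vm, ties.method = "first")
      h <- c(xp, vm[cbind(seq_len(nrow(vm)), imax)])
    }
    if (keep_cache)
      cache <- list(U = U, Uv = Uv, v = v, e = e, alpha = alpha, imax = imax, L = L)
  } else if (cfg$variant == "conv_adapool") {
    Us <- lapply(c(3L, 9L, 15L), function(k) unfold_same(x, k))
    names(Us) <- c("3", "9", "15")
    A <- do.call(rbind, lapply(c(3L, 9L, 15L), function(k)
      crossprod(params[[paste0("W_k", k)]], Us[[as.character(k)]]) +
        params[[paste0("b_k", k)]]))
    Z <- pmax(A, 0)
    segs <- adaptive_segments(L, 5L)
    P <- vapply(segs, function(cols) rowMeans(Z[, cols, drop = FALSE]),
                numeric(nrow(Z)))
    h <- as.vector(P)
    if (keep_cache) cache <- list(Us = Us, A = A, Z = Z, segs = segs, L = L)
  } else if (cfg$variant == "query_attention") {
    K <- params$W_k %*% x + params$b_k
    V <- params$W_q %*% x + params$b_q
    u <- as.vector(crossprod(K, params$q)) / sqrt(cfg$d_in)
    if (!is.null(mask)) u[!mask] <- -Inf
    a <- exp(u - max(u)); a <- a / sum(a)
    h <- as.vector(V %*% a)
    if (keep_cache) cache <- list(K = K, V = V, a = a, x = x, L = L)
  } else if (cfg$variant == "fnn") {
    h <- if (is.null(mask)) rowMeans(x) else rowMeans(x[, mask, drop = FALSE])
    if (keep_cache) cache <- list(L = if (is.null(mask)) L else sum(mask))
  }
  list(h = h, cache = cache)
}

# Split points of adaptive average pooling of L columns into n_out segments.
adaptive_segments <- function(L, n_out) {
  lapply(seq_len(n_out) - 1L, function(t) {
    (floor(t * L / n_out) + 1L):ceiling((t + 1L) * L / n_out)
  })
}

# Backward pass matching encoder_forward; returns gradients for the encoder
# parameters (named like params). dh is the gradient w.r.t. h.
encoder_backward <- function(dh, cache, params, cfg, x) {
  g <- list()
  if (cfg$variant %in% c("la", "la_no_softmax", "la_no_maxpool", "attention_from_v")) {
    d_out <- cfg$d_out
    dxp <- dh[seq_len(d_out)]
    dv <- matrix(0, d_out, cache$L)
    if (cfg$variant != "la_no_maxpool") {
      dvmax <- dh[(d_out + 1L):(2L * d_out)]
      dv[cbind(seq_len(d_out), cache$imax)] <- dvmax
    }
    if (cfg$variant == "la_no_softmax") {
      de <- matrix(dxp / cache$L, d_out, cache$L)
    } else {
      alpha <- cache$alpha
      dv <- dv + alpha * dxp
      dalpha <- cache$v * dxp
      de <- alpha * (dalpha - rowSums(alpha * dalpha))
    }
    g$b_e <- rowSums(de)
    if (cfg$variant == "attention_from_v") {
      g$W_e <- cache$Uv %*% t(de)
      dUv <- params$W_e %*% de
      dv <- dv + fold_same(dUv, cfg$s, d_out, cache$L)
    } else {
      g$W_e <- cache$U %*% t(de)
    }
    g$W_v <- cache$U %*% t(dv)
    g$b_v <- rowSums(dv)
  } else if (cfg$variant == "conv_adapool") {
    dP <- matrix(dh, 3L * cfg$d_out, 5L)
    dZ <- matrix(0, nrow(dP), cache$L)
    for (t in seq_along(cache$segs)) {
      cols <- cache$segs[[t]]
      dZ[, cols] <- dZ[, cols] + dP[, t] / length(cols)
    }
    dA <- dZ * (cache$A > 0)
    off <- 0L
    for (k in c(3L, 9L, 15L)) {
      rows <- (off + 1L):(off + cfg$d_out)
      dAk <- dA[rows, , drop = FALSE]
      g[[paste0("W_k", k)]] <- cache$Us[[as.character(k)]] %*% t(dAk)
      g[[paste0("b_k", k)]] <- rowSums(dAk)
      off <- off + cfg$d_out
    }
  } else if (cfg$variant == "query_attention") {
    a <- cache$a
    dV <- outer(dh, a)
    da <- as.vector(crossprod(cache$V, dh))
    du <- a * (da - sum(a * da))
    sc <- 1 / sqrt(cfg$d_in)
    g$q  <- as.vector(cache$K %*% du) * sc
    dK <- outer(params$q, du) * sc
    g$W_k <- dK %*% t(cache$x); g$b_k <- rowSums(dK)
    g$W_q <- dV %*% t(cache$x); g$b_q <- rowSums(dV)
  }
  g
}

# --- classifier -------------------------------------------------------------

# H: c_in x B matrix of encoder outputs. dropmask: hidden x B 0/1 matrix or
# NULL (inference). Inverted dropout keeps inference weight-free.
classifier_forward <- function(params, cfg, H, dropmask = NULL) {
  A1 <- params$W1 %*% H + params$b1
  Z <- pmax(A1, 0)
  if (!is.null(dropmask) && cfg$dropout > 0)
    Z <- Z * dropmask / (1 - cfg$dropout)
  logits <- params$W2 %*% Z + params$b2
  list(logits = logits, A1 = A1, Z = Z)
}

classifier_backward <- function(dlogits, fwd, params, cfg, H, dropmask = NULL) {
  g <- list(W2 = dlogits %*% t(fwd$Z), b2 = rowSums(dlogits))
  dZ <- crossprod(params$W2, dlogits)
  if (!is.null(dropmask) && cfg$dropout > 0)
    dZ <- dZ * dropmask / (1 - cfg$dropout)
  dA1 <- dZ * (fwd$A1 > 0)
  g$W1 <- dA1 %*% t(H); g$b1 <- rowSums(dA1)
  list(grads = g, dH = crossprod(params$W1, dA1))
}

# Column-wise softmax.
col_softmax <- function(logits) {
  ex <- exp(sweep(logits, 2L, apply(logits, 2L, max)))
  sweep(ex, 2L, colSums(ex), "/")
}

# --- public forward ---------------------------------------------------------

#' Forward pass: per-residue embedding to class probabilities
#'
#' Runs the full architecture (aggregation stage of the configured variant,
#' then the classifier, then a softmax over classes) in inference mode:
#' dropout disabled, argmax ties broken by lowest class index.
#'
#' @param x a `d_in x L` embedding matrix, or a (optionally named) list of
#'   them.
#' @param model an [la_model()]; alternatively pass `params` and `config`.
#' @param params,config low-level alternative to `model`.
#' @param mask optional logical mask (single-matrix input only): `TRUE` marks
#'   real residue positions, `FALSE` marks padding to be excluded from the
#'   attention normalization and max pooling.
#' @return for a single matrix: a list with `probabilities` (named, sums
#'   to 1) and `predicted_class`; for a list input: a data.frame with `id`,
#'   `predicted_class`, and one probability column per class.
#' @export
la_forward <- function(x, model = NULL, params = NULL, config = NULL, mask = NULL) {
  if (!is.null(model)) {
    stopifnot(inherits(model, "la_model"))
    params <- model$params; config <- model$config
    vocab <- model$vocab
  } else {
    stopifnot(!is.null(params), inherits(config, "la_config"))
    vocab <- class_vocabulary(config$n_classes)
  }
  if (is.matrix(x)) {
    h <- encoder_forward(params, config, x, mask = mask)$h
    logits <- classifier_forward(params, config, matrix(h, ncol = 1L))$logits
    pr <- drop(col_softmax(logits))
    names(pr) <- vocab
    return(list(probabilities = pr, predicted_class = vocab[which.max(pr)]))
  }
  stopifnot(is.list(x))
  H <- vapply(x, function(xi) encoder_forward(params, config, xi)$h,
              numeric(classifier_input_width(config)))
  if (classifier_input_width(config) == 1L) H <- matrix(H, nrow = 1L)
  probs <- t(col_softmax(classifier_forward(params, config, H)$logits))
  colnames(probs) <- vocab
  ids <- if (!is.null(names(x))) names(x) else sprintf("seq%04d", seq_along(x))
  out <- data.frame(id = ids,
                    predicted_class = vocab[max.col(probs, ties.method = "first")],
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(probs, check.names = FALSE))
}

#' Forward pass over a padded batch
#'
#' Consumes the padded representation produced by [make_batches()]: a
#' `d_in x L_max x B` array whose padding columns are zero, plus a `B x L_max`
#' logical mask of real positions. Padding columns take part in the
#' convolution exactly like the zero vectors of the single-sequence
#' definition, and are excluded from the softmax normalization and the max
#' pooling via the mask, so each protein's probabilities equal its unbatched
#' forward pass.
#'
#' @param xbatch `d_in x L_max x B` numeric array.
#' @param masks `B x L_max` logical matrix, `TRUE` for real positions.
#' @param model an [la_model()].
#' @return `B x n_classes` probability matrix.
#' @export
la_forward_padded <- function(xbatch, masks, model) {
  stopifnot(inherits(model, "la_model"), length(dim(xbatch)) == 3L,
            nrow(masks) == dim(xbatch)[3])
  cfg <- model$config
  H <- vapply(seq_len(dim(xbatch)[3]), function(b) {
    encoder_forward(model$params, cfg,
                    matrix(xbatch[, , b], nrow = dim(xbatch)[1L]),
                    mask = masks[b, ])$h
  }, numeric(classifier_input_width(cfg)))
  if (classifier_input_width(cfg) == 1L) H <- matrix(H, nrow = 1L)
  probs <- t(col_softmax(classifier_forward(model$params, cfg, H)$logits))
  colnames(probs) <- model$vocab
  probs
}

#' Build a forward function for an architecture variant
#'
#' @param config an [la_config()]; the `variant` field selects the
#'   architecture.
#' @return a function `(x, params)` returning the class-probability vector for
#'   one `d_in x L` embedding matrix.
#' @export
build_variant <- function(config) {
  stopifnot(inherits(config, "la_config"))
  force(config)
  function(x, params) {
    la_forward(x, params = params, config = config)$probabilities
  }
}

#' Predict locations for a set of proteins
#'
#' @param object a trained [la_model()].
#' @param newdata named list of `d_in x L` embedding matrices.
#' @param ... unused.
#' @return data.frame: `id`, `predicted_class`, one probability column per
#'   class in vocabulary order.
#' @export
predict.la_model <- function(object, newdata, ...) {
  la_forward(newdata, model = object)
}

#' Mean attention mass over a window of positions
#'
#' Diagnostic for where the attention looks: the attention weights
#' `alpha` are averaged over feature channels and summed over `window`
#' positions. Under uniform attention the expected value is
#' `length(window) / L`.
#'
#' @param model a trained `la_model` (variant `"la"` or
#'   `"attention_from_v"`).
#' @param x `d_in x L` embedding matrix.
#' @param window integer vector of positions (e.g. `1:9` for an N-terminal
#'   window).
#' @return scalar attention mass in [0, 1].
#' @export
attention_mass <- function(model, x, window) {
  cfg <- model$config
  stopifnot(cfg$variant %in% c("la", "attention_from_v"))
  ef <- encoder_forward(model$params, cfg, x, keep_cache = TRUE)
  alpha <- ef$cache$alpha
  stopifnot(all(window >= 1L), all(window <= ncol(alpha)))
  mean(colSums(t(alpha[, window, drop = FALSE])))
}
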