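#' Training configuration
#'
#' Optimization schedule defaults: Adam with learning rate 5e-5, batch size
#' 150, early stopping after 80 epochs without improvement in validation
#' loss. Early stopping is driven by validation loss; validation Q10 is logged
#' for inspection only.
#'
#' @param learning_rate Adam step size (> 0).
#' @param batch_size minibatch size (>= 1).
#' @param patience epochs without validation-loss improvement before stopping.
#' @param max_epochs hard cap on epochs (early stopping is the operative
#'   criterion).
#' @param seed integer; governs weight initialization, shuffling and dropout.
#' @param class_weighting if `TRUE`, weight the cross-entropy by
#'   inverse class frequency ([class_weights()]).
#' @param weight_decay decoupled (AdamW-style) weight decay applied to
#'   weight matrices, not biases; 0 (the default) reproduces plain Adam.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-5, batch_size = 150L,
                         patience = 80L, max_epochs = 1000L, seed = 42L,
                         class_weighting = FALSE, weight_decay = 0) {
  stopifnot(learning_rate > 0, batch_size >= 1L, patience >= 1L,
            max_epochs >= 1L, weight_decay >= 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed),
                 class_weighting = isTRUE(class_weighting),
                 weight_decay = weight_decay),
            class = "train_config")
}

#' Pad a dataset into shuffled minibatches with masks
#'
#' Each batch is padded to its longest member with zero columns; a logical
#' mask marks real residue positions. Shuffling is deterministic given
#' `seed`; pass `NULL` to keep input order.
#'
#' @param embeddings named list of `d_in x L` matrices.
#' @param labels vector of class labels aligned with `embeddings` (or named).
#' @param batch_size number of proteins per batch.
#' @param seed integer or `NULL`.
#' @return list of batches, each a list with `x` (`d_in x L_max x B` array,
#'   zero-padded), `mask` (`B x L_max` logical), `ids`, `labels`, `lengths`.
#' @export
make_batches <- function(embeddings, labels, batch_size, seed = NULL) {
  stopifnot(length(embeddings) > 0L, length(labels) == length(embeddings))
  if (!is.null(names(labels)) && !is.null(names(embeddings)))
    labels <- labels[names(embeddings)]
  n <- length(embeddings)
  ord <- seq_len(n)
  if (!is.null(seed)) {
    set.seed(seed)
    ord <- sample.int(n)
  }
  starts <- seq(1L, n, by = batch_size)
  lapply(starts, function(s0) {
    idx <- ord[s0:min(s0 + batch_size - 1L, n)]
    lens <- vapply(embeddings[idx], ncol, 0L)
    Lmax <- max(lens)
    d_in <- nrow(embeddings[[idx[1L]]])
    B <- length(idx)
    x <- array(0, dim = c(d_in, Lmax, B))
    mask <- matrix(FALSE, B, Lmax)
    for (b in seq_len(B)) {
      x[, seq_len(lens[b]), b] <- embeddings[[idx[b]]]
      mask[b, seq_len(lens[b])] <- TRUE
    }
    list(x = x, mask = mask, ids = names(embeddings)[idx],
         labels = unname(labels[idx]), lengths = unname(lens))
  })
}

#' Inverse-frequency class weights
#'
#' Balanced-loss weights `w_c = N / (K * N_c)` with `N` the number of
#' samples, `K` the vocabulary size and `N_c` the class count (clamped to 1
#' for absent classes). Equal counts give all weights 1.
#'
#' @param labels vector of class labels.
#' @param vocab class vocabulary (defines `K` and the output order).
#' @return named numeric vector of length `K`.
#' @export
class_weights <- function(labels, vocab = class_vocabulary()) {
  if (length(labels) == 0L) stop("empty label list", call. = FALSE)
  bad <- setdiff(unique(labels), vocab)
  if (length(bad) > 0L)
    stop("label(s) outside vocabulary: ", paste(bad, collapse = ", "),
         call. = FALSE)
  counts <- table(factor(labels, levels = vocab))
  n_c <- pmax(as.numeric(counts), 1)
  stats::setNames(length(labels) / (length(vocab) * n_c), vocab)
}

# Weighted cross-entropy over a B-column logits matrix; y integer classes.
# Returns the loss and the logits gradient (normalized by total weight).
softmax_ce <- function(logits, y, w) {
  probs <- col_softmax(logits)
  B <- ncol(logits)
  py <- probs[cbind(y, seq_len(B))]
  wy <- w[y]
  loss <- sum(wy * -log(pmax(py, 1e-12))) / sum(wy)
  dlogits <- probs
  dlogits[cbind(y, seq_len(B))] <- dlogits[cbind(y, seq_len(B))] - 1
  dlogits <- sweep(dlogits, 2L, wy / sum(wy), "*")
  list(loss = loss, dlogits = dlogits, probs = probs)
}

# One Adam step over flat named lists of parameters/gradients. Decoupled
# weight decay (AdamW) acts on weight matrices only, never biases.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    step <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (weight_decay > 0 && !startsWith(nm, "b"))
      step <- step + weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * step
  }
  list(params = params, state = state)
}

# Forward+backward over one batch; returns loss and summed gradients.
batch_grad <- function(params, cfg, xs, y, w, dropmasks) {
  B <- length(xs)
  ci <- classifier_input_width(cfg)
  H <- matrix(0, ci, B)
  caches <- vector("list", B)
  for (b in seq_len(B)) {
    ef <- encoder_forward(params, cfg, xs[[b]], keep_cache = TRUE)
    H[, b] <- ef$h
    caches[[b]] <- ef$cache
  }
  fwd <- classifier_forward(params, cfg, H, dropmasks)
  ce <- softmax_ce(fwd$logits, y, w)
  cb <- classifier_backward(ce$dlogits, fwd, params, cfg, H, dropmasks)
  grads <- cb$grads
  for (b in seq_len(B)) {
    ge <- encoder_backward(cb$dH[, b], caches[[b]], params, cfg, xs[[b]])
    for (nm in names(ge))
      grads[[nm]] <- if (is.null(grads[[nm]])) ge[[nm]] else grads[[nm]] + ge[[nm]]
  }
  list(loss = ce$loss, grads = grads)
}

# Mean (optionally class-weighted) cross-entropy and Q10 on a labeled set,
# dropout disabled.
evaluate_loss <- function(params, cfg, embeddings, y, w, vocab) {
  ci <- classifier_input_width(cfg)
  H <- vapply(embeddings, function(xi) encoder_forward(params, cfg, xi)$h,
              numeric(ci))
  if (ci == 1L) H <- matrix(H, nrow = 1L)
  fwd <- classifier_forward(params, cfg, H)
  ce <- softmax_ce(fwd$logits, y, w)
  pred <- max.col(t(fwd$logits), ties.method = "first")
  list(loss = ce$loss, q10 = 100 * mean(pred == y))
}

#' Train a model with Adam and early stopping
#'
#' Optimizes the cross-entropy objective (optionally class-weighted) on the
#' training set; after each epoch the validation loss is evaluated with
#' stochastic layers disabled. Training stops when the validation loss has
#' not improved for `patience` consecutive epochs (or at `max_epochs`), and
#' the parameters of the best-validation-loss epoch are restored. Fully
#' reproducible given `config$seed`, which is split internally into a
#' weight-initialization stream and per-epoch shuffling/dropout streams.
#'
#' @param model an [la_model()] defining the architecture and vocabulary;
#'   its parameters are re-initialized from the seed.
#' @param train_set,validation_set lists with elements `embeddings` (named
#'   list of `d_in x L` matrices) and `labels` (character vector aligned with
#'   the embeddings).
#' @param config a [train_config()].
#' @return list of class `la_training`: `model` (trained), `history`
#'   (data.frame epoch/train_loss/val_loss/val_q10), `best_epoch`,
#'   `stopped_epoch`.
#' @export
la_train <- function(model, train_set, validation_set, config = train_config()) {
  stopifnot(inherits(model, "la_model"), inherits(config, "train_config"))
  cfg <- model$config; vocab <- model$vocab
  tr_emb <- train_set$embeddings; va_emb <- validation_set$embeddings
  tr_lab <- train_set$labels;     va_lab <- validation_set$labels
  stopifnot(length(tr_emb) > 0L, length(va_emb) > 0L,
            length(tr_lab) == length(tr_emb), length(va_lab) == length(va_emb))
  overlap <- intersect(names(tr_emb), names(va_emb))
  if (length(overlap) > 0L)
    warning("train and validation sets share ", length(overlap), " id(s)",
            call. = FALSE)
  y_tr <- match(tr_lab, vocab); y_va <- match(va_lab, vocab)
  if (anyNA(y_tr) || anyNA(y_va))
    stop("labels outside the model vocabulary", call. = FALSE)
  w <- if (config$class_weighting) class_weights(tr_lab, vocab)
       else stats::setNames(rep(1, length(vocab)), vocab)

  set.seed(config$seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, 2L)
  params <- init_params(cfg, seed = subseeds[1L])
  state <- list(t = 0L,
                m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))

  best <- list(loss = Inf, params = params, epoch = 0L)
  bad_epochs <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_q10 = numeric())
  n_hidden <- cfg$hidden
  for (epoch in seq_len(config$max_epochs)) {
    epoch_seed <- (subseeds[2L] + epoch) %% (.Machine$integer.max - 1L) + 1L
    batches <- make_batches(tr_emb, tr_lab, config$batch_size, seed = epoch_seed)
    ep_loss <- 0; ep_n <- 0L
    for (bi in seq_along(batches)) {
      bt <- batches[[bi]]
      B <- length(bt$ids)
      xs <- lapply(seq_len(B), function(b)
        matrix(bt$x[, seq_len(bt$lengths[b]), b], nrow = dim(bt$x)[1L]))
      dm <- if (cfg$dropout > 0)
        matrix(stats::runif(n_hidden * B) >= cfg$dropout, n_hidden, B) * 1
      else NULL
      bg <- batch_grad(params, cfg, xs, match(bt$labels, vocab), w, dm)
      if (!is.finite(bg$loss))
        stop(sprintf("non-finite training loss at epoch %d, batch %d",
                     epoch, bi), call. = FALSE)
      upd <- adam_step(params, bg$grads, state, config$learning_rate,
                       weight_decay = config$weight_decay)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + bg$loss * B; ep_n <- ep_n + B
    }
    ev <- evaluate_loss(params, cfg, va_emb, y_va, w, vocab)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / ep_n,
                                   val_loss = ev$loss, val_q10 = ev$q10))
    if (ev$loss < best$loss) {
      best <- list(loss = ev$loss, params = params, epoch = epoch)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= config$patience) break
    }
  }
  model$params <- best$params
  structure(list(model = model, history = hist, best_epoch = best$epoch,
                 stopped_epoch = nrow(hist), best_val_loss = best$loss),
            class = "la_training")
}

#' @export
print.la_training <- function(x, ...) {
  cat(sprintf("training run: %d epoch(s), best epoch %d (val loss %.4f, val Q10 %.1f)\n",
              x$stopped_epoch, x$best_epoch, x$best_val_loss,
              x$history$val_q10[x$best_epoch]))
  invisible(x)
}
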