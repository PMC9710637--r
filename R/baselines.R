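#' Mean-pool a per-residue embedding to a per-protein vector
#'
#' Averages the `d_in x L` embedding over the length dimension, the
#' representation used by the FNN and annotation-transfer baselines.
#'
#' @param x `d_in x L` embedding matrix.
#' @return length-`d_in` numeric vector.
#' @export
mean_pool <- function(x) {
  stopifnot(is.matrix(x), ncol(x) >= 1L)
  rowMeans(x)
}

#' Two-layer feed-forward classifier on a pooled embedding
#'
#' The mean-pool baseline head: two affine maps with a ReLU between, then a
#' softmax over classes. Equivalent to `la_forward` with `variant = "fnn"`
#' when the pooled vector came from [mean_pool()].
#'
#' @param p length-`d_in` pooled embedding vector.
#' @param params parameter list with `W1` (`hidden x d_in`), `b1`,
#'   `W2` (`n_classes x hidden`), `b2` — e.g. `la_model(...)$params` of an
#'   `"fnn"` model.
#' @param vocab optional class vocabulary used to name the output.
#' @return list with `probabilities` (sums to 1) and `predicted_class`
#'   (index if `vocab` is `NULL`, label otherwise).
#' @export
fnn_forward <- function(p, params, vocab = NULL) {
  if (length(p) != ncol(params$W1))
    stop(sprintf("width mismatch: input has %d entries, classifier expects %d",
                 length(p), ncol(params$W1)), call. = FALSE)
  logits <- params$W2 %*% pmax(params$W1 %*% p + params$b1, 0) + params$b2
  pr <- drop(col_softmax(logits))
  k <- which.max(pr)
  if (!is.null(vocab)) {
    names(pr) <- vocab
    k <- vocab[k]
  }
  list(probabilities = pr, predicted_class = k)
}

#' Nearest-neighbour annotation transfer under L1 distance
#'
#' Transfers the location label of the closest reference protein in pooled
#' embedding space (L1/Manhattan distance); the standard embedding-based
#' annotation transfer (EAT) baseline with `k = 1`. For `k > 1` the labels
#' of the `k` nearest references vote, ties broken by smallest summed
#' distance. Exhaustive exact scan; ties in distance broken by first
#' occurrence in reference order.
#'
#' @param query length-`d_in` pooled embedding, or a matrix/list of queries
#'   (one per row of the returned data.frame).
#' @param reference matrix of reference embeddings, one per row (or named
#'   list of vectors).
#' @param labels class labels aligned with the reference rows.
#' @param k number of neighbours (default 1).
#' @return for a single query: list with `label`, `nn_id`, `distance`;
#'   for multiple queries: data.frame `query_id`, `transferred_class`,
#'   `nn_id`, `l1_distance`.
#' @export
eat_predict <- function(query, reference, labels, k = 1L) {
  if (is.list(reference)) reference <- do.call(rbind, reference)
  stopifnot(is.matrix(reference), nrow(reference) >= 1L,
            length(labels) == nrow(reference), k >= 1L)
  ref_ids <- if (!is.null(rownames(reference))) rownames(reference)
             else as.character(seq_len(nrow(reference)))
  one <- function(q) {
    if (length(q) != ncol(reference))
      stop(sprintf("d_in mismatch: query has %d entries, reference has %d",
                   length(q), ncol(reference)), call. = FALSE)
    d <- rowSums(abs(sweep(reference, 2L, q)))
    if (k == 1L) {
      j <- which.min(d)
      return(list(label = labels[j], nn_id = ref_ids[j], distance = d[j]))
    }
    nn <- order(d)[seq_len(min(k, length(d)))]
    votes <- tapply(rep(1L, length(nn)), labels[nn], sum)
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      sums <- vapply(top, function(cl) sum(d[nn][labels[nn] == cl]), 0)
      top <- top[which.min(sums)]
    }
    j <- nn[labels[nn] == top][1L]
    list(label = top, nn_id = ref_ids[j], distance = d[nn[1L]])
  }
  if (is.numeric(query) && is.null(dim(query)))
    return(one(query))
  if (is.list(query)) query <- do.call(rbind, query)
  res <- apply(query, 1L, one)
  data.frame(
    query_id = if (!is.null(rownames(query))) rownames(query)
               else as.character(seq_len(nrow(query))),
    transferred_class = vapply(res, `[[`, "", "label"),
    nn_id = vapply(res, `[[`, "", "nn_id"),
    l1_distance = vapply(res, `[[`, 0, "distance"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
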