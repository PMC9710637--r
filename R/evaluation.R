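#' Confusion matrix of predicted vs true location classes
#'
#' @param predicted character vector of predicted classes (or the data.frame
#'   returned by [predict.la_model()], whose `predicted_class` column is
#'   used).
#' @param truth character vector of true classes, aligned with `predicted`
#'   (matched by id when both carry names/ids).
#' @param class_order ordered class vocabulary.
#' @return `K x K` integer matrix of class `confusion_matrix`; rows are true
#'   classes, columns predicted classes.
#' @export
confusion <- function(predicted, truth, class_order = class_vocabulary()) {
  if (is.data.frame(predicted)) {
    if (!is.null(names(truth))) {
      missing_ids <- setdiff(predicted$id, names(truth))
      if (length(missing_ids) > 0L)
        stop("prediction id(s) without truth labels: ",
             paste(utils::head(missing_ids, 10L), collapse = ", "), call. = FALSE)
      truth <- truth[predicted$id]
    }
    predicted <- predicted$predicted_class
  }
  stopifnot(length(predicted) == length(truth), length(predicted) > 0L)
  bad <- setdiff(unique(c(predicted, truth)), class_order)
  if (length(bad) > 0L)
    stop("label(s) outside class_order: ", paste(bad, collapse = ", "),
         call. = FALSE)
  cm <- table(factor(truth, levels = class_order),
              factor(predicted, levels = class_order))
  cm <- unclass(cm)
  dimnames(cm) <- list(true = class_order, predicted = class_order)
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Row-normalized view of a confusion matrix, sorted by class prevalence
#'
#' Rows (true classes) are divided by their totals and the classes reordered
#' most-common-first, the usual display convention.
#'
#' @param cm a [confusion()] matrix.
#' @return numeric matrix of row fractions.
#' @export
confusion_display <- function(cm) {
  ord <- order(rowSums(cm), decreasing = TRUE)
  m <- cm[ord, ord, drop = FALSE]
  rs <- rowSums(m)
  sweep(m, 1L, pmax(rs, 1L), "/")
}

#' Overall 10-class accuracy (Q10)
#'
#' Percentage of correctly predicted proteins: `100 * trace / total`. The
#' majority baseline — predicting every protein into the most common class —
#' scores `100 * max(row sums) / total` on the same matrix.
#'
#' @param cm a [confusion()] matrix.
#' @return percentage in [0, 100].
#' @export
q10 <- function(cm) {
  total <- sum(cm)
  if (total == 0L) stop("empty confusion matrix", call. = FALSE)
  100 * sum(diag(cm)) / total
}

#' Per-class accuracy (confusion-matrix diagonal over row sums)
#' @param cm a [confusion()] matrix.
#' @return named vector in [0, 1]; `NaN` for classes with no true members.
#' @export
per_class_accuracy <- function(cm) {
  stats::setNames(diag(cm) / rowSums(cm), rownames(cm))
}

#' Q10 of the majority baseline
#' @param cm a [confusion()] matrix (only its row sums — the true class
#'   distribution — are used).
#' @return percentage in [0, 100].
#' @export
majority_q10 <- function(cm) {
  total <- sum(cm)
  if (total == 0L) stop("empty confusion matrix", call. = FALSE)
  100 * max(rowSums(cm)) / total
}

#' K-category Matthews correlation coefficient
#'
#' The multi-class generalization of the MCC computed from a confusion
#' matrix (Gorodkin's R_K): with `c` the number correct, `s` the total,
#' `t_k` the true and `p_k` the predicted class totals,
#' `(c*s - sum t_k p_k) / sqrt((s^2 - sum p_k^2) * (s^2 - sum t_k^2))`.
#' Returns 0 when a denominator term vanishes. For `K = 2` this reduces to
#' the familiar binary MCC.
#'
#' @param cm a [confusion()] matrix.
#' @return value in [-1, 1].
#' @export
multiclass_mcc <- function(cm) {
  cm <- unclass(cm) * 1.0
  s <- sum(cm)
  if (s == 0) stop("empty confusion matrix", call. = FALSE)
  cc <- sum(diag(cm))
  tk <- rowSums(cm)
  pk <- colSums(cm)
  num <- cc * s - sum(tk * pk)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  if (den == 0) return(0)
  num / den
}

#' Macro-averaged F1 score
#'
#' Unweighted mean over classes of the per-class F1
#' (`2TP / (2TP + FP + FN)`). Classes with neither true nor predicted
#' members contribute 0 and are reported via `message()`.
#'
#' @param cm a [confusion()] matrix.
#' @return value in [0, 1].
#' @export
macro_f1 <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  den <- 2 * tp + fp + fn
  empty <- den == 0
  if (any(empty))
    message("class(es) with no true and no predicted members score F1 = 0: ",
            paste(rownames(cm)[empty], collapse = ", "))
  f1 <- ifelse(empty, 0, 2 * tp / den)
  mean(f1)
}

#' Full evaluation report
#'
#' @param predicted,truth,class_order as in [confusion()].
#' @return list of class `eval_report`: `q10`, `per_class_accuracy`, `mcc`,
#'   `macro_f1`, `n`, `confusion`.
#' @export
eval_report <- function(predicted, truth, class_order = class_vocabulary()) {
  cm <- confusion(predicted, truth, class_order)
  structure(list(q10 = q10(cm),
                 per_class_accuracy = per_class_accuracy(cm),
                 mcc = multiclass_mcc(cm),
                 macro_f1 = suppressMessages(macro_f1(cm)),
                 n = sum(cm),
                 confusion = cm),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("evaluation over %d proteins\n", x$n))
  cat(sprintf("  Q10      %.1f%%\n", x$q10))
  cat(sprintf("  MCC      %.3f\n", x$mcc))
  cat(sprintf("  macro F1 %.3f\n", x$macro_f1))
  invisible(x)
}

#' Mean and standard deviation of metrics over random seeds
#'
#' Runs a seeded training+evaluation procedure once per seed and aggregates
#' each returned metric as mean ± sample standard deviation (n-1
#' denominator). The per-seed values are retained.
#'
#' @param run function taking one integer seed and returning a named numeric
#'   vector (or list) of metrics.
#' @param seeds integer vector of seeds; the conventional protocol uses 10.
#' @return list with `mean`, `sd` (named numeric vectors) and `per_seed`
#'   (seeds x metrics matrix).
#' @export
multi_seed <- function(run, seeds = 1:10) {
  stopifnot(length(seeds) >= 2L)
  rows <- lapply(seeds, function(s) {
    out <- tryCatch(run(s), error = function(e)
      stop(sprintf("run failed for seed %d: %s", s, conditionMessage(e)),
           call. = FALSE))
    unlist(out)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- as.character(seeds)
  list(mean = colMeans(m), sd = apply(m, 2L, stats::sd), per_seed = m)
}

#' Resample a labeled set to match a target class distribution
#'
#' Draws `n` proteins with replacement: each draw first samples a class from
#' `target_dist`, then a member of that class uniformly. Used to score a
#' classifier under a different class prevalence than the evaluation set's
#' own (the expected resampled accuracy is `sum_c target_c *
#' per_class_accuracy_c`).
#'
#' @param ids vector of protein ids.
#' @param labels class labels aligned with `ids`.
#' @param target_dist named probability vector over classes (sums to 1).
#' @param n number of draws (default: `length(ids)`).
#' @param seed integer seed.
#' @return integer vector of indices into `ids` (length `n`).
#' @export
resample_to_distribution <- function(ids, labels, target_dist,
                                     n = length(ids), seed = 1L) {
  stopifnot(length(ids) == length(labels), n >= 1L)
  if (abs(sum(target_dist) - 1) > 1e-9)
    stop("target distribution must sum to 1", call. = FALSE)
  pos <- names(target_dist)[target_dist > 0]
  absent <- setdiff(pos, unique(labels))
  if (length(absent) > 0L)
    stop("target class(es) with positive mass absent from dataset: ",
         paste(absent, collapse = ", "), call. = FALSE)
  by_class <- split(seq_along(ids), labels)
  set.seed(seed)
  cls <- sample(names(target_dist), n, replace = TRUE, prob = target_dist)
  vapply(cls, function(cl) {
    members <- by_class[[cl]]
    members[sample.int(length(members), 1L)]
  }, 0L, USE.NAMES = FALSE)
}

#' Write a confusion matrix as TSV (class order in the header)
#' @param cm a [confusion()] matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_confusion_tsv <- function(cm, path) {
  df <- as.data.frame.matrix(unclass(cm))
  utils::write.table(cbind(true = rownames(cm), df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
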