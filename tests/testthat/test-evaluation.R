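vocab3 <- c("Nucleus", "Cytoplasm", "Plastid")

test_that("confusion matrices count true-vs-predicted pairs", {
  truth <- c("Nucleus", "Cytoplasm", "Plastid")
  cm <- confusion(truth, truth, vocab3)
  expect_equal(unname(diag(cm)), c(1L, 1L, 1L))
  expect_equal(sum(cm) - sum(diag(cm)), 0L)
  cm2 <- confusion("Cytoplasm", "Nucleus", vocab3)
  expect_equal(unname(cm2["Nucleus", "Cytoplasm"]), 1L)
  expect_equal(sum(cm2), 1L)
  # conservation for random labels
  set.seed(1)
  p <- sample(vocab3, 200, replace = TRUE)
  t0 <- sample(vocab3, 200, replace = TRUE)
  expect_equal(sum(confusion(p, t0, vocab3)), 200L)
  expect_error(confusion("Moon", "Nucleus", vocab3), "outside")
  # display view: row-normalized, most common class first
  cmd <- confusion_display(confusion(p, t0, vocab3))
  expect_equal(unname(rowSums(cmd)), rep(1, 3), tolerance = 1e-12)
  expect_equal(rownames(cmd)[1], names(which.max(table(t0))))
})

test_that("Q10 is overall accuracy and matches the per-protein route", {
  p <- c(rep("Nucleus", 8), rep("Cytoplasm", 2))
  t0 <- rep("Nucleus", 10)
  expect_equal(q10(confusion(p, t0, vocab3)), 80)
  expect_equal(q10(confusion(t0, t0, vocab3)), 100)
  # two-route equivalence on random inputs
  set.seed(2)
  for (i in 1:5) {
    p <- sample(vocab3, 50, replace = TRUE)
    t0 <- sample(vocab3, 50, replace = TRUE)
    expect_equal(q10(confusion(p, t0, vocab3)), 100 * mean(p == t0))
  }
})

test_that("the majority baseline scores the largest class share", {
  set.seed(8)
  vocab <- class_vocabulary()
  t0 <- sample(vocab, 300, replace = TRUE,
               prob = c(0.3, 0.25, 0.1, 0.1, 0.08, 0.06, 0.05, 0.03, 0.02, 0.01))
  maj <- names(which.max(table(t0)))
  cm <- confusion(rep(maj, 300), t0, vocab)
  expect_equal(q10(cm), 100 * max(table(t0)) / 300)
  expect_equal(majority_q10(cm), q10(cm))
})

test_that("K-category MCC matches its closed forms", {
  perfect <- confusion(vocab3, vocab3, vocab3)
  expect_equal(multiclass_mcc(perfect), 1.0)
  # statistical independence: counts proportional to t_i * p_j
  cm <- structure(outer(c(30, 20, 10), c(40, 15, 5)) / 60,
                  class = c("confusion_matrix", "matrix"),
                  dimnames = list(true = vocab3, predicted = vocab3))
  expect_equal(multiclass_mcc(cm), 0, tolerance = 1e-12)
  # any 2x2 matrix reduces to binary MCC
  set.seed(4)
  for (i in 1:10) {
    m <- matrix(sample(0:30, 4, replace = TRUE), 2, 2)
    if (sum(m) == 0) next
    tp <- m[1, 1]; fn <- m[1, 2]; fp <- m[2, 1]; tn <- m[2, 2]
    den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    binary <- if (den == 0) 0 else (tp * tn - fp * fn) / den
    expect_equal(multiclass_mcc(m), binary, tolerance = 1e-12)
  }
  # invariance under simultaneous row/column permutation
  cmr <- confusion(sample(vocab3, 60, replace = TRUE),
                   sample(vocab3, 60, replace = TRUE), vocab3)
  perm <- c(3, 1, 2)
  expect_equal(multiclass_mcc(unclass(cmr)[perm, perm]), multiclass_mcc(cmr))
})

test_that("macro F1 averages per-class F1 without weighting", {
  perfect <- confusion(vocab3, vocab3, vocab3)
  expect_equal(macro_f1(perfect), 1.0)
  # one class never predicted, others perfect: (1 + 1 + 0)/3... the missed
  # class's F1 is 0 only if it is also never true-and-correct; construct it:
  p <- c("Nucleus", "Cytoplasm", "Nucleus")
  t0 <- c("Nucleus", "Cytoplasm", "Plastid")
  cm <- confusion(p, t0, vocab3)
  # per-class: Nucleus F1 = 2*1/(2+1+0), Cytoplasm 1, Plastid 0
  expect_equal(macro_f1(cm), (2 / 3 + 1 + 0) / 3, tolerance = 1e-12)
  # permutation symmetry
  set.seed(5)
  p <- sample(vocab3, 80, replace = TRUE)
  t0 <- sample(vocab3, 80, replace = TRUE)
  m1 <- suppressMessages(macro_f1(confusion(p, t0, vocab3)))
  m2 <- suppressMessages(macro_f1(confusion(p, t0, rev(vocab3))))
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("multi-seed aggregation reports mean and n-1 standard deviation", {
  runs <- multi_seed(function(s) c(q10 = c(60, 70)[s]), seeds = 1:2)
  expect_equal(unname(runs$mean["q10"]), 65)
  expect_equal(unname(runs$sd["q10"]), sd(c(60, 70)))
  expect_equal(unname(runs$sd["q10"]), 7.0710678, tolerance = 1e-6)
  same <- multi_seed(function(s) c(m = 42), seeds = 1:5)
  expect_equal(unname(same$sd["m"]), 0)
  expect_error(multi_seed(function(s) stop("boom"), seeds = 1:2), "seed 1")
  expect_equal(nrow(multi_seed(function(s) c(a = s), 1:10)$per_seed), 10L)
})

test_that("distribution-matched resampling hits the target frequencies", {
  set.seed(9)
  labels <- rep(vocab3, c(500, 300, 200))
  ids <- sprintf("p%04d", seq_along(labels))
  target <- c(Nucleus = 0.5, Cytoplasm = 0.3, Plastid = 0.2)
  idx <- resample_to_distribution(ids, labels, target, n = 10000, seed = 3)
  freq <- table(factor(labels[idx], levels = vocab3)) / 10000
  for (cl in vocab3) {
    se <- sqrt(target[cl] * (1 - target[cl]) / 10000)
    expect_lt(abs(freq[cl] - target[cl]), 3 * se + 1e-12)
  }
  # determinism and degenerate target
  expect_identical(idx, resample_to_distribution(ids, labels, target,
                                                 n = 10000, seed = 3))
  one <- resample_to_distribution(ids, labels, c(Nucleus = 1, Cytoplasm = 0,
                                                 Plastid = 0), n = 50, seed = 1)
  expect_true(all(labels[one] == "Nucleus"))
  expect_error(resample_to_distribution(ids[1:500], labels[1:500],
                                        c(Nucleus = 0.5, Cytoplasm = 0.5),
                                        seed = 1), "absent")
})

test_that("resampled Q10 converges to the prevalence-weighted accuracy", {
  # fixed synthetic classifier with known per-class accuracy
  set.seed(11)
  n_per <- c(Nucleus = 400, Cytoplasm = 300, Plastid = 300)
  acc <- c(Nucleus = 0.9, Cytoplasm = 0.6, Plastid = 0.3)
  labels <- rep(names(n_per), n_per)
  preds <- unlist(lapply(names(n_per), function(cl) {
    n <- n_per[cl]; k <- round(acc[cl] * n)
    wrong <- setdiff(vocab3, cl)[1]
    c(rep(cl, k), rep(wrong, n - k))
  }))
  ids <- sprintf("p%04d", seq_along(labels))
  target <- c(Nucleus = 0.2, Cytoplasm = 0.2, Plastid = 0.6)
  idx <- resample_to_distribution(ids, labels, target, n = 40000, seed = 2)
  got <- 100 * mean(preds[idx] == labels[idx])
  want <- 100 * sum(target * acc[names(target)])
  expect_lt(abs(got - want), 1.0)  # ~4 binomial standard errors at n = 40k
})

test_that("eval reports bundle the metrics consistently", {
  set.seed(6)
  p <- sample(vocab3, 100, replace = TRUE)
  t0 <- sample(vocab3, 100, replace = TRUE)
  rep0 <- eval_report(p, t0, vocab3)
  expect_equal(rep0$q10, q10(rep0$confusion))
  expect_equal(rep0$mcc, multiclass_mcc(rep0$confusion))
  expect_equal(rep0$n, 100L)
  expect_true(all(rep0$per_class_accuracy >= 0 & rep0$per_class_accuracy <= 1,
                  na.rm = TRUE))
  # id-matched route: predictions data.frame + named truth
  preds_df <- data.frame(id = sprintf("x%03d", 1:100), predicted_class = p)
  truth_named <- setNames(t0, preds_df$id)
  rep1 <- eval_report(preds_df, truth_named, vocab3)
  expect_equal(rep1$q10, rep0$q10)
  expect_error(confusion(data.frame(id = "zz", predicted_class = "Nucleus"),
                         truth_named, vocab3), "without truth")
})
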