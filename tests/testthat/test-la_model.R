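test_that("convolution matches closed-form examples and the padding rule", {
  # filter size 1 is a per-position affine map
  out <- conv_coefficients(matrix(c(1, 2, 3), 1, 3), array(2, c(1, 1, 1)), 0.5)
  expect_equal(as.vector(out), c(2.5, 4.5, 6.5))
  # boundary columns use zero vectors
  out3 <- conv_coefficients(matrix(c(1, 2, 3), 1, 3), array(1, c(3, 1, 1)), 0)
  expect_equal(as.vector(out3), c(3, 6, 5))
  # d_in mismatch is an error
  expect_error(conv_coefficients(matrix(0, 3, 4), array(0, c(3, 2, 1)),
                                 numeric(1)), "d_in")
})

test_that("vectorized conv/attention/pool match naive loops on random instances", {
  set.seed(101)
  for (rep in 1:25) {
    d_in <- sample(1:8, 1); d_out <- sample(1:4, 1)
    L <- sample(1:30, 1); s <- sample(c(1, 3, 5, 9), 1)
    x <- matrix(rnorm(d_in * L), d_in, L)
    wb <- random_conv_weights(s, d_in, d_out)
    e_fast <- conv_coefficients(x, wb$W, wb$b)
    expect_equal(e_fast, naive_conv(x, wb$W, wb$b), tolerance = 1e-6)
    a_fast <- attention_weights(e_fast)
    expect_equal(a_fast, naive_softmax_rows(e_fast), tolerance = 1e-6)
    v <- matrix(rnorm(d_out * L), d_out, L)
    expect_equal(attention_pool(a_fast, v), naive_attention_pool(a_fast, v),
                 tolerance = 1e-6)
  }
})

test_that("attention weights normalize, respect masks, handle edge cases", {
  expect_equal(as.vector(attention_weights(matrix(0, 1, 4))), rep(0.25, 4))
  expect_equal(as.vector(attention_weights(matrix(5, 1, 1))), 1)
  expect_equal(as.vector(attention_weights(matrix(log(1:3), 1))),
               c(1, 2, 3) / 6)
  # per-row sums are 1 over unmasked positions; masked positions exactly 0
  e <- matrix(rnorm(12), 3, 4)
  mask <- c(TRUE, TRUE, FALSE, TRUE)
  a <- attention_weights(e, mask)
  expect_equal(rowSums(a), rep(1, 3), tolerance = 1e-6)
  expect_true(all(a[, 3] == 0))
  expect_error(attention_weights(e, rep(FALSE, 4)), "masked")
})

test_that("attention pooling and max pooling follow their contracts", {
  expect_equal(attention_pool(matrix(c(1, 0, 0), 1), matrix(c(7, 8, 9), 1)), 7)
  v <- matrix(rnorm(8), 2, 4)
  expect_equal(attention_pool(matrix(0.25, 2, 4), v), rowMeans(v))
  expect_error(attention_pool(matrix(0, 2, 3), matrix(0, 2, 4)), "mismatch")
  expect_equal(max_pool_values(matrix(c(1, 5, 3), 1)), 5)
  expect_equal(max_pool_values(matrix(c(1, 5, 3), 1),
                               mask = c(TRUE, FALSE, TRUE)), 3)
  expect_equal(max_pool_values(matrix(4.5, 1, 1)), 4.5)
  expect_error(max_pool_values(matrix(0, 1, 2), mask = c(FALSE, FALSE)),
               "masked")
})

test_that("full forward equals the manual composition of its stages", {
  set.seed(31)
  cfg <- la_config(variant = "la", s = 5, d_in = 6, d_out = 4, hidden = 8,
                   n_classes = 10, dropout = 0)
  model <- la_model(cfg, seed = 3)
  x <- matrix(rnorm(6 * 17), 6, 17)
  p <- model$params
  e <- crossprod(p$W_e, lightattn:::unfold_same(x, 5)) + p$b_e
  v <- crossprod(p$W_v, lightattn:::unfold_same(x, 5)) + p$b_v
  alpha <- attention_weights(e)
  h <- c(attention_pool(alpha, v), max_pool_values(v))
  logits <- p$W2 %*% pmax(p$W1 %*% h + p$b1, 0) + p$b2
  manual <- exp(logits - max(logits)); manual <- manual / sum(manual)
  got <- la_forward(x, model)
  expect_equal(unname(got$probabilities), as.vector(manual), tolerance = 1e-6)
  expect_equal(sum(got$probabilities), 1, tolerance = 1e-6)
  expect_equal(got$predicted_class,
               model$vocab[which.max(got$probabilities)])
})

test_that("output width is fixed at 2*d_out regardless of sequence length", {
  cfg <- la_config(variant = "la", s = 9, d_in = 4, d_out = 6, hidden = 5,
                   n_classes = 3, dropout = 0)
  model <- la_model(cfg, seed = 1)
  for (L in c(1, 5, 30, 3000)) {
    h <- lightattn:::encoder_forward(model$params, cfg,
                                     matrix(rnorm(4 * L), 4, L))$h
    expect_length(h, 12L)
  }
})

test_that("padded-batch predictions equal unbatched predictions", {
  set.seed(77)
  cfg <- la_config(variant = "la", s = 9, d_in = 5, d_out = 4, hidden = 6,
                   n_classes = 10, dropout = 0.25)
  model <- la_model(cfg, seed = 2)
  lens <- c(1, 5, 30, 300)
  emb <- lapply(lens, function(L) matrix(rnorm(5 * L), 5, L))
  names(emb) <- paste0("p", lens)
  batches <- make_batches(emb, setNames(rep("Nucleus", 4), names(emb)),
                          batch_size = 4, seed = NULL)
  probs_batched <- la_forward_padded(batches[[1]]$x, batches[[1]]$mask, model)
  for (b in seq_along(lens)) {
    solo <- la_forward(emb[[batches[[1]]$ids[b]]], model)$probabilities
    expect_equal(unname(probs_batched[b, ]), unname(solo), tolerance = 1e-5)
  }
  # padding a single protein out to 3x its length changes nothing
  x <- emb$p30
  xpad <- cbind(x, matrix(0, 5, 60))
  mask <- c(rep(TRUE, 30), rep(FALSE, 60))
  padded <- la_forward_padded(array(xpad, c(5, 90, 1)),
                              matrix(mask, 1), model)
  expect_equal(unname(padded[1, ]),
               unname(la_forward(x, model)$probabilities), tolerance = 1e-5)
})

test_that("hand-set weights let the attention isolate a single residue", {
  # one channel (d_out = 1), s = 1: e_j = w_e * x_j, v_j = x_j.
  # A large positive w_e on a one-hot-ish input puts all mass on position 1.
  cfg <- la_config(variant = "la", s = 1, d_in = 1, d_out = 1, hidden = 2,
                   n_classes = 2, dropout = 0)
  model <- la_model(cfg, seed = 1)
  model$params$W_e <- matrix(50)  # huge logit where x is large
  model$params$b_e <- 0
  model$params$W_v <- matrix(1); model$params$b_v <- 0
  x <- matrix(c(1, 0, 0, 0, 0), 1)   # signal at position 1 only
  ef <- lightattn:::encoder_forward(model$params, cfg, x, keep_cache = TRUE)
  expect_equal(ef$cache$alpha[1, 1], 1, tolerance = 1e-6)
  expect_equal(ef$h[1], 1, tolerance = 1e-6)  # x' ~ v[, 1]
})

test_that("variant forwards implement their ablations", {
  set.seed(5)
  d_in <- 4; d_out <- 3
  x <- matrix(rnorm(d_in * 11), d_in, 11)
  # classifier input widths
  widths <- c(la = 2 * d_out, la_no_softmax = 2 * d_out,
              la_no_maxpool = d_out, attention_from_v = 2 * d_out,
              conv_adapool = 15 * d_out, query_attention = d_in, fnn = d_in)
  for (v in names(widths)) {
    cfg <- la_config(variant = v, s = 3, d_in = d_in, d_out = d_out,
                     hidden = 4, n_classes = 5, dropout = 0)
    expect_equal(ncol(la_model(cfg, seed = 1)$params$W1),
                 unname(widths[v]), info = v)
    pr <- build_variant(cfg)(x, la_model(cfg, seed = 1)$params)
    expect_equal(sum(pr), 1, tolerance = 1e-6, info = v)
  }
  expect_error(la_config(variant = "nope"), "arg")
  # LA w/o softmax: pooled part is the per-channel mean of the coefficients e
  cfg <- la_config(variant = "la_no_softmax", s = 3, d_in = d_in,
                   d_out = d_out, hidden = 4, n_classes = 5, dropout = 0)
  m <- la_model(cfg, seed = 2)
  ef <- lightattn:::encoder_forward(m$params, cfg, x, keep_cache = TRUE)
  expect_equal(ef$h[1:d_out], rowMeans(ef$cache$e), tolerance = 1e-12)
  # attention_from_v with zero coefficient conv -> uniform attention
  cfg <- la_config(variant = "attention_from_v", s = 3, d_in = d_in,
                   d_out = d_out, hidden = 4, n_classes = 5, dropout = 0)
  m <- la_model(cfg, seed = 3)
  m$params$W_e[] <- 0; m$params$b_e[] <- 0
  ef <- lightattn:::encoder_forward(m$params, cfg, x, keep_cache = TRUE)
  expect_true(all(abs(ef$cache$alpha - 1 / 11) < 1e-12))
  # conv_adapool pools the length dimension to exactly 5 positions
  for (L in c(1, 4, 5, 13, 200)) {
    segs <- lightattn:::adaptive_segments(L, 5L)
    expect_length(segs, 5L)
    expect_true(all(unlist(segs) >= 1 & unlist(segs) <= L))
    expect_true(all(seq_len(L) %in% unlist(segs)))
  }
})

test_that("parameter count follows the closed form and is monotone", {
  cfg <- la_config(s = 9, d_in = 1024, d_out = 1024, hidden = 32,
                   n_classes = 10)
  n <- count_parameters(cfg)
  expect_equal(n, 2 * (9 * 1024 * 1024 + 1024) + (2048 * 32 + 32) +
                 (32 * 10 + 10))
  expect_equal(round(n / 1e6), 19)
  expect_equal(count_parameters(la_config(s = 1, d_in = 1, d_out = 1,
                                          hidden = 1, n_classes = 2)), 11)
  # increasing any dimension strictly increases the count
  base <- list(s = 3, d_in = 4, d_out = 5, hidden = 6, n_classes = 3)
  n0 <- count_parameters(do.call(la_config, base))
  for (field in names(base)) {
    up <- base
    up[[field]] <- up[[field]] + if (field == "s") 2 else 1
    expect_gt(count_parameters(do.call(la_config, up)), n0)
  }
})

test_that("analytic gradients match numerical gradients for every variant", {
  set.seed(99)
  num_grad <- function(f, p, eps = 1e-5) {
    vapply(seq_along(p), function(i) {
      p1 <- p; p1[i] <- p1[i] + eps
      p2 <- p; p2[i] <- p2[i] - eps
      (f(p1) - f(p2)) / (2 * eps)
    }, 0)
  }
  for (v in c("la", "la_no_softmax", "la_no_maxpool", "attention_from_v",
              "conv_adapool", "query_attention", "fnn")) {
    cfg <- la_config(variant = v, s = 3, d_in = 3, d_out = 2, hidden = 4,
                     n_classes = 3, dropout = 0)
    params <- lightattn:::init_params(cfg, seed = 1)
    xs <- list(matrix(rnorm(3 * 6), 3, 6), matrix(rnorm(3 * 2), 3, 2))
    y <- c(1L, 3L); w <- rep(1, 3)
    bg <- lightattn:::batch_grad(params, cfg, xs, y, w, NULL)
    for (nm in names(bg$grads)) {
      fn <- function(pv) {
        pp <- params; pp[[nm]][] <- pv
        lightattn:::batch_grad(pp, cfg, xs, y, w, NULL)$loss
      }
      expect_equal(as.vector(bg$grads[[nm]]),
                   num_grad(fn, as.vector(params[[nm]])),
                   tolerance = 1e-6, info = paste(v, nm))
    }
  }
})

test_that("checkpoints round-trip with a JSON sidecar", {
  cfg <- la_config(variant = "la", s = 3, d_in = 4, d_out = 3, hidden = 4,
                   n_classes = 10)
  model <- la_model(cfg, seed = 9)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, model$params)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$config$variant, "la")
  expect_equal(side$class_vocabulary, model$vocab)
  expect_equal(side$n_parameters, count_parameters(model))
  x <- matrix(rnorm(4 * 8), 4, 8)
  expect_equal(la_forward(x, back)$probabilities,
               la_forward(x, model)$probabilities)
})
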