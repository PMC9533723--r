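test_that("class weights balance the loss mass", {
  expect_equal(class_weights(100, 100), c(w_pos = 1, w_neg = 1))
  w <- class_weights(50, 150)
  expect_equal(w[["w_pos"]], 2)
  expect_equal(w[["w_neg"]], 2 / 3, tolerance = 1e-6)
  # construction: equal weighted class masses for arbitrary counts
  for (counts in list(c(1, 9), c(37, 12), c(5, 5))) {
    w <- class_weights(counts[1], counts[2])
    expect_equal(w[["w_pos"]] * counts[1], w[["w_neg"]] * counts[2])
  }
  expect_error(class_weights(0, 10), "zero-count")
})

test_that("model structure and deterministic initialization", {
  cfg <- murmur_cnn_config(init_seed = 99)
  p1 <- stillsnet:::init_cnn_params(cfg)
  p2 <- stillsnet:::init_cnn_params(cfg)
  expect_identical(p1, p2)
  # 3 conv + 2 hidden dense + 1 output layer
  expect_equal(sum(startsWith(names(p1), "Wc")), 3)
  expect_equal(sum(startsWith(names(p1), "Wd")), 3)
  expect_equal(nrow(p1$Wd3), 1)                       # single sigmoid unit
  expect_equal(dim(p1$Wc1), c(16, 9))                 # 3x3 kernels on 1 chan
  expect_equal(dim(p1$Wc2), c(32, 9 * 16))
  expect_equal(dim(p1$Wd1), c(64, 6 * 16 * 64))       # 55x129 -> 6x16 pooled
  # forward pass of an untrained net lies in (0,1)
  x <- array(stats::runif(55 * 129 * 3), c(55, 129, 3))
  fwd <- stillsnet:::cnn_forward(p1, stillsnet:::as_spec_array(x, c(55, 129)))
  expect_true(all(fwd$p > 0 & fwd$p < 1))
  # different seed, different parameters
  p3 <- stillsnet:::init_cnn_params(murmur_cnn_config(init_seed = 100))
  expect_false(identical(p1$Wc1, p3$Wc1))
})

test_that("backpropagation matches numerical gradients", {
  cfg <- tiny_cnn(input_shape = c(11L, 13L), seed = 3)
  withr::with_seed(5, {
    xs <- array(stats::runif(11 * 13 * 3), c(11, 13, 3))
  })
  ys <- c(1, 0, 1)
  w <- ifelse(ys == 1, 1.3, 0.7)
  ps <- stillsnet:::init_cnn_params(cfg)
  xa <- stillsnet:::as_spec_array(xs, cfg$input_shape)
  fwd <- stillsnet:::cnn_forward(ps, xa, keep_cache = TRUE)
  g <- stillsnet:::cnn_backward(ps, fwd, w * (fwd$p - ys) / 3)
  lossfn <- function(params) {
    p <- stillsnet:::cnn_forward(params, xa)$p
    -mean(w * (ys * log(p) + (1 - ys) * log(1 - p)))
  }
  withr::with_seed(1, {
    for (nm in names(ps)) {
      for (k in sample(length(ps[[nm]]), min(3, length(ps[[nm]])))) {
        eps <- 1e-6
        pp <- ps; pp[[nm]][k] <- pp[[nm]][k] + eps
        pm <- ps; pm[[nm]][k] <- pm[[nm]][k] - eps
        num <- (lossfn(pp) - lossfn(pm)) / (2 * eps)
        expect_equal(g[[nm]][k], num, tolerance = 1e-4)
      }
    }
  })
})

test_that("training separates a separable toy problem", {
  toy <- toy_patterns(n_each = 20, shape = c(12, 16))
  m <- fit_murmur_cnn(toy$x, toy$y, tiny_cnn(c(12L, 16L), seed = 2),
                      murmur_train_config(epochs = 20, batch_size = 8,
                                          shuffle_seed = 4))
  # descent sanity and convergence within 20 epochs
  expect_lt(m$history$loss[nrow(m$history)], m$history$loss[1])
  expect_equal(m$history$accuracy[nrow(m$history)], 1)
  p <- predict(m, toy$x)
  expect_true(all(p[toy$y == 1] > 0.9))
  expect_true(all(p[toy$y == 0] < 0.1))
  # batched prediction equals per-item prediction
  p_item <- vapply(toy$x, function(s) predict(m, s), 1)
  expect_equal(p, p_item, tolerance = 1e-12)
  # inference is deterministic
  expect_identical(predict(m, toy$x), p)
})

test_that("training is bit-reproducible under fixed seeds", {
  toy <- toy_patterns(n_each = 8, shape = c(12, 16))
  tc <- murmur_train_config(epochs = 3, batch_size = 8, shuffle_seed = 7)
  m1 <- fit_murmur_cnn(toy$x, toy$y, tiny_cnn(c(12L, 16L)), tc)
  m2 <- fit_murmur_cnn(toy$x, toy$y, tiny_cnn(c(12L, 16L)), tc)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("class weighting improves minority recall on imbalanced data", {
  # imbalanced training: 8 positives vs 48 negatives of a noisy toy task
  shape <- c(12, 16)
  mk <- function(n, positive, seed) withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      m <- matrix(0.3, shape[1], shape[2])
      band <- if (positive) 3:6 else 9:12
      m[, band] <- 0.6
      m + matrix(stats::rnorm(prod(shape), sd = 0.22), shape[1], shape[2])
    })
  })
  x <- c(mk(8, TRUE, 1), mk(48, FALSE, 2))
  y <- c(rep(1, 8), rep(0, 48))
  xt <- c(mk(25, TRUE, 3), mk(25, FALSE, 4))
  yt <- c(rep(1, 25), rep(0, 25))
  cfg <- tiny_cnn(c(12L, 16L), seed = 5)
  tc_w <- murmur_train_config(epochs = 12, batch_size = 8, shuffle_seed = 6)
  tc_u <- murmur_train_config(epochs = 12, batch_size = 8, shuffle_seed = 6,
                              class_weights = c(1, 1))
  mw <- fit_murmur_cnn(x, y, cfg, tc_w)
  mu <- fit_murmur_cnn(x, y, cfg, tc_u)
  recall <- function(m) mean(predict(m, xt)[yt == 1] > 0.5)
  expect_gte(recall(mw), recall(mu))
})

test_that("single-class training warns; label validation errors", {
  toy <- toy_patterns(n_each = 4, shape = c(12, 16))
  expect_warning(
    fit_murmur_cnn(toy$x[1:4], rep(1, 4), tiny_cnn(c(12L, 16L)),
                   murmur_train_config(epochs = 1, batch_size = 4)),
    "single-class")
  expect_error(fit_murmur_cnn(toy$x, rep(0.5, length(toy$x)),
                              tiny_cnn(c(12L, 16L))),
               "0/1")
  expect_error(predict(fit_murmur_cnn(toy$x, toy$y, tiny_cnn(c(12L, 16L)),
                                      murmur_train_config(epochs = 1)),
                       matrix(0, 5, 5)),
               "does not match")
})

test_that("save/load round trip reproduces predictions exactly", {
  toy <- toy_patterns(n_each = 6, shape = c(12, 16))
  m <- fit_murmur_cnn(toy$x, toy$y, tiny_cnn(c(12L, 16L)),
                      murmur_train_config(epochs = 2, batch_size = 8))
  f <- withr::local_tempfile(fileext = ".rds")
  save_murmur_cnn(m, f)
  m2 <- load_murmur_cnn(f)
  expect_identical(predict(m2, toy$x), predict(m, toy$x))
})
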