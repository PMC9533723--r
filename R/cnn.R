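# Small convolutional network for per-cycle Still's murmur probability.
#
# Architecture: [conv 3x3 "same" -> ReLU -> maxpool 2x2] x 3 -> flatten ->
# dense ReLU -> dense ReLU -> dense 1 sigmoid. Trained with class-weighted
# binary cross-entropy and momentum SGD with exponential learning-rate decay.
#
# Implemented directly on BLAS: convolutions are lowered to matrix products
# via im2col, so the heavy lifting runs in optimized dgemm. All randomness
# (initialization, epoch shuffling) flows through named seeds, making
# training bit-reproducible.

#' CNN architecture configuration
#'
#' Three convolution stages, two hidden dense layers and a single sigmoid
#' output unit. Each convolution stage is a 3x3 convolution with "same"
#' padding, ReLU activation and 2x2 max pooling.
#'
#' @param conv_filters integer vector of length 3: filters per convolution
#'   stage (default 16, 32, 64).
#' @param dense_units integer vector of length 2: units of the two hidden
#'   dense layers (default 64, 64).
#' @param input_shape input grid as `c(time_frames, freq_bins)` (default
#'   55 x 129).
#' @param input_center constant subtracted from the input grid before the
#'   first convolution. Spectrograms are min-max normalized to \[0, 1\], so
#'   the default 0.5 centers them at zero; without centering, early
#'   gradients chase a constant predictor and momentum SGD can stall on a
#'   long plateau at chance loss.
#' @param init_seed integer seed for deterministic weight initialization.
#' @return An object of class `murmur_cnn_config`.
#' @export
murmur_cnn_config <- function(conv_filters = c(16L, 32L, 64L),
                              dense_units = c(64L, 64L),
                              input_shape = c(55L, 129L),
                              input_center = 0.5,
                              init_seed = 1L) {
  stopifnot(length(conv_filters) == 3, length(dense_units) == 2,
            all(conv_filters > 0), all(dense_units > 0),
            length(input_shape) == 2, length(input_center) == 1)
  structure(list(conv_filters = as.integer(conv_filters),
                 dense_units = as.integer(dense_units),
                 input_shape = as.integer(input_shape),
                 input_center = as.numeric(input_center),
                 init_seed = as.integer(init_seed)),
            class = "murmur_cnn_config")
}

#' Training configuration
#'
#' Momentum SGD with per-epoch exponentially decayed learning rate
#' (`lr0 * lr_decay^(epoch-1)`) on class-weighted binary cross-entropy.
#'
#' @param epochs number of passes over the training set (default 50).
#' @param batch_size minibatch size (default 32).
#' @param momentum momentum coefficient (default 0.9).
#' @param lr0 initial learning rate (default 0.01).
#' @param lr_decay exponential per-epoch decay factor in (0, 1\] (default
#'   0.95).
#' @param class_weights `c(w_pos, w_neg)` loss weights, or `NULL` to derive
#'   balancing weights from the training counts (see [class_weights()]).
#' @param shuffle_seed integer seed for epoch shuffling.
#' @return An object of class `murmur_train_config`.
#' @export
murmur_train_config <- function(epochs = 50, batch_size = 32, momentum = 0.9,
                                lr0 = 0.01, lr_decay = 0.95,
                                class_weights = NULL, shuffle_seed = 1L) {
  if (lr0 <= 0) stopf("lr0 must be positive")
  if (lr_decay <= 0 || lr_decay > 1) stopf("lr_decay must be in (0, 1]")
  if (!is.null(class_weights) && any(class_weights <= 0))
    stopf("class weights must be positive")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 momentum = momentum, lr0 = lr0, lr_decay = lr_decay,
                 class_weights = class_weights,
                 shuffle_seed = as.integer(shuffle_seed)),
            class = "murmur_train_config")
}

#' Balancing class weights for the weighted cross-entropy
#'
#' `w_c = (n_pos + n_neg) / (2 * n_c)`, so each class carries equal total
#' mass in the loss regardless of imbalance; with balanced counts both
#' weights are 1 and the loss reduces to standard cross-entropy.
#'
#' @param n_pos,n_neg positive (Still's) and negative cycle counts, both
#'   >= 1.
#' @return Named vector `c(w_pos, w_neg)`.
#' @export
class_weights <- function(n_pos, n_neg) {
  if (n_pos < 1 || n_neg < 1)
    stopf("class weights undefined for a zero-count class")
  n <- n_pos + n_neg
  c(w_pos = n / (2 * n_pos), w_neg = n / (2 * n_neg))
}

## ---- internal layers -------------------------------------------------------

.idx_cache <- new.env(parent = emptyenv())

# Feature maps are held channels-first, dims (C, H, W, N): the im2col matrix
# product then lands directly in that layout (F fastest), so neither the
# forward nor the backward pass needs a permutation of the big arrays.

# Linear indices into the zero-padded array (C, H+2, W+2, N) that gather all
# 3x3 patches into a (9C) x (H*W*N) matrix; rows ordered (c, dh, dw) with c
# fastest, columns ordered (h, w, sample).
im2col_idx <- function(H, W, C, N) {
  key <- paste(H, W, C, N, sep = "x")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L; Wp <- W + 2L
  hh <- rep(seq_len(H), times = W)
  ww <- rep(seq_len(W), each = H)
  blocks <- vector("list", 9L)
  i <- 0L
  for (dw in 0:2) for (dh in 0:2) {
    i <- i + 1L
    base <- as.integer(C) * as.integer((hh + dh - 1L) + Hp * (ww + dw - 1L))
    blocks[[i]] <- outer(seq_len(C), base, `+`)          # C x HW
  }
  v <- as.integer(do.call(rbind, blocks))                # (9C x HW), col-major
  idx <- rep(v, N) + rep.int(as.integer((seq_len(N) - 1L) * C * Hp * Wp),
                             rep.int(length(v), N))
  if (N <= 64) .idx_cache[[key]] <- idx    # cache steady-state batch shapes
  idx
}

conv_forward <- function(x, Wm, b) {
  d <- dim(x)                              # C H W N
  C <- d[1]; H <- d[2]; Wd <- d[3]; N <- d[4]
  P <- array(0, c(C, H + 2L, Wd + 2L, N))
  P[, 2:(H + 1L), 2:(Wd + 1L), ] <- x
  K <- matrix(P[im2col_idx(H, Wd, C, N)], nrow = 9L * C)
  Z <- Wm %*% K + b
  dim(Z) <- c(nrow(Wm), H, Wd, N)
  list(out = Z, K = K, in_dim = d)
}

conv_backward <- function(dOut, cache, Wm, need_dx = TRUE) {
  d <- cache$in_dim
  C <- d[1]; H <- d[2]; Wd <- d[3]; N <- d[4]
  dY <- dOut
  dim(dY) <- c(dim(dOut)[1], H * Wd * N)
  dW <- tcrossprod(dY, cache$K)                          # F x 9C
  db <- rowSums(dY)
  dX <- NULL
  if (need_dx) {
    dK <- crossprod(Wm, dY)                              # (9C) x (HWN)
    # Accumulate into the padded gradient with (c, h) collapsed into one
    # dimension so the row subscript is a contiguous range (fast subsetting).
    dP <- array(0, c(C * (H + 2L), Wd + 2L, N))
    i <- 0L
    for (dw in 1:3) for (dh in 1:3) {
      blk <- dK[(i * C + 1L):((i + 1L) * C), , drop = FALSE]
      i <- i + 1L
      dim(blk) <- c(C * H, Wd, N)
      rr <- (C * (dh - 1L) + 1L):(C * (dh + H - 1L))
      cc <- dw:(dw + Wd - 1L)
      dP[rr, cc, ] <- dP[rr, cc, , drop = FALSE] + blk
    }
    dX <- dP[(C + 1L):(C * (H + 1L)), 2:(Wd + 1L), , drop = FALSE]
    dim(dX) <- c(C, H, Wd, N)
  }
  list(dW = dW, db = db, dX = dX)
}

maxpool_forward <- function(x) {
  d <- dim(x)                              # F H W N
  Ho <- d[2] %/% 2L; Wo <- d[3] %/% 2L
  ro <- seq(1L, 2L * Ho, 2L); co <- seq(1L, 2L * Wo, 2L)
  x11 <- x[, ro, co, , drop = FALSE]
  x21 <- x[, ro + 1L, co, , drop = FALSE]
  x12 <- x[, ro, co + 1L, , drop = FALSE]
  x22 <- x[, ro + 1L, co + 1L, , drop = FALSE]
  m <- pmax(x11, x21, x12, x22)
  m11 <- x11 == m
  m21 <- x21 == m & !m11
  m12 <- x12 == m & !(m11 | m21)
  m22 <- !(m11 | m21 | m12)
  list(out = m, masks = list(m11, m21, m12, m22), in_dim = d)
}

maxpool_backward <- function(dOut, cache) {
  d <- cache$in_dim
  Ho <- d[2] %/% 2L; Wo <- d[3] %/% 2L
  ro <- seq(1L, 2L * Ho, 2L); co <- seq(1L, 2L * Wo, 2L)
  dX <- array(0, d)
  dX[, ro, co, ] <- dOut * cache$masks[[1]]
  dX[, ro + 1L, co, ] <- dOut * cache$masks[[2]]
  dX[, ro, co + 1L, ] <- dOut * cache$masks[[3]]
  dX[, ro + 1L, co + 1L, ] <- dOut * cache$masks[[4]]
  dX
}

# Pooled spatial dims after the three conv/pool stages.
cnn_dims <- function(input_shape) {
  h <- input_shape[1]; w <- input_shape[2]
  for (i in 1:3) { h <- h %/% 2L; w <- w %/% 2L }
  c(h, w)
}

init_cnn_params <- function(config) {
  with_seed(config$init_seed, {
    f <- config$conv_filters
    du <- config$dense_units
    cin <- c(1L, f[1], f[2])
    p <- list()
    for (l in 1:3) {
      fan_in <- 9L * cin[l]
      p[[paste0("Wc", l)]] <- matrix(
        stats::rnorm(f[l] * fan_in, sd = sqrt(2 / fan_in)), f[l], fan_in)
      p[[paste0("bc", l)]] <- numeric(f[l])
    }
    hw <- cnn_dims(config$input_shape)
    flat <- hw[1] * hw[2] * f[3]
    sizes <- c(flat, du, 1L)
    for (l in 1:3) {
      fan_in <- sizes[l]
      sd <- if (l < 3) sqrt(2 / fan_in) else sqrt(1 / fan_in)
      p[[paste0("Wd", l)]] <- matrix(
        stats::rnorm(sizes[l + 1L] * fan_in, sd = sd), sizes[l + 1L], fan_in)
      p[[paste0("bd", l)]] <- numeric(sizes[l + 1L])
    }
    p
  })
}

cnn_forward <- function(params, x, keep_cache = FALSE) {
  N <- dim(x)[4]
  caches <- list()
  a <- x
  for (l in 1:3) {
    cf <- conv_forward(a, params[[paste0("Wc", l)]], params[[paste0("bc", l)]])
    z <- cf$out
    relu_mask <- z > 0
    a1 <- z * relu_mask
    pf <- maxpool_forward(a1)
    if (keep_cache)
      caches[[l]] <- list(conv = cf, relu = relu_mask, pool = pf)
    a <- pf$out
  }
  flat_dim <- prod(dim(a)[1:3])
  A <- a
  dim(A) <- c(flat_dim, N)
  Z4 <- params$Wd1 %*% A + params$bd1
  A4 <- Z4 * (Z4 > 0)
  Z5 <- params$Wd2 %*% A4 + params$bd2
  A5 <- Z5 * (Z5 > 0)
  Z6 <- params$Wd3 %*% A5 + params$bd3
  p <- 1 / (1 + exp(-as.numeric(Z6)))
  if (!keep_cache) return(list(p = p))
  list(p = p, caches = caches, A = A, Z4 = Z4, A4 = A4, Z5 = Z5, A5 = A5,
       pooled_dim = dim(a))
}

cnn_backward <- function(params, fwd, dZ6) {
  g <- list()
  dZ6 <- matrix(dZ6, nrow = 1)
  g$Wd3 <- tcrossprod(dZ6, fwd$A5)
  g$bd3 <- rowSums(dZ6)
  dA5 <- crossprod(params$Wd3, dZ6)
  dZ5 <- dA5 * (fwd$Z5 > 0)
  g$Wd2 <- tcrossprod(dZ5, fwd$A4)
  g$bd2 <- rowSums(dZ5)
  dA4 <- crossprod(params$Wd2, dZ5)
  dZ4 <- dA4 * (fwd$Z4 > 0)
  g$Wd1 <- tcrossprod(dZ4, fwd$A)
  g$bd1 <- rowSums(dZ4)
  dA <- crossprod(params$Wd1, dZ4)
  da <- array(dA, fwd$pooled_dim)
  for (l in 3:1) {
    cache <- fwd$caches[[l]]
    dz <- maxpool_backward(da, cache$pool) * cache$relu
    cb <- conv_backward(dz, cache$conv, params[[paste0("Wc", l)]],
                        need_dx = l > 1)
    g[[paste0("Wc", l)]] <- cb$dW
    g[[paste0("bc", l)]] <- cb$db
    if (l > 1) da <- cb$dX
  }
  g
}

as_spec_array <- function(x, input_shape) {
  if (is.list(x) && !is.array(x))
    x <- array(unlist(x), c(dim(x[[1]]), length(x)))
  d <- dim(x)
  if (length(d) == 2) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (d[1] != input_shape[1] || d[2] != input_shape[2])
    stopf("spectrogram shape %d x %d does not match model input %d x %d",
          d[1], d[2], input_shape[1], input_shape[2])
  dim(x) <- c(1L, d[1], d[2], d[3])        # channels-first: (C, H, W, N)
  x
}

## ---- fitting ---------------------------------------------------------------

#' Fit the Still's murmur cycle classifier
#'
#' Trains the convolutional network on labeled cycle spectrograms by
#' minimizing the class-weighted binary cross-entropy
#' `-[w1 y log p + w0 (1-y) log(1-p)]` (averaged per batch) with momentum
#' SGD. The learning rate at epoch e is `lr0 * lr_decay^(e-1)`. Fixed
#' `init_seed` and `shuffle_seed` make training fully reproducible.
#'
#' @param x cycle spectrograms: a `time x freq x n` array or a list of
#'   `time x freq` matrices, as produced by [featurize_cycle()].
#' @param y binary labels, 1 = Still's murmur cycle, 0 = other.
#' @param config a [murmur_cnn_config()].
#' @param train a [murmur_train_config()].
#' @param verbose print per-epoch loss.
#' @return An object of class `murmur_cnn` with components `params`,
#'   `config`, `train`, `history` (per-epoch data.frame with `epoch`, `lr`,
#'   `loss`, `accuracy`), `class_weights` and `n_params`.
#' @seealso [predict.murmur_cnn()], [class_weights()]
#' @export
fit_murmur_cnn <- function(x, y, config = murmur_cnn_config(),
                           train = murmur_train_config(), verbose = FALSE) {
  x <- as_spec_array(x, config$input_shape) - config$input_center
  y <- as.numeric(y)
  n <- dim(x)[4]
  if (n == 0 || length(y) != n)
    stopf("need one label per spectrogram (%d labels, %d spectrograms)",
          length(y), n)
  if (!all(y %in% c(0, 1))) stopf("labels must be 0/1")
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  cw <- train$class_weights
  if (is.null(cw)) {
    if (n_pos == 0 || n_neg == 0) {
      warning("single-class training set; class weights undefined, using 1/1")
      cw <- c(w_pos = 1, w_neg = 1)
    } else cw <- class_weights(n_pos, n_neg)
  } else cw <- c(w_pos = cw[[1]], w_neg = cw[[2]])
  wvec <- ifelse(y == 1, cw[["w_pos"]], cw[["w_neg"]])

  params <- init_cnn_params(config)
  vel <- lapply(params, function(p) p * 0)
  hist_rows <- vector("list", train$epochs)

  with_seed(train$shuffle_seed, {
    for (epoch in seq_len(train$epochs)) {
      lr <- train$lr0 * train$lr_decay^(epoch - 1)
      ord <- sample.int(n)
      losses <- numeric(0)
      correct <- 0L
      for (start in seq(1L, n, by = train$batch_size)) {
        ii <- ord[start:min(start + train$batch_size - 1L, n)]
        nb <- length(ii)
        xb <- x[, , , ii, drop = FALSE]
        yb <- y[ii]; wb <- wvec[ii]
        fwd <- cnn_forward(params, xb, keep_cache = TRUE)
        p <- pmin(pmax(fwd$p, 1e-12), 1 - 1e-12)
        loss <- -mean(wb * (yb * log(p) + (1 - yb) * log(1 - p)))
        losses <- c(losses, loss * nb)
        correct <- correct + sum((fwd$p > 0.5) == (yb == 1))
        dZ6 <- wb * (p - yb) / nb
        g <- cnn_backward(params, fwd, dZ6)
        for (nm in names(params)) {
          vel[[nm]] <- train$momentum * vel[[nm]] - lr * g[[nm]]
          params[[nm]] <- params[[nm]] + vel[[nm]]
        }
      }
      hist_rows[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                       loss = sum(losses) / n,
                                       accuracy = correct / n)
      if (verbose)
        message(sprintf("epoch %3d  lr %.5f  loss %.4f  acc %.3f",
                        epoch, lr, sum(losses) / n, correct / n))
    }
  })

  structure(list(params = params, config = config, train = train,
                 history = do.call(rbind, hist_rows), class_weights = cw,
                 n_params = sum(vapply(params, length, 1L))),
            class = "murmur_cnn")
}

#' Predict per-cycle Still's murmur probabilities
#'
#' @param object a fitted [fit_murmur_cnn()] model.
#' @param newdata spectrograms as in [fit_murmur_cnn()] (a single
#'   `time x freq` matrix is treated as one cycle).
#' @param type `"prob"` (default) for probabilities in \[0, 1\], `"class"`
#'   for `"SM"`/`"PPM"` labels at `threshold`.
#' @param threshold decision threshold for `type = "class"` (default 0.5;
#'   SM iff p > threshold).
#' @param batch_size prediction batch size.
#' @param ... unused.
#' @return Numeric probabilities or a character vector of labels.
#' @export
predict.murmur_cnn <- function(object, newdata, type = c("prob", "class"),
                               threshold = 0.5, batch_size = 64, ...) {
  type <- match.arg(type)
  x <- as_spec_array(newdata, object$config$input_shape) -
    object$config$input_center
  n <- dim(x)[4]
  p <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    ii <- start:min(start + batch_size - 1L, n)
    p[ii] <- cnn_forward(object$params, x[, , , ii, drop = FALSE])$p
  }
  if (type == "prob") p else classify_cycle(p, threshold)
}

#' @export
print.murmur_cnn <- function(x, ...) {
  f <- x$config$conv_filters; du <- x$config$dense_units
  hw <- cnn_dims(x$config$input_shape)
  cat("Still's murmur cycle classifier (CNN)\n")
  cat(sprintf("  input: %d x %d spectrogram\n",
              x$config$input_shape[1], x$config$input_shape[2]))
  cat(sprintf("  conv stages: 3x3 'same' + ReLU + 2x2 maxpool, filters %s\n",
              paste(f, collapse = "/")))
  cat(sprintf("  dense: %d -> %d -> %d -> 1 (sigmoid)\n",
              hw[1] * hw[2] * f[3], du[1], du[2]))
  cat(sprintf("  parameters: %s\n", format(x$n_params, big.mark = ",")))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs, final loss %.4f, accuracy %.3f\n",
                nrow(x$history), x$history$loss[nrow(x$history)],
                x$history$accuracy[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.murmur_cnn <- function(object, ...) {
  print(object)
  cat(sprintf("  class weights: w_pos %.4f, w_neg %.4f\n",
              object$class_weights[["w_pos"]],
              object$class_weights[["w_neg"]]))
  cat("  training history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' Plot the training history of a fitted cycle classifier
#'
#' @param x a `murmur_cnn` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.murmur_cnn <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "weighted cross-entropy", ...)
  invisible(x)
}

#' Save / load a fitted cycle classifier
#'
#' Serialization round-trips reproduce predictions exactly.
#'
#' @param model a `murmur_cnn` object.
#' @param path file path.
#' @return `save_murmur_cnn` returns `path` invisibly; `load_murmur_cnn`
#'   returns the model.
#' @export
save_murmur_cnn <- function(model, path) {
  stopifnot(inherits(model, "murmur_cnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_murmur_cnn
#' @export
load_murmur_cnn <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "murmur_cnn"))
  model
}
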