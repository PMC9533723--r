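# Shared fixtures, built in code at test time.

# A filtered synthetic recording of the given murmur class.
make_filtered <- function(class = "none", seed = 1, ...) {
  o <- synthesize_recording(synth_params(murmur_class = class, seed = seed,
                                         ...))
  list(rec = apply_bandpass(o$recording), truth = o$truth, raw = o$recording)
}

# Tiny CNN configuration for fast unit tests (not the production default).
tiny_cnn <- function(input_shape = c(12L, 16L), seed = 1L)
  murmur_cnn_config(conv_filters = c(4L, 4L, 8L), dense_units = c(8L, 8L),
                    input_shape = input_shape, init_seed = seed)

# Two linearly separable constant spectrogram patterns.
toy_patterns <- function(n_each = 20, shape = c(12, 16), seed = 42) {
  withr::with_seed(seed, {
    pos <- lapply(seq_len(n_each), function(i) {
      m <- matrix(0.1, shape[1], shape[2])
      m[, seq_len(shape[2] %/% 2)] <- 0.9
      m + matrix(stats::rnorm(prod(shape), sd = 0.02), shape[1], shape[2])
    })
    neg <- lapply(seq_len(n_each), function(i) {
      m <- matrix(0.1, shape[1], shape[2])
      m[, (shape[2] %/% 2 + 1):shape[2]] <- 0.9
      m + matrix(stats::rnorm(prod(shape), sd = 0.02), shape[1], shape[2])
    })
    list(x = c(pos, neg), y = c(rep(1, n_each), rep(0, n_each)))
  })
}

# Brute-force majority-vote oracle for recording classification.
vote_oracle <- function(probs, threshold = 0.5) {
  sm <- 0L
  for (p in probs) if (p > threshold) sm <- sm + 1L
  if (sm > length(probs) / 2) "SM" else "PPM"
}

# Pairwise-concordance AUC oracle (ties count 1/2).
concordance_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}
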