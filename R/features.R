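# Fixed-size spectrogram features: each segmented cardiac cycle becomes a
# 55 (time) x 129 (frequency) grid of min-max normalized decibel magnitudes.
# 129 bins = nfft/2 + 1 at nfft = 256; the time axis is linearly resampled to
# 55 frames so the CNN input shape is independent of cycle duration.

#' Short-time Fourier magnitude spectrogram of a cardiac cycle
#'
#' Frames the cycle waveform with a Hann window (length `win`, hop
#' `round(win * (1 - overlap))`), zero-pads to `nfft` and returns the
#' one-sided magnitude spectrum per frame. The frame count grows with cycle
#' duration; the frequency axis always has `nfft/2 + 1` bins spanning 0 to
#' the Nyquist frequency.
#'
#' @param cycle a cardiac cycle from [segment_recording()], or a numeric
#'   vector (then `fs_hz` must be given).
#' @param fs_hz sampling rate, taken from the cycle when omitted.
#' @param nfft FFT length (default 256, giving 129 frequency bins).
#' @param win window length in samples (default `nfft`).
#' @param overlap fractional window overlap (default 0.75).
#' @return A frames x (nfft/2+1) magnitude matrix with attributes
#'   `freq_hz` (bin centre frequencies) and `time_s` (frame centre times).
#' @export
raw_spectrogram <- function(cycle, fs_hz = NULL, nfft = 256, win = nfft,
                            overlap = 0.75) {
  if (is.list(cycle)) {
    fs_hz <- fs_hz %||% cycle$fs_hz
    x <- cycle$samples
  } else x <- as.numeric(cycle)
  if (is.null(fs_hz)) stopf("fs_hz required when passing a bare vector")
  n <- length(x)
  if (n < win) stopf("cycle shorter than one analysis window (%d < %d)", n, win)
  hop <- max(1L, round(win * (1 - overlap)))
  n_frames <- (n - win) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1)) / (win - 1))   # Hann
  frames <- matrix(x[outer(seq_len(win), starts, `+`)], nrow = win) * w
  if (nfft > win) frames <- rbind(frames, matrix(0, nfft - win, n_frames))
  sp <- stats::mvfft(frames)
  n_bins <- nfft %/% 2 + 1L
  mag <- t(Mod(sp[seq_len(n_bins), , drop = FALSE]))
  attr(mag, "freq_hz") <- (seq_len(n_bins) - 1) * fs_hz / nfft
  attr(mag, "time_s") <- (starts + win / 2) / fs_hz
  mag
}

#' Resample a spectrogram's time axis to a fixed frame count
#'
#' Linear interpolation of each frequency bin onto `target_frames`
#' equispaced points between the first and last frame. The frequency axis is
#' untouched. An input that already has `target_frames` frames is returned
#' unchanged.
#'
#' @param grid a frames x bins magnitude matrix (>= 2 frames).
#' @param target_frames output frame count (default 55).
#' @return A `target_frames` x bins matrix.
#' @export
resample_time_axis <- function(grid, target_frames = 55) {
  n <- nrow(grid)
  if (n < 2) stopf("need at least 2 frames to resample the time axis")
  if (n == target_frames) return(grid)
  xout <- seq(1, n, length.out = target_frames)
  out <- apply(grid, 2, function(col) stats::approx(seq_len(n), col, xout)$y)
  fr <- attr(grid, "freq_hz")
  if (!is.null(fr)) attr(out, "freq_hz") <- fr
  out
}

#' Convert a magnitude grid to normalized decibels
#'
#' `20 * log10(grid + 1e-10)` followed by per-spectrogram min-max
#' normalization to \[0, 1\]. A grid with zero dynamic range (all values
#' equal) maps to all zeros. Because the dB transform turns a gain into an
#' additive constant, the normalized output is invariant to scaling the
#' waveform by any positive constant (up to the 1e-10 magnitude floor).
#'
#' @param grid non-negative magnitude matrix.
#' @return Matrix of the same shape with values in \[0, 1\].
#' @export
to_db_and_normalize <- function(grid) {
  if (any(grid < 0)) stopf("magnitudes must be non-negative")
  db <- 20 * log10(grid + 1e-10)
  rng <- range(db)
  out <- if (diff(rng) == 0) array(0, dim(grid))
         else (db - rng[1]) / diff(rng)
  fr <- attr(grid, "freq_hz")
  if (!is.null(fr)) attr(out, "freq_hz") <- fr
  out
}

#' Featurize a cardiac cycle as a 55 x 129 normalized spectrogram
#'
#' Composition of [raw_spectrogram()], [resample_time_axis()] and
#' [to_db_and_normalize()], in that order (dB conversion and normalization
#' after time resampling). The result is always exactly
#' `target_frames x (nfft/2 + 1)` for any admissible cycle.
#'
#' @inheritParams raw_spectrogram
#' @param target_frames output frame count (default 55).
#' @return A `target_frames` x `(nfft/2+1)` matrix in \[0, 1\].
#' @export
featurize_cycle <- function(cycle, fs_hz = NULL, nfft = 256, win = nfft,
                            overlap = 0.75, target_frames = 55) {
  g <- raw_spectrogram(cycle, fs_hz = fs_hz, nfft = nfft, win = win,
                       overlap = overlap)
  to_db_and_normalize(resample_time_axis(g, target_frames))
}

#' Featurize all cycles of a segmentation result
#'
#' @param seg a successful [segment_recording()] result.
#' @param ... passed to [featurize_cycle()].
#' @return A 3-d array `time x freq x n_cycles`.
#' @export
featurize_segmentation <- function(seg, ...) {
  stopifnot(inherits(seg, "pcg_segmentation"), seg$success)
  mats <- lapply(seg$cycles, featurize_cycle, ...)
  array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
}
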