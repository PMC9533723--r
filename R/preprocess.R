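#' Bandpass filter specification
#'
#' The preprocessing filter is a 4th-order digital Butterworth bandpass with a
#' 40--500 Hz passband: wide enough for normal heart sounds (20--200 Hz),
#' Still's murmur (90--170 Hz) and pathological murmurs (80--500 Hz), while
#' rejecting low-frequency rumble and high-frequency acquisition noise.
#'
#' @param order total filter order; must be even and >= 2 (default 4).
#' @param low_hz,high_hz passband edges in Hz (defaults 40 and 500); the
#'   magnitude response is -3 dB (half power) at the edges, the Butterworth
#'   band-edge convention.
#' @param fs_hz sampling rate in Hz.
#' @return An object of class `bandpass_spec`.
#' @export
bandpass_spec <- function(order = 4, low_hz = 40, high_hz = 500,
                          fs_hz = 4000) {
  if (order < 2 || order %% 2 != 0) stopf("filter order must be even and >= 2")
  if (!(0 < low_hz && low_hz < high_hz && high_hz < fs_hz / 2))
    stopf("passband edges must satisfy 0 < low < high < fs/2")
  structure(list(order = order, low_hz = low_hz, high_hz = high_hz,
                 fs_hz = fs_hz), class = "bandpass_spec")
}

#' Design the Butterworth bandpass filter
#'
#' Designs the digital Butterworth bandpass (bilinear transform with
#' prewarping, via [signal::butter()]) and factors it into cascaded
#' second-order sections for numerically stable application: poles are
#' grouped into complex-conjugate pairs and each biquad receives one zero at
#' z = 1 and one at z = -1, with the overall gain split evenly across
#' sections.
#'
#' @param spec a [bandpass_spec()].
#' @return An object of class `bandpass_filter` with components `b`, `a`
#'   (full transfer function) and `sos` (matrix of biquads, columns
#'   `b0 b1 b2 a0 a1 a2`).
#' @export
design_bandpass <- function(spec) {
  stopifnot(inherits(spec, "bandpass_spec"))
  w <- c(spec$low_hz, spec$high_hz) * 2 / spec$fs_hz
  bt <- signal::butter(spec$order %/% 2, w, "pass")
  b <- bt$b / bt$a[1]
  a <- bt$a / bt$a[1]

  poles <- polyroot(rev(a))
  if (any(Mod(poles) >= 1)) stopf("designed filter is unstable")
  # Group poles into conjugate pairs (sort by argument magnitude, then take
  # consecutive pairs p, Conj(p)).
  up <- poles[Im(poles) >= 0]
  up <- up[order(Arg(up))]
  n_sec <- spec$order %/% 2
  g_sec <- b[1]^(1 / n_sec)
  sos <- t(vapply(seq_len(n_sec), function(i) {
    p <- up[i]
    c(g_sec * c(1, 0, -1), 1, -2 * Re(p), Mod(p)^2)
  }, numeric(6)))
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  structure(list(b = b, a = a, sos = sos, spec = spec),
            class = "bandpass_filter")
}

#' Frequency response of a designed filter
#'
#' Evaluates the complex transfer function H(e^{i 2 pi f / fs}) of the
#' cascaded second-order sections at the requested frequencies.
#'
#' @param filt a [design_bandpass()] result.
#' @param freq_hz frequencies in Hz.
#' @param db return magnitude in dB (default) or complex response.
#' @return Numeric vector of magnitudes in dB (or complex values).
#' @export
bandpass_response <- function(filt, freq_hz, db = TRUE) {
  stopifnot(inherits(filt, "bandpass_filter"))
  z <- exp(-1i * 2 * pi * freq_hz / filt$spec$fs_hz)
  h <- rep(1 + 0i, length(z))
  for (i in seq_len(nrow(filt$sos))) {
    s <- filt$sos[i, ]
    h <- h * (s[1] + s[2] * z + s[3] * z^2) / (s[4] + s[5] * z + s[6] * z^2)
  }
  if (db) 20 * log10(Mod(h)) else h
}

#' Measure the half-power (-3 dB) edges of a designed bandpass
#'
#' Finds the frequencies below and above the passband centre at which the
#' squared magnitude crosses one half (attenuation 10*log10(2) ~ 3.01 dB),
#' by root bracketing on the measured response.
#'
#' @param filt a [design_bandpass()] result.
#' @return Named numeric vector `c(low_hz, high_hz)`.
#' @export
bandpass_edges <- function(filt) {
  spec <- filt$spec
  half <- -10 * log10(2)
  f0 <- sqrt(spec$low_hz * spec$high_hz)   # geometric centre of the passband
  lo <- stats::uniroot(function(f) bandpass_response(filt, f) - half,
                       c(1e-3, f0), tol = 1e-9)$root
  hi <- stats::uniroot(function(f) bandpass_response(filt, f) - half,
                       c(f0, spec$fs_hz / 2 - 1e-3), tol = 1e-9)$root
  c(low_hz = lo, high_hz = hi)
}

#' Apply the bandpass filter to a recording
#'
#' Runs a single causal forward pass of the cascaded second-order sections.
#' Output length, sampling rate and metadata are unchanged.
#'
#' @param recording a [pcg_recording()].
#' @param spec a [bandpass_spec()]; its `fs_hz` must match the recording.
#' @param filt optionally, a pre-designed [design_bandpass()] filter.
#' @return The filtered [pcg_recording()].
#' @export
apply_bandpass <- function(recording, spec = bandpass_spec(fs_hz = recording$fs_hz),
                           filt = NULL) {
  stopifnot(inherits(recording, "pcg_recording"))
  if (is.null(filt)) {
    if (spec$fs_hz != recording$fs_hz)
      stopf("filter fs (%g) does not match recording fs (%g)",
            spec$fs_hz, recording$fs_hz)
    filt <- design_bandpass(spec)
  } else if (filt$spec$fs_hz != recording$fs_hz) {
    stopf("filter fs (%g) does not match recording fs (%g)",
          filt$spec$fs_hz, recording$fs_hz)
  }
  x <- recording$samples
  for (i in seq_len(nrow(filt$sos))) {
    s <- filt$sos[i, ]
    x <- as.numeric(signal::filter(s[1:3], s[4:6], x))
  }
  out <- recording
  out$samples <- x
  out
}
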