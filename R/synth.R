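#' Parameters for synthetic phonocardiogram generation
#'
#' Bundles the acoustic and timing parameters of one synthetic heart-sound
#' recording. Parameters left `NULL` are drawn, deterministically given
#' `seed`, from the documented default ranges when the recording is rendered:
#' duration uniform on 7--15 s, heart rate uniform on 60--140 bpm, Still's
#' murmur frequency uniform on 90--170 Hz, pathological murmur frequency on
#' 80--500 Hz, and murmur amplitude (relative to the S1 peak) uniform on
#' 0.2--0.8.
#'
#' @param duration_s recording length in seconds, or `NULL` to draw from
#'   \[7, 15\].
#' @param heart_rate_bpm mean heart rate in beats per minute, or `NULL` to
#'   draw from \[60, 140\].
#' @param hr_jitter_frac unitless standard deviation of beat-to-beat period
#'   jitter, as a fraction of the mean period.
#' @param murmur_class one of `"none"`, `"stills"`, `"holosystolic"`,
#'   `"ejection"`, `"continuous"`, `"diastolic"`.
#' @param murmur_freq_hz centre frequency of the murmur in Hz, or `NULL` to
#'   draw from the class band (Still's 90--170 Hz; pathological 80--500 Hz).
#' @param murmur_rel_amp murmur amplitude relative to the S1 peak, or `NULL`
#'   to draw from \[0.2, 0.8\].
#' @param snr_db signal-to-noise ratio of the additive noise in dB.
#' @param fs_hz sampling rate in Hz (default 4000).
#' @param noise_type `"white"` (default) or `"pink"`.
#' @param artifact_bursts logical; add occasional short wideband bursts
#'   mimicking handling noise.
#' @param location chest location recorded in the metadata.
#' @param seed integer RNG seed; together with the parameters it fully
#'   determines the rendered waveform.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(duration_s = NULL, heart_rate_bpm = NULL,
                         hr_jitter_frac = 0.03,
                         murmur_class = "none", murmur_freq_hz = NULL,
                         murmur_rel_amp = NULL, snr_db = 20,
                         fs_hz = 4000, noise_type = c("white", "pink"),
                         artifact_bursts = FALSE, location = "LLSB",
                         seed = 1L) {
  murmur_class <- match.arg(murmur_class, .murmur_classes)
  noise_type <- match.arg(noise_type)
  if (!is.null(duration_s) && duration_s <= 0)
    stopf("duration_s must be positive")
  if (!is.null(heart_rate_bpm) &&
      (heart_rate_bpm < 40 || heart_rate_bpm > 200))
    stopf("heart_rate_bpm must lie in [40, 200]")
  if (fs_hz < 2000) stopf("fs_hz must be >= 2000 Hz")
  if (!is.null(murmur_rel_amp) && murmur_rel_amp < 0)
    stopf("murmur_rel_amp must be >= 0")
  if (!is.null(murmur_freq_hz)) {
    if (murmur_class == "stills" &&
        (murmur_freq_hz < 90 || murmur_freq_hz > 170))
      stopf("Still's murmur frequency must lie in [90, 170] Hz")
    if (murmur_freq_hz >= fs_hz / 2)
      stopf("murmur_freq_hz must be below the Nyquist frequency")
  }
  if (!location %in% .pcg_locations)
    stopf("unknown location '%s'", location)
  structure(list(duration_s = duration_s, heart_rate_bpm = heart_rate_bpm,
                 hr_jitter_frac = hr_jitter_frac, murmur_class = murmur_class,
                 murmur_freq_hz = murmur_freq_hz,
                 murmur_rel_amp = murmur_rel_amp, snr_db = snr_db,
                 fs_hz = fs_hz, noise_type = noise_type,
                 artifact_bursts = artifact_bursts, location = location,
                 seed = as.integer(seed)),
            class = "synth_params")
}

# Gaussian-windowed damped sinusoid for a heart-sound transient. Asymmetric
# envelope: fast attack, slower decay, so the energy onset is sharp enough for
# envelope-based lobe detection (as in real S1/S2 sounds).
render_transient <- function(t, onset, dur, freq, amp, phase,
                             rise_frac = 0.3) {
  tt <- t - onset
  inside <- tt >= 0 & tt <= dur
  env <- numeric(length(t))
  peak <- rise_frac * dur
  sig_r <- peak / 2.5          # attack reaches ~exp(-3) at onset
  sig_f <- (dur - peak) / 2.5
  ti <- tt[inside]
  env[inside] <- ifelse(ti < peak,
                        exp(-(ti - peak)^2 / (2 * sig_r^2)),
                        exp(-(ti - peak)^2 / (2 * sig_f^2)))
  amp * env * sin(2 * pi * freq * tt + phase)
}

# Band-limited Gaussian noise for broadband murmurs (order-4 Butterworth).
render_bandnoise <- function(n, fs, low, high) {
  bt <- signal::butter(2, c(low, high) * 2 / fs, "pass")
  x <- signal::filter(bt, stats::rnorm(n))
  as.numeric(x) / stats::sd(x)
}

# Piecewise-linear crescendo--decrescendo ("diamond") envelope on [a, b],
# peaking at `peak_frac` of the window.
triangle_env <- function(t, a, b, peak_frac = 0.5) {
  env <- numeric(length(t))
  p <- a + peak_frac * (b - a)
  up <- t >= a & t < p
  dn <- t >= p & t <= b
  env[up] <- (t[up] - a) / (p - a)
  env[dn] <- (b - t[dn]) / (b - p)
  env
}

# Flat envelope with short cosine on/off ramps.
plateau_env <- function(t, a, b, ramp = 0.01) {
  env <- numeric(length(t))
  inside <- t >= a & t <= b
  ti <- t[inside]
  e <- rep(1, length(ti))
  r1 <- ti < a + ramp
  e[r1] <- 0.5 - 0.5 * cos(pi * (ti[r1] - a) / ramp)
  r2 <- ti > b - ramp
  e[r2] <- 0.5 - 0.5 * cos(pi * (b - ti[r2]) / ramp)
  env[inside] <- e
  env
}

pink_noise <- function(n) {
  # Paul Kellet's economy IIR pink filter on white Gaussian noise.
  w <- stats::rnorm(n)
  b0 <- b1 <- b2 <- 0
  out <- numeric(n)
  for (i in seq_len(n)) {
    b0 <- 0.99765 * b0 + w[i] * 0.0990460
    b1 <- 0.96300 * b1 + w[i] * 0.2965164
    b2 <- 0.57000 * b2 + w[i] * 1.0526913
    out[i] <- b0 + b1 + b2 + w[i] * 0.1848
  }
  out / stats::sd(out)
}

#' Synthesize one phonocardiogram with ground-truth landmarks
#'
#' Renders a heart-sound recording cycle by cycle: S1 as a ~80 ms damped
#' oscillation in the 30--100 Hz range at the start of each cycle, S2 as a
#' shorter (~60 ms), quieter transient in 40--150 Hz at the systole/diastole
#' boundary, and a murmur according to `murmur_class`:
#' \describe{
#'   \item{stills}{a narrowband tone at the drawn 90--170 Hz frequency with a
#'     triangular (diamond) envelope starting 30--50 ms after the S1 onset and
#'     ending before S2 -- the early-to-mid systolic, musical profile of
#'     Still's murmur.}
#'   \item{holosystolic}{80--500 Hz band-limited noise with a near-constant
#'     envelope spanning S1 to S2 (e.g. ventricular septal defect).}
#'   \item{ejection}{crescendo--decrescendo 150--400 Hz band noise peaking in
#'     mid-systole.}
#'   \item{continuous}{band noise whose envelope extends through S2 into
#'     diastole (e.g. patent ductus arteriosus).}
#'   \item{diastolic}{decrescendo band noise after S2.}
#' }
#' Systole length follows `0.30 * period + 0.10 s`, capped at 45% of the
#' period, so systole stays shorter than diastole at pediatric heart rates.
#' White (or pink) Gaussian noise is added and scaled so the realized SNR
#' equals `snr_db` exactly; the waveform is finally scaled to peak 0.95.
#' Identical parameters and seed give bit-identical output.
#'
#' @param params a [synth_params()] object.
#' @param id recording identifier stored in the returned recording.
#' @return A list with components `recording` (a [pcg_recording()]) and
#'   `truth` (ground truth: `s1_onsets_s`, `s2_onsets_s`, `cycle_intervals_s`
#'   as a two-column matrix of half-open \[start, end) pairs, `murmur_class`,
#'   and `murmur_windows_s`, one \[start, end) row per complete cycle).
#' @export
synthesize_recording <- function(params, id = "synth") {
  stopifnot(inherits(params, "synth_params"))
  with_seed(params$seed, {
    dur <- params$duration_s %||% stats::runif(1, 7, 15)
    hr <- params$heart_rate_bpm %||% stats::runif(1, 60, 140)
    cls <- params$murmur_class
    fm <- params$murmur_freq_hz %||% switch(cls,
      none = NA_real_,
      stills = stats::runif(1, 90, 170),
      ejection = stats::runif(1, 150, 400),
      stats::runif(1, 80, 500))
    amp_m <- params$murmur_rel_amp %||%
      if (cls == "none") 0 else stats::runif(1, 0.2, 0.8)
    fs <- params$fs_hz
    if (!is.na(fm) && fm >= fs / 2)
      stopf("sampling rate %g Hz cannot represent a %g Hz murmur", fs, fm)

    period <- 60 / hr
    # Beat grid with multiplicative jitter (truncated at 3 SD).
    onsets <- numeric(0)
    t0 <- 0
    while (t0 <= dur + 1e-9) {
      onsets <- c(onsets, t0)
      eps <- max(-3, min(3, stats::rnorm(1)))
      t0 <- t0 + period * (1 + params$hr_jitter_frac * eps)
    }
    n_cyc <- length(onsets) - 1L       # complete cycles
    if (n_cyc < 1L) stopf("duration too short for a single cardiac cycle")

    n <- round(dur * fs)
    t <- (seq_len(n) - 1) / fs
    x <- numeric(n)

    f_s1 <- stats::runif(1, 35, 90)
    f_s2 <- stats::runif(1, 50, 140)
    stills_delay <- stats::runif(1, 0.03, 0.05)

    s2_onsets <- numeric(n_cyc)
    murmur_win <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n_cyc + 1L)) {
      o <- onsets[i]
      p <- if (i <= n_cyc) onsets[i + 1L] - o else period
      sys_s <- min(0.30 * p + 0.10, 0.45 * p)
      s2 <- o + sys_s
      x <- x + render_transient(t, o, 0.08, f_s1, 1.0, stats::runif(1, 0, 2 * pi))
      if (i <= n_cyc) {
        s2_onsets[i] <- s2
        x <- x + render_transient(t, s2, 0.06, f_s2, 0.6,
                                  stats::runif(1, 0, 2 * pi))
        win <- switch(cls,
          none = NULL,
          stills = c(o + stills_delay, s2 - 0.02),
          holosystolic = c(o, s2),
          ejection = c(o + 0.02, s2 - 0.01),
          continuous = c(o, o + 0.90 * p),
          diastolic = c(s2 + 0.02, s2 + 0.02 + 0.6 * (p - sys_s)))
        if (!is.null(win)) {
          murmur_win <- rbind(murmur_win, win)
          env <- switch(cls,
            stills = triangle_env(t, win[1], win[2]),
            holosystolic = plateau_env(t, win[1], win[2]),
            ejection = triangle_env(t, win[1], win[2]),
            continuous = {
              e <- plateau_env(t, win[1], win[2], ramp = 0.01)
              fade <- t > s2 & t <= win[2]
              e[fade] <- e[fade] * (win[2] - t[fade]) / (win[2] - s2)
              e
            },
            diastolic = {
              e <- numeric(n)
              ii <- t >= win[1] & t <= win[2]
              e[ii] <- (win[2] - t[ii]) / (win[2] - win[1])
              e
            })
          sig_m <- if (cls == "stills") {
            sin(2 * pi * fm * t + stats::runif(1, 0, 2 * pi))
          } else {
            band <- switch(cls,
              holosystolic = c(80, 500),
              ejection = c(max(80, fm - 100), min(500, fm + 100)),
              continuous = c(80, 400),
              diastolic = c(80, 350))
            render_bandnoise(n, fs, band[1], band[2]) * 0.35
          }
          x <- x + amp_m * env * sig_m
        }
      }
    }

    # Additive noise at exactly the requested SNR.
    sig_pw <- mean(x^2)
    noise <- if (params$noise_type == "pink") pink_noise(n) else stats::rnorm(n)
    if (is.finite(params$snr_db)) {
      target_pw <- sig_pw / 10^(params$snr_db / 10)
      noise <- noise * sqrt(target_pw / mean(noise^2))
      x <- x + noise
    }
    if (isTRUE(params$artifact_bursts)) {
      for (k in seq_len(stats::rpois(1, 2))) {
        at <- stats::runif(1, 0, dur - 0.05)
        ii <- which(t >= at & t < at + 0.03)
        x[ii] <- x[ii] + stats::rnorm(length(ii), sd = 1.5)
      }
    }
    x <- 0.95 * x / max(abs(x))

    label <- switch(cls, none = "no_murmur", stills = "stills", "other")
    rec <- pcg_recording(x, fs, id = id, label = label,
                         location = params$location)
    truth <- list(
      s1_onsets_s = onsets,
      s2_onsets_s = s2_onsets,
      cycle_intervals_s = cbind(start = onsets[seq_len(n_cyc)],
                                end = onsets[seq_len(n_cyc) + 1L]),
      murmur_class = cls,
      murmur_windows_s = murmur_win)
    list(recording = rec, truth = truth)
  })
}

#' Synthesize a labeled dataset of phonocardiogram WAV files
#'
#' Writes one 16-bit PCM WAV file and one ground-truth JSON per recording,
#' plus a manifest CSV (`id,path,label,location,class_detail`). Pathological
#' murmur subclasses all map to diagnostic label `"other"`; `"none"` maps to
#' `"no_murmur"`. Identical arguments and seed give identical manifests and
#' file contents.
#'
#' @param n_per_class named integer vector of recording counts, names drawn
#'   from the murmur classes (`none`, `stills`, `holosystolic`, `ejection`,
#'   `continuous`, `diastolic`).
#' @param out_dir output directory (created if missing).
#' @param seed integer seed controlling all randomness.
#' @param locations chest location(s); a single value used for all recordings
#'   or a vector sampled uniformly per recording.
#' @param snr_db,hr_jitter_frac,murmur_rel_amp passed to [synth_params()];
#'   `NULL` draws the documented defaults per recording.
#' @param fs_hz sampling rate of the generated WAV files.
#' @return The manifest as a data.frame, invisibly; also written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
synthesize_dataset <- function(n_per_class, out_dir, seed = 1L,
                               locations = "LLSB", snr_db = 20,
                               hr_jitter_frac = 0.03, murmur_rel_amp = NULL,
                               fs_hz = 4000) {
  stopifnot(length(n_per_class) > 0, !is.null(names(n_per_class)))
  bad <- setdiff(names(n_per_class), .murmur_classes)
  if (length(bad)) stopf("unknown murmur class(es): %s",
                         paste(bad, collapse = ", "))
  if (any(n_per_class < 0)) stopf("counts must be >= 0")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory '%s'", out_dir)

  classes <- rep(names(n_per_class), times = as.integer(n_per_class))
  n_rec <- length(classes)
  draws <- with_seed(seed, list(
    seeds = sample.int(.Machine$integer.max - 1L, n_rec),
    locs = if (length(locations) == 1L) rep(locations, n_rec)
           else sample(locations, n_rec, replace = TRUE)))

  rows <- vector("list", n_rec)
  for (i in seq_len(n_rec)) {
    cls <- classes[i]
    id <- sprintf("rec%04d_%s", i, cls)
    sp <- synth_params(murmur_class = cls, seed = draws$seeds[i],
                       snr_db = snr_db, hr_jitter_frac = hr_jitter_frac,
                       murmur_rel_amp = murmur_rel_amp,
                       location = draws$locs[i], fs_hz = fs_hz)
    out <- synthesize_recording(sp, id = id)
    wav <- file.path(out_dir, paste0(id, ".wav"))
    write_wav(out$recording$samples, fs_hz, wav)
    truth <- out$truth
    truth$cycle_intervals_s <- unname(apply(truth$cycle_intervals_s, 1, c,
                                            simplify = FALSE))
    truth$murmur_windows_s <- if (nrow(truth$murmur_windows_s))
      unname(apply(truth$murmur_windows_s, 1, c, simplify = FALSE)) else list()
    jsonlite::write_json(truth, file.path(out_dir, paste0(id, ".json")),
                         auto_unbox = TRUE, digits = NA)
    rows[[i]] <- data.frame(id = id, path = wav,
                            label = out$recording$label,
                            location = draws$locs[i], class_detail = cls,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows) %||%
    data.frame(id = character(), path = character(), label = character(),
               location = character(), class_detail = character())
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}
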