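test_that("cycle count follows duration/period arithmetic without jitter", {
  o <- synthesize_recording(synth_params(murmur_class = "none",
                                         duration_s = 9, heart_rate_bpm = 80,
                                         hr_jitter_frac = 0, seed = 1))
  expect_equal(nrow(o$truth$cycle_intervals_s), 12)   # 9 s / 0.75 s
  expect_equal(length(o$recording$samples), 9 * 4000)
  # Cycle intervals are the consecutive-S1 partition.
  ivals <- o$truth$cycle_intervals_s
  expect_true(all(diff(o$truth$s1_onsets_s) > 0))
  expect_equal(ivals[-1, "start"], ivals[-nrow(ivals), "end"],
               ignore_attr = TRUE)
  # Exactly one S2 strictly inside each complete cycle.
  for (i in seq_len(nrow(ivals))) {
    inside <- o$truth$s2_onsets_s > ivals[i, 1] & o$truth$s2_onsets_s < ivals[i, 2]
    expect_equal(sum(inside), 1)
  }
})

test_that("identical params and seed give bit-identical output", {
  p <- synth_params(murmur_class = "stills", seed = 77)
  a <- synthesize_recording(p)
  b <- synthesize_recording(p)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth, b$truth)
  # and a different seed gives a different waveform
  c <- synthesize_recording(synth_params(murmur_class = "stills", seed = 78))
  expect_false(identical(a$recording$samples, c$recording$samples))
})

test_that("Still's murmur is narrowband in 90-170 Hz with diamond timing", {
  for (seed in c(5, 21, 99)) {
    o <- synthesize_recording(synth_params(murmur_class = "stills",
                                           snr_db = Inf, seed = seed))
    fs <- o$recording$fs_hz
    wins <- o$truth$murmur_windows_s
    ivals <- o$truth$cycle_intervals_s
    expect_equal(nrow(wins), nrow(ivals))
    for (i in seq_len(nrow(wins))) {
      # onset 30-50 ms after S1; ends strictly before S2
      expect_gte(wins[i, 1] - ivals[i, 1], 0.03)
      expect_lte(wins[i, 1] - ivals[i, 1], 0.05)
      expect_lt(wins[i, 2], o$truth$s2_onsets_s[i])
    }
    # dominant spectral peak of the murmur-window signal lies in [90, 170];
    # measure after the ~80 ms S1 transient has rung down so its low-band
    # tail does not pollute the periodogram
    i <- 3
    a <- max(wins[i, 1], ivals[i, 1] + 0.085)
    seg <- o$recording$samples[ceiling(a * fs):ceiling(wins[i, 2] * fs)]
    pg <- stats::spec.pgram(stats::ts(seg, frequency = fs), plot = FALSE,
                            taper = 0)
    fpk <- pg$freq[which.max(pg$spec)]
    expect_gte(fpk, 90)
    expect_lte(fpk, 170)
    # >= 90% of murmur-window power inside the band
    inband <- pg$freq >= 85 & pg$freq <= 175
    expect_gte(sum(pg$spec[inband]) / sum(pg$spec), 0.9)
  }
})

test_that("Still's murmur energy is systolic, absent in diastole", {
  o <- synthesize_recording(synth_params(murmur_class = "stills",
                                         murmur_rel_amp = 0.8, snr_db = Inf,
                                         seed = 11))
  fs <- o$recording$fs_hz
  ivals <- o$truth$cycle_intervals_s
  s2 <- o$truth$s2_onsets_s
  for (i in c(2, 4)) {
    win <- o$truth$murmur_windows_s[i, ]
    # envelope maximum strictly inside systole
    seg_idx <- floor(ivals[i, 1] * fs):ceiling(ivals[i, 2] * fs)
    # diastolic segment: after S2 end (+60 ms ring-down), before next S1
    dia <- o$recording$samples[ceiling((s2[i] + 0.09) * fs):
                                 floor((ivals[i, 2] - 0.01) * fs)]
    sys <- o$recording$samples[ceiling(win[1] * fs):floor(win[2] * fs)]
    expect_lt(mean(dia^2), 0.02 * mean(sys^2))
    pk <- which.max(abs(sys)) / fs + win[1]
    expect_gt(pk, ivals[i, 1])
    expect_lt(pk, s2[i])
  }
})

test_that("additive noise realizes the requested SNR within 1 dB", {
  for (snr in c(5, 15, 25)) {
    p_clean <- synth_params(murmur_class = "stills", snr_db = Inf, seed = 31)
    p_noisy <- synth_params(murmur_class = "stills", snr_db = snr, seed = 31)
    s <- synthesize_recording(p_clean)$recording$samples
    xn <- synthesize_recording(p_noisy)$recording$samples
    # project the noisy waveform onto the clean signal to split components
    # (final peak normalization rescales both, so estimate the gain)
    a <- sum(xn * s) / sum(s * s)
    resid <- xn - a * s
    snr_est <- 10 * log10(sum((a * s)^2) / sum(resid^2))
    expect_lt(abs(snr_est - snr), 1)
  }
})

test_that("synthesize_dataset writes a consistent, deterministic corpus", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  counts <- c(stills = 4, holosystolic = 4, none = 2)
  m1 <- synthesize_dataset(counts, d1, seed = 9)
  m2 <- synthesize_dataset(counts, d2, seed = 9)
  expect_equal(nrow(m1), 10)
  expect_equal(sum(m1$label == "stills"), 4)
  expect_equal(sum(m1$label != "stills"), 6)
  expect_equal(sum(m1$label == "no_murmur"), 2)
  # deterministic: identical manifests (paths aside) and identical audio
  expect_equal(m1$id, m2$id)
  expect_equal(m1$label, m2$label)
  h1 <- vapply(file.path(d1, paste0(m1$id, ".wav")),
               function(f) unname(tools::md5sum(f)), "")
  h2 <- vapply(file.path(d2, paste0(m2$id, ".wav")),
               function(f) unname(tools::md5sum(f)), "")
  expect_equal(unname(h1), unname(h2))
  # ground-truth JSON exists per recording and parses
  gt <- jsonlite::read_json(file.path(d1, paste0(m1$id[1], ".json")),
                            simplifyVector = TRUE)
  expect_true(all(c("s1_onsets_s", "s2_onsets_s", "cycle_intervals_s",
                    "murmur_class") %in% names(gt)))
  # empty-count classes are simply absent
  m3 <- synthesize_dataset(c(stills = 0, none = 0, holosystolic = 3),
                           withr::local_tempdir(), seed = 1)
  expect_equal(nrow(m3), 3)
})

test_that("invalid synthesis parameters are rejected", {
  expect_error(synth_params(duration_s = -1), "positive")
  expect_error(synth_params(murmur_class = "squeak"), "arg")
  expect_error(synth_params(fs_hz = 1000), "2000")
  expect_error(synth_params(murmur_class = "stills", murmur_freq_hz = 250),
               "90")
})
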