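---
title: "Identifying Still's murmur in phonocardiograms: models and methods"
author: "stillsnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying Still's murmur in phonocardiograms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The clinical problem

Still's murmur is the most common innocent heart murmur of childhood: a
low-pitched, musical, early-to-mid systolic murmur best heard at the lower
left sternal border (LLSB). Because primary care providers distinguish it
from pathological murmurs far less reliably than pediatric cardiologists do,
many children with a benign Still's murmur are referred for specialist
consultation and echocardiography. A classifier that recognizes the
*obvious, typical* Still's murmur at the point of care can cull a large
share of these referrals without removing children with true heart disease
from the referral stream.

`stillsnet` frames this as a binary decision on a heart-sound recording
(phonocardiogram, PCG): **SM** (Still's murmur) versus **PPM** (potentially
pathological murmur). The conservative asymmetry is built in at every stage:
whenever the pipeline is uncertain — segmentation fails, a cycle vote ties,
a probability sits exactly on the threshold — the recording stays a referral
(PPM). Note the positive class is the *innocent* murmur, so "sensitivity"
here is the fraction of true Still's murmurs recognized as such, the reverse
of the convention in pathology-detection work.

## Pipeline

1. **Bandpass filter.** A 4th-order digital Butterworth bandpass with a
   40–500 Hz passband (half-power edges). Normal heart sounds occupy roughly
   20–200 Hz, Still's murmur 90–170 Hz, and pathological murmurs 80–500 Hz,
   so the band keeps everything informative while rejecting rumble and
   acquisition noise. The filter is designed by bilinear transform with
   prewarping and applied as cascaded second-order sections in a single
   causal forward pass. We deliberately do not use forward–backward
   filtering: that would square the magnitude response and double the
   effective order, while phase distortion is immaterial for envelope and
   spectrogram features.

2. **Segmentation** into cardiac cycles, defined as the half-open interval
   between the onsets of two consecutive S1 sounds, with the S2 onset as an
   interior landmark. Segmentation can *fail*, and failure is routed
   directly to a PPM decision with recording score 0 (see below).

3. **Featurization.** Each cycle becomes a fixed 55 × 129 spectrogram
   (time × frequency) of min–max-normalized decibel magnitudes.

4. **Cycle classification.** A small convolutional network maps each
   spectrogram to the probability that the cycle contains a Still's murmur.

5. **Recording decision.** Cycles are thresholded at 0.5 (strict) and the
   majority decides; ties go to PPM. The mean cycle probability serves as a
   continuous recording score for ROC analysis.

## Segmentation model

The lobe detector is a standard Shannon-energy construction: frames of
20 ms with 10 ms hop on the amplitude-normalized signal; per-frame average
Shannon energy $-\mathrm{mean}(x^2 \log x^2)$ (which emphasizes
medium-intensity components over both background noise and sharp spikes);
3-frame moving average; standardization to zero mean and unit variance.
Lobes are maximal runs above 0.5 SD, with runs closer than 50 ms merged and
runs shorter than 20 ms discarded.

S1/S2 identities come from interval statistics. The primary rule is
alternation: of the two alternating sets of inter-onset gaps, the shorter
set is systole (S1→S2), because systole is shorter than diastole at
pediatric heart rates. The assignment is accepted only when systolic gaps
are consistent (coefficient of variation < 0.25), systole is shorter than
diastole by at least a 5% margin (an exact tie is unassignable), and the
implied heart rate lies in 40–200 bpm.

A murmur that is audible *between* S1 and S2 — precisely the Still's case —
adds a third lobe per cycle and breaks alternation. Two deterministic
fallbacks handle this, tried in order and validated by actually building the
cycle partition:

* prune lobes below half the median peak energy and retry alternation
  (murmur lobes are usually weaker than the S1/S2 transients);
* estimate the cycle period from the envelope autocorrelation, walk the
  lobe sequence at that period from the strongest lobes to build the S1
  train, and take the last lobe strictly inside each cycle as S2 (systolic
  murmurs end before S2). The walk tolerates ±25% of a period, and the
  resulting period train must pass the same CV/heart-rate checks.

Failure semantics are first-class. A recording fails with
`envelope_saturated` when more than 70% of envelope frames exceed the
threshold, with `too_few_lobes`/`too_few_cycles` when fewer than 4 lobes or
3 complete cycles are found (a majority vote over fewer than 3 cycles is not
meaningful), and with `inconsistent_intervals` otherwise. Loud holosystolic
and continuous murmurs fill systole (or the whole cycle) with energy, so
their lobes merge into one near-uniform lobe per cycle and every assignment
candidate fails — which is the desired behavior, since at the LLSB such
murmurs are pathological: the failure itself carries diagnostic information
and the recording is classified PPM with score 0.

All thresholds above (0.5 SD detection, 50 ms merge, 20 ms minimum lobe,
CV < 0.25, 70% saturation, 3-cycle minimum, 5% tie margin, ±25% walk
tolerance) are exposed in the configuration; the values are the package's
own choices, validated against the synthetic cohorts described below.

## Featurization

The short-time Fourier transform uses a 256-sample Hann window with 75%
overlap at the 4 kHz working rate, zero-padded to `nfft = 256`, keeping the
one-sided spectrum of 129 = 256/2 + 1 bins over 0–2000 Hz. The frame count
grows with cycle duration, so the time axis is linearly resampled onto 55
equispaced points between the first and last frame; 55 × 129 is then the
fixed input shape of the CNN regardless of heart rate. After resampling
(order matters), magnitudes are converted to decibels with a 1e-10 floor and
min–max normalized to [0, 1] per spectrogram; a zero-range spectrogram maps
to all zeros. Per-spectrogram min–max (rather than corpus-level statistics)
makes the feature invariant to recording gain, which is arbitrary across
stethoscopes and patients; a positive gain changes the dB image by an
additive constant that the min–max removes (exactly, up to the 1e-10
floor).

## The cycle classifier

The network is intentionally small — the input is a coarse 55 × 129 grid
and the training sets are thousands, not millions, of cycles:

* three convolution stages: 3×3 kernels, "same" padding, ReLU, 2×2 max
  pooling, with 16/32/64 filters;
* two fully connected hidden layers of 64 units with ReLU;
* a single sigmoid output unit, read as the probability that the cycle
  contains a Still's murmur.

Training minimizes class-weighted binary cross-entropy
$-[w_1\, y \log p + w_0\, (1-y) \log(1-p)]$ with
$w_c = (n_1 + n_0) / (2 n_c)$, so each class contributes equal mass to the
loss regardless of imbalance; with balanced data the loss reduces to
standard cross-entropy. The optimizer is plain momentum SGD (momentum 0.9)
with an exponentially decayed learning rate
$\eta_e = \eta_0 \cdot 0.95^{\,e-1}$, $\eta_0 = 0.01$ by default. We treat
the momentum coefficient 0.9 as the canonical "0.9" of this setup; a raw
learning rate of 0.9 diverges on this loss surface. Both are configuration
fields, so either reading is runnable.

The input grid is centered by subtracting 0.5 before the first convolution
(the `input_center` config field). Min–max-normalized spectrograms have a
mean near 0.5 with strongly correlated pixels, and without centering the
early gradient is dominated by the constant (DC) direction: momentum SGD
then stalls for many epochs on a plateau at chance loss, for some
initializations never escaping within a short training run. Centering
removes that plateau — in our trials every initialization converged within
a few epochs once inputs were centered, while uncentered runs were
init-lottery.

The implementation is pure R on top of BLAS: convolutions are lowered to
matrix products via im2col with feature maps held channels-first, so the
heavy work runs in `dgemm` and the backward pass needs no array
permutations. Initialization is He-scaled Gaussian for ReLU layers (Glorot
for the output), and all randomness — initialization and epoch shuffling —
flows through named seeds, making training bit-reproducible. Backpropagation
is verified against central-difference numerical gradients in the test
suite.

Defaults: 50 epochs, batch size 32. The filter ladder (16/32/64), kernel and
pool sizes, epochs and batch size are the package's own choices (the
smallest conventional configuration that cleanly passes the synthetic
benchmark); all are exposed in `murmur_cnn_config()` /
`murmur_train_config()`.

## Decisions, metrics and evaluation

A cycle is SM iff $p > 0.5$ (strict; the boundary goes to PPM). A recording
is SM iff strictly more than half of its cycles vote SM; ties go to PPM. A
recording that failed segmentation is PPM with recording score 0, so it
enters ROC analysis at the bottom of the ranking. The recording score used
for the ROC sweep is the mean cycle probability; sweeping a threshold over
this score gives a proper (monotone) ROC, which the majority vote inside a
per-cycle threshold sweep would not.

Evaluation uses SM as the positive class: sensitivity $= 100\,tp/(tp+fn)$,
specificity $= 100\,tn/(tn+fp)$, accuracy over all evaluated recordings.
Reports come in two variants: over *all* recordings, and *excluding* those
that failed segmentation. The ROC is empirical (one point per distinct
score, ties grouped) and the AUC is the trapezoidal area, which equals the
pairwise concordance probability with ties counted one half — an identity
the tests exercise directly.

Cross-validation is stratified five-fold at the recording level: each fold
holds 20% of the Still's and 20% of the other recordings, every recording is
validated exactly once, and fold-level confusion counts are *pooled* (summed)
into the aggregate report, with per-fold reports retained. Four
training strategies select the data subset: all locations or LLSB only,
crossed with all recordings or murmur recordings only. An optional held-out
test path trains once and reports both metric variants plus per-recording
scores by true class.

## The synthetic phonocardiogram generator

Real pediatric murmur libraries with echocardiographic confirmation are not
publicly available, so the package ships a generator that emulates the
acoustic structure every pipeline stage depends on, with exact ground-truth
landmarks:

* **Beat grid.** Duration uniform on 7–15 s; heart rate uniform on
  60–140 bpm; beat-to-beat period jitter 3% (multiplicative Gaussian,
  truncated at 3 SD). Systole occupies $0.30\,T + 0.10$ s, capped at
  $0.45\,T$ — shorter than diastole at pediatric rates, which the segmenter
  exploits.
* **Heart sounds.** S1: ~80 ms damped oscillation at 35–90 Hz, amplitude 1;
  S2: ~60 ms at 50–140 Hz, amplitude 0.6; both with fast-attack,
  slower-decay Gaussian envelopes.
* **Murmurs.** Still's: a pure tone at a frequency drawn from 90–170 Hz
  with a triangular (diamond) envelope starting 30–50 ms after S1 onset and
  ending 20 ms before S2 — the early-to-mid systolic, musical profile.
  Holosystolic: 80–500 Hz band-limited noise with a near-constant envelope
  spanning S1→S2. Ejection: crescendo–decrescendo 150–400 Hz band noise
  peaking mid-systole. Continuous: band noise extending through S2 into
  diastole. Diastolic: decrescendo band noise after S2. Murmur amplitude
  relative to the S1 peak defaults to uniform on 0.2–0.8.
* **Noise.** White Gaussian (pink optional) scaled so the realized SNR
  equals the request exactly; default 20 dB. Optional artifact bursts.

The working rate is 4 kHz: pediatric electronic stethoscopes of the class
used for murmur libraries record at 4 kHz, and 2 kHz of bandwidth
comfortably covers the 40–500 Hz analysis band. Amplitude ratios among
S1, S2 and murmur are not published quantities; the defaults above are
stated assumptions, all exposed as parameters.

What the generator does *not* emulate: respiration modulation, multi-site
acoustic transfer (all synthetic recordings are nominally LLSB), atypical
murmur morphologies, pediatric arrhythmias, and real stethoscope handling
noise beyond the optional bursts. Consequently, passing the synthetic
benchmark demonstrates that the pipeline's machinery — segmentation with
failure routing, featurization, learning, voting, evaluation — works end to
end on acoustically faithful input; it is **not** evidence of clinical
performance on real recordings, whose variability is far richer.

## Numerical and design choices

* Half-open, 0-based time intervals in seconds everywhere; incomplete
  trailing cycles are dropped.
* The dB floor is 1e-10; degenerate (zero-range) normalization maps to
  zeros; $0 \log 0 := 0$ in the Shannon energy.
* Lobe onsets are reported at the first frame-start time of the run; with a
  10 ms hop this bounds the quantization error well inside the 30 ms
  accuracy budget.
* Ties: vote ties and boundary probabilities → PPM; equal alternating gap
  means (within 5%) → segmentation failure; equal pooled values in max
  pooling → gradient to the first maximum.
* Seeds are named per role (simulation, fold assignment, weight
  initialization, shuffling); derived seeds stay below $2^{31}$.
* Problem sizes in the shipped checks: the segmentation cohorts use 100
  normal/Still's and 50 loud holosystolic recordings; the end-to-end
  benchmark trains on 150 recordings (~1100–1300 cycles) and evaluates 50
  held-out recordings, training for 8 epochs, by which the loss has
  converged on this separable task across initializations.

## Known limitations

* The CNN trains on a single CPU thread through BLAS; at the default 50
  epochs on tens of thousands of cycles it would be slow compared to a GPU
  framework. The architecture is small enough that this is a practical, not
  fundamental, limit.
* The per-cycle threshold and the recording-score threshold coincide at the
  0.5 default but are distinct concepts; the ROC sweeps the recording-level
  score. Sweeping the per-cycle threshold inside the vote is also possible
  and gives a coarser, step-like curve.
* Patient-level grouping in cross-validation is available only implicitly
  (one recording per synthetic "patient"); real datasets with repeated
  patients should group folds by patient id.
* The generator's murmurs are stationary within a recording; beat-to-beat
  murmur variability is limited to the amplitude effect of period jitter.
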