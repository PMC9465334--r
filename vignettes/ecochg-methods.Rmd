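---
title: "Objective detection of cochlear microphonic responses: models and methods"
author: "ecochg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Objective detection of cochlear microphonic responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Intracochlear electrocochleography (ECochG) records sound-evoked inner-ear
potentials directly from the electrode array of a cochlear implant. The
dominant component, the cochlear microphonic (CM), follows the stimulus
waveform and — crucially — inverts when the acoustic stimulus polarity is
flipped. Recordings are therefore made in pairs: 100 stimulus-locked epochs
for a condensation (CON) and 100 for a rarefaction (RAR) pure-tone stimulus.
The difference potential DIF = (CON − RAR)/2 doubles the CM and cancels
polarity-neutral components; the sum SUM = (CON + RAR)/2 does the opposite.
Whether a recording contains a CM/DIF response is traditionally judged by
eye, which requires experience and is not reproducible across examiners.
This package implements three objective detectors for that dichotomous
question, the preprocessing they sit on, the evaluation statistics used to
compare them, and a synthetic-recording generator so that the whole chain is
testable with known ground truth.

## Signal model and the synthetic generator

`synthRecording()` models the CM as a gated pure tone at the stimulus
frequency $f$:

$$ s(t) = A \, g(t) \sin\!\big(2\pi f (t - \tau)\big), $$

where $\tau$ is the onset delay (default 1 ms, the recording delay of the
stimulation protocol), and $g(t)$ gates the tone to the stimulus duration
with 1 ms raised-cosine ramps. Condensation epochs carry $+s(t)$, rarefaction
epochs $-s(t)$, each plus white Gaussian noise (per-polarity SD `noiseSd`,
default 1 µV — amplitudes are nominal microvolts; the absolute scale of real
recordings varies greatly between subjects). Options add low-frequency
sinusoidal baseline wander (<20 Hz, random phase per epoch), outlier epochs,
and stitching steps. Stimulus-window settings (duration, delay, measurement
window, maximum level) follow the standard per-frequency protocol table;
sampling is 20 kHz so the 5 kHz analysis band edge sits well inside Nyquist.

Amplitude is calibrated to a target ensemble SNR by `amplitudeForSnr()`,
which inverts by bisection

$$ \mathrm{SNR}(A) = 10\log_{10}\frac{N\,\overline{s_A^2}}{\sigma^2/2}, $$

the expected plus–minus SNR of the raw DIF ensemble ($N$ epoch pairs; a DIF
epoch carries half the per-polarity noise variance). Dataset recipes
(`synthDataset()`) default to the mean per-frequency, per-level SNRs of the
labelled clinical reference cohort (supra/near/sub-threshold stimulation,
e.g. 4.41/2.62/2.37 dB at 500 Hz), with a 50/50 signal/noise mix per cell so
that sensitivity and specificity are both estimable.

What the generator deliberately does *not* model: hair-cell nonlinearity and
higher-harmonic neurophonic content, latency and morphology variability
across subjects, colored physiological background noise, and electrode-
dependent amplitude gradients. Synthetic benchmarks are therefore *easier*
than clinical data — at the reference SNRs all three detectors saturate near
AUC 1.0, where the clinical study found 0.85–0.97. Passing tests show the
chain is implemented correctly and behaves with the right directionality,
not that clinical performance would reach the same numbers.

## Preprocessing

The chain in `preprocessRecording()`, per polarity:

1. **Stitching removal.** Buffer-concatenation steps sit at the same sample
   in every epoch, so they are detected on the ensemble mean trace (first
   differences exceeding 8× the median absolute first difference — the
   constant is plumbing, exposed as `k`) and the step, estimated against
   the local median difference, is subtracted from every epoch from the
   discontinuity onward. Averaging across epochs suppresses the estimate's
   noise by $\sqrt{N}$.
2. **Gaussian-weighted screening.** Each epoch is replaced by a weighted
   mean of itself and its four neighbours with kernel
   $w(l) = \exp[-0.5\,(l/(\sigma\,(5-1)/2))^2]$, $l=-2..2$, $\sigma=0.4$
   (weights ≈ 0.044, 0.458, 1, 0.458, 0.044). The printed kernel has no
   normalization; we divide by the sum of the weights actually used so
   amplitudes stay on the original microvolt scale, and truncate/renormalize
   at the ensemble edges so the epoch count is preserved (the exclusion
   cap's percentages assume it).
3. **Exclusion.** Each weighted epoch is correlated with the mean of all
   epochs; epochs with Pearson r < −0.2 are excluded, at most
   `floor(0.1 N)` of them (the worst-correlated first). Zero-variance
   epochs have undefined correlation and are scored r = 0. The −0.2
   threshold only removes strongly anti-correlated sweeps; uncorrelated
   noise epochs (r ≈ 0) pass it by design.
4. **Pairing.** Both polarities are pruned to the common retained epoch
   index set, so CON/RAR shapes stay equal and DIF pairing is well defined.
5. **Band-pass.** Zero-phase (forward–backward) 2nd-order Butterworth,
   100 Hz–5 kHz for the objective path (10 Hz–5 kHz for visual display).
   Filter design comes from `signal::butter`; the forward–backward pass is
   implemented in-package with odd-reflection padding and steady-state
   initial conditions, because the measurement windows are short (6.5–19.1
   ms) and naive zero-padded filtering distorts in-band amplitudes by tens
   of percent at the edges.

**Which ensemble feeds the detectors.** The sliding five-epoch kernel makes
adjacent *weighted* epochs strongly correlated (lag-1 r ≈ 0.67). Feeding
those rows to a one-sample Hotelling test would violate its i.i.d.-rows
assumption and push the type-I error far above nominal, and the
alternating-sign (±) noise estimate would collapse on across-epoch-smoothed
data. The weighted ensemble is therefore used only as the *screening
instrument* for exclusion — weighting raises per-epoch SNR so large
anti-phase artifact sweeps reveal themselves — while the Hotelling matrix,
the buffer-split correlation, the DIF/SUM epochs and the ± SNR all consume
the retained, unweighted, band-passed epochs. This design choice is what
makes the detector's nominal calibration testable (and tested).

**SNR estimation.** `snrPlusMinus()` is the Schimmel-style estimator: the
plain ensemble average holds signal plus residual noise, the
alternating-sign average ($+1,-1,+1,\dots$ across epochs) holds residual
noise only; $\mathrm{SNR} = 10\log_{10}[(P_{tot}-P_{noise})/P_{noise}]$,
reported saturated at a 60 dB cap when the noise estimate vanishes.

## The Hotelling detector

`buildTVM()` partitions the measurement window into Q contiguous windows
(boundaries at `round(jT/Q)`; every sample belongs to exactly one window)
and takes each window's mean voltage — the time-voltage means (TVMs). Rows
of the N×Q matrix are the CON epochs stacked on the *sign-flipped* RAR
epochs (N = 200 at the standard protocol). Stacking both polarities is the
package's resolution of an ambiguity: a 100-row per-polarity matrix cannot
support the documented Q sweep up to 195 (the covariance would be singular
beyond Q = 99), while the stacked construction both supports it and makes
the no-response null exactly a zero mean vector (the CM inverts with
polarity; everything polarity-neutral cancels in expectation after
band-passing).

`hotellingT2()` computes the one-sample statistic
$T^2 = N\,\bar{x}^\top S^{-1} \bar{x}$ against the zero vector, referred to
an $F(Q, N-Q)$ distribution via $F = T^2 (N-Q)/(Q(N-1))$, with detection at
$\alpha = 0.01$. With Q = 1 it reduces to the squared one-sample t — one of
the oracle identities in the test suite, alongside a sign-flip permutation
oracle for the p-value itself.

`tuneQ()` sweeps Q from 5 to 195 in steps of 5 (values exceeding N−1 or the
sample count are skipped with a warning) and picks, per stimulus frequency,
the Q maximizing training accuracy of the `p < α` decision; ties go to the
smallest Q (fewer parameters, more error dof). The shipped per-frequency
defaults (250→90, 500→80, 750→100, 1000→85, 1500→105, 2000→100) are the
values tuned on the clinical reference cohort. Too-long windows average out
the CM's peaks and valleys; too-short windows overfit — the tuned optimum
sits between.

## The correlation detector

`corrBufferSplit()` measures repeatability: per repetition, CON epochs are
randomly split into two 50-epoch buffers and RAR epochs into two more; each
buffer is averaged and the Pearson correlations of the two CON means and
the two RAR means are averaged into CORR. The random split is repeated 100
times and averaged into the final coefficient. The polarities are kept
separate because their responses evolve inversely. Odd epoch counts leave
one random epoch out per repetition, keeping the two buffer means
identically distributed; zero-variance buffer means score r = 0. A logistic
regression (`fitCorrClassifier()`, maximum likelihood via `glm`) maps the
coefficient to a response probability, thresholded at 0.5; on separable
training data, where the ML estimate diverges, the classifier falls back to
a flagged midpoint threshold rule.

## The scalogram classifier

`cwtScalogram()` renders the averaged DIF trace as a time-frequency image:
an analytic Morlet wavelet (centre frequency $\omega_0 = 6$, the
conventional compromise between time and frequency resolution) evaluated by
FFT over 64 log-spaced scales whose pseudo-frequencies
(Torrence–Compo relation) cover the 100 Hz–5 kHz analysis band. The
magnitude is min–max normalized per image (an all-zero trace stays an
all-zero image, flagged, rather than dividing by a zero range), resampled
to 224×224 with `EBImage::resize`, and replicated across three channels —
replication rather than a colormap, since a colormap would inject an
arbitrary nonlinearity.

The classifier interface is pluggable. The default, fully supported
backbone is a compact convolutional network operating on a 7×7 block-mean
reduction of the scalogram (32×32): two convolutional layers (5×5×8 and
3×3×16, ReLU, 2×2 max-pooling) and two dense layers (576→32→1, sigmoid),
trained with minibatch SGD with momentum on the binary cross-entropy
(batch 8, up to 25 epochs, momentum 0.9), with stratified 10-fold
cross-validation available to detect overfitting before the final
full-data fit. The `"large-pretrained"` backbone slot mirrors the
transfer-learning variant (a large ImageNet-pretrained image classifier
with its last layers replaced for binary output, fine-tuned at learning
rate 1e-4); it requires user-supplied weights and a compatible backend and
is not bundled. Because a freshly initialized compact network barely moves
at a fine-tuning rate within 25 epochs, the default learning rate is
resolved per backbone: 1e-4 for fine-tuning, 0.05 for the compact net.
Training, fold assignment and initialization are all deterministic given
the configuration seed.

## Evaluation stack

`confusionMetrics()` reports accuracy, sensitivity and specificity with a
95% normal-approximation half-width for accuracy (the CI method is an
assumption; the reference tables print symmetric half-widths without naming
one). `rocAuc()` sweeps the empirical ROC over unique score thresholds —
ties move diagonally — so the trapezoidal area equals the Mann–Whitney
statistic; Hotelling scores enter as 1 − p (the test reports p-values, not
probabilities). `delongTest()` implements the placement-value DeLong
comparison of two correlated AUCs, one-sided by default; a self-comparison
returns p = 0.5 exactly. `fleissKappa()` implements the standard
chance-corrected multi-rater agreement, with the degenerate all-unanimous
case reported as undefined. `consensusLabel()` encodes the two-round
labelling protocol: unanimity decides; a 2-of-3 split triggers a
re-presented second round decided by unanimity; one or zero positives
decide noise without a second round. How a *persistent* 2-of-3 split after
re-presentation was resolved is not documented in the protocol; the package
scores it as noise (unanimity or nothing), which is the conservative
reading.

`runBenchmark()` wires it together: a 70/30 split stratified by frequency ×
label, all tuning on the training split only, metrics and pairwise DeLong
comparisons on the test split only, with an identifier-disjointness guard
against leakage.

## Numerical choices and problem sizes

- Container format: one plain-text file per recording (JSON header,
  `%.17g` voltage rows) — lossless for IEEE doubles, diffable, portable.
- Covariance solves use Cholesky factorization; a singular covariance
  (Q too large) is reported as an actionable error. The Q-sweep exploits
  the linearity of window averaging: the TVM covariance for every Q is a
  block average of one full T×T sample covariance.
- The zero-phase filter pads by odd reflection (3× filter length) and
  initializes both passes at the steady-state response to the first padded
  sample.
- Test and acceptance problem sizes are chosen to exercise the transition
  regions at desk scale: type-I calibration on 5,000 noise recordings
  (99% binomial CI around α = 0.01), the detector benchmark on 600
  recordings at the three reference SNR levels, power monotonicity over a
  −20…+10 dB grid (60 replicates per point) where both statistical
  detectors actually transition from chance to saturation, and the
  SNR-improvement direction on 200 ensembles with 15% coherent anti-phase
  artifact epochs at 3× amplitude in clear-response (12 dB) recordings —
  the regime the r < −0.2 rule is designed for: at the printed threshold,
  only artifacts that are both large and anti-phase are excludable at all.

## Known limitations

- The compact CNN is a deliberately small CPU-sized network; it is not a
  reproduction of a large pretrained backbone, and no trained weights ship
  with the package.
- The synthetic noise is white and Gaussian; real recordings carry colored
  noise, drift and system artifacts beyond the stitching/wander/outlier
  models here, so absolute synthetic performance overstates clinical
  performance.
- Exclusion screening cannot catch uncorrelated (r ≈ 0) outlier epochs —
  a property of the printed threshold, preserved intentionally.
- Only CM/DIF detection is implemented; the neurophonic/summating
  components (ANN/SUM, CAP, SP) are out of scope.
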