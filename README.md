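# ecochg

Objective, examiner-independent detection of cochlear microphonic (CM/DIF)
responses in intracochlear electrocochleography (ECochG).

## The problem

ECochG records sound-evoked inner-ear potentials directly from a cochlear
implant's electrode array and is increasingly used to monitor residual
inner-ear function during and after implantation. The dominant component,
the cochlear microphonic (CM), follows the stimulus waveform and inverts
with acoustic stimulus polarity, so recordings are made as paired epoch
ensembles — typically 100 condensation (CON) and 100 rarefaction (RAR)
sweeps of a pure tone (250–2,000 Hz). The difference potential
DIF = (CON − RAR)/2 emphasizes the CM; whether a recording contains a
CM/DIF response at all is usually judged visually, which demands expert
experience and is not reproducible across examiners. This package replaces
that judgement with objective detectors, for clinicians and researchers who
need standardized, immediate, reproducible answers (including in the
operating theatre).

## What is inside

- **Preprocessing** (`preprocessRecording()`): stitching-step removal,
  Gaussian-weighted epoch screening
  (`w(l) = exp[-0.5 (l/(σ(5-1)/2))²]`, σ = 0.4, five epochs under the
  kernel) with correlation-based exclusion (r < −0.2, capped at 10% of
  epochs), zero-phase 2nd-order Butterworth band-pass (100 Hz–5 kHz
  objective path), DIF/SUM derivation and plus–minus (±) SNR estimation.
- **Hotelling detector** (`buildTVM()`, `hotellingT2()`, `tuneQ()`): the
  epoch matrix is reduced to Q time-voltage means (TVMs) per epoch and the
  one-sample statistic `T² = N x̄ᵀ S⁻¹ x̄` is tested against the zero
  (noise) vector via `F = T²(N−Q)/(Q(N−1)) ~ F(Q, N−Q)` at α = 0.01; Q is
  tuned per stimulus frequency (defaults 250→90, 500→80, 750→100, 1000→85,
  1500→105, 2000→100).
- **Correlation detector** (`corrBufferSplit()`, `fitCorrClassifier()`):
  CON and RAR are each randomly split into two 50-epoch buffers, buffer
  means are correlated, the split is repeated 100 times and averaged into a
  final coefficient read out by a logistic model.
- **Scalogram classifier** (`cwtScalogram()`, `trainClassifier()`,
  `kfoldCV()`): Morlet CWT scalograms (224×224×3) classified by a compact
  convolutional network trained with SGD with momentum (batch 8, ≤25
  epochs), with stratified 10-fold cross-validation.
- **Evaluation** (`confusionMetrics()`, `rocAuc()`, `delongTest()`,
  `fleissKappa()`, `consensusLabel()`, `runBenchmark()`): confusion
  metrics, ROC/AUC (Mann–Whitney-consistent), one-sided paired DeLong AUC
  comparison, multi-rater agreement, two-round consensus labelling, and a
  leakage-guarded 70/30 benchmark runner.
- **Synthetic generator** (`synthRecording()`, `synthDataset()`,
  `injectArtifacts()`): polarity-inverting gated-tone CM at calibrated SNR,
  white noise, baseline wander, outlier epochs and stitching steps — known
  ground truth for every downstream stage.

See `vignettes/ecochg-methods.Rmd` for the models, assumptions and design
decisions, and `inst/cli/ecochg.R` for a command-line wrapper
(`simulate | preprocess | detect | tune-q | evaluate`).

## Worked example

```r
library(ecochg)

stim   <- stimulusSpec(500, thresholdCategory = "supra")
params <- synthesisParams(stim, cmAmplitude = amplitudeForSnr(4.41), seed = 7)
rec    <- synthRecording(params, recordingId = "demo")
rec
#> ECochGRecording 'demo' (intraoperative, electrode 1)
#>   500 Hz stimulus, 100 epochs/polarity x 192 samples @ 20000 Hz
#>   ground truth: CM present

pre <- preprocessRecording(rec)    # screen, exclude, band-pass 100 Hz-5 kHz
deriveDifSum(pre)
#> DerivedResponse 'demo': 100 DIF epochs x 192 samples
#>   plus-minus SNR: 6.59 dB | 0 epoch pair(s) excluded

ht <- hotellingDetect(pre, Q = 80)
sprintf("Hotelling T2 = %.1f, p = %.3g, detected = %s",
        ht$statistic, ht$p.value, ht$detected)
#> "Hotelling T2 = 1112.3, p = 7.47e-25, detected = TRUE"

corrBufferSplit(pre, seed = 7)
#> Split-buffer correlation 'demo': corr coeff = 0.581 (100 reps)
```

The recording was synthesized at the 500 Hz supra-threshold reference SNR
(4.41 dB): the Hotelling test rejects the zero-mean (noise) hypothesis
decisively and the split-buffer coefficient sits far above the noise level.
A noise-only control (`cmAmplitude = 0`) gives `p = 0.954` and a
coefficient of `-0.024` — no detection:

```r
noise <- preprocessRecording(synthRecording(
  synthesisParams(stim, cmAmplitude = 0, seed = 8)))
hotellingDetect(noise, Q = 80)$p.value   #> 0.954
corrBufferSplit(noise, seed = 8)$corrCoeff  #> -0.024
```

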