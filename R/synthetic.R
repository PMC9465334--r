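## Synthetic ECochG recordings with known ground truth.
##
## The cochlear microphonic is modelled as a gated pure tone at the stimulus
## frequency that inverts with acoustic polarity; noise is white Gaussian
## with optional low-frequency baseline wander. Amplitudes are nominal
## microvolts. The generator exists so that every downstream stage is
## testable end-to-end without clinical data.

## Mean per-frequency plus-minus SNR (dB) of the labelled clinical cohort by
## stimulation level, used as default targets for dataset recipes.
.snrTargets <- data.frame(
  frequency = rep(c(250, 500, 750, 1000, 1500, 2000), each = 3),
  category  = rep(c("supra", "near", "sub"), times = 6),
  snr_dB    = c(2.68, 2.32, 2.28,
                4.41, 2.62, 2.37,
                4.20, 2.80, 2.41,
                5.64, 2.95, 2.38,
                3.98, 2.40, 2.30,
                4.24, 2.40, 2.42)
)

#' Reference SNR targets by frequency and stimulation level
#'
#' Mean plus-minus SNR values (dB) by stimulus frequency and stimulation
#' level (supra-, near-, sub-threshold) used as default targets when
#' synthesizing datasets with [synthDataset()].
#'
#' @return A data.frame with columns `frequency`, `category`, `snr_dB`.
#' @export
snrTargets <- function() .snrTargets

#' The gated cochlear-microphonic waveform template
#'
#' A pure tone at the stimulus frequency, gated to the stimulus duration with
#' 1 ms raised-cosine onset/offset ramps and delayed by the recording delay.
#' This is the deterministic component `s(t)` that the condensation polarity
#' carries as `+s` and the rarefaction polarity as `-s`.
#'
#' @param stim a [StimulusSpec-class].
#' @param samplingRate sampling rate in Hz.
#' @param amplitude peak amplitude in microvolts.
#' @param onsetDelay onset delay in ms (default: the stimulus recording
#'   delay).
#' @return Numeric vector with one value per sample of the measurement
#'   window.
#' @export
cmWaveform <- function(stim, samplingRate, amplitude = 1,
                       onsetDelay = stim@recordingDelay) {
  dur <- stim@stimulusDuration
  if (onsetDelay + dur > stim@measurementWindow + 1e-9)
    stop("onset delay + stimulus duration exceed the measurement window")
  nS <- windowSamples(stim, samplingRate)
  t <- (seq_len(nS) - 1) / samplingRate * 1000  # ms
  env <- numeric(nS)
  ramp <- min(1, dur / 2)  # 1 ms raised-cosine ramps
  inGate <- t >= onsetDelay & t <= onsetDelay + dur
  env[inGate] <- 1
  up <- inGate & t < onsetDelay + ramp
  env[up] <- 0.5 * (1 - cos(pi * (t[up] - onsetDelay) / ramp))
  down <- inGate & t > onsetDelay + dur - ramp
  env[down] <- 0.5 * (1 - cos(pi * (onsetDelay + dur - t[down]) / ramp))
  amplitude * env * sin(2 * pi * stim@frequency * (t - onsetDelay) / 1000)
}

#' Synthesis parameters for one recording
#'
#' Bundles and validates the knobs of the synthetic generator. Defaults
#' reflect the recording protocol the generator emulates: 100 epochs per
#' polarity, 20 kHz sampling (the 5 kHz band-pass edge sits well inside
#' Nyquist), 1 ms onset delay, white Gaussian noise of 1 microvolt SD, no
#' wander or artifacts.
#'
#' @param stimulus a [StimulusSpec-class].
#' @param cmAmplitude CM peak amplitude in microvolts; 0 means noise-only
#'   (ground truth "absent").
#' @param cmOnsetDelay CM onset delay in ms.
#' @param noiseSd white-noise SD in microvolts.
#' @param wanderAmplitude,wanderFrequency optional sinusoidal baseline wander
#'   (microvolts, Hz; random phase per epoch).
#' @param outlierFraction fraction (0..0.5) of epochs per polarity replaced
#'   by uncorrelated higher-variance noise.
#' @param outlierNoiseScale SD multiplier of outlier-epoch noise.
#' @param stitchAmplitude,stitchSample optional step discontinuity added to
#'   every epoch at a sample index (microvolts; 0 disables).
#' @param nEpochs epochs per polarity (>= 4).
#' @param samplingRate Hz.
#' @param seed integer seed for a deterministic recording, or `NULL`.
#' @return A validated list of class `"synthesisParams"`.
#' @export
synthesisParams <- function(stimulus = stimulusSpec(500), cmAmplitude = 1,
                            cmOnsetDelay = stimulus@recordingDelay,
                            noiseSd = 1, wanderAmplitude = 0,
                            wanderFrequency = 10, outlierFraction = 0,
                            outlierNoiseScale = 3, stitchAmplitude = 0,
                            stitchSample = NA_integer_, nEpochs = 100,
                            samplingRate = 20000, seed = NULL) {
  stopifnot(is(stimulus, "StimulusSpec"))
  if (nEpochs < 4) stop("nEpochs must be at least 4")
  if (cmAmplitude < 0) stop("cmAmplitude must be non-negative")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  if (outlierFraction < 0 || outlierFraction > 0.5)
    stop("outlierFraction must lie in [0, 0.5]")
  if (cmOnsetDelay + stimulus@stimulusDuration >
      stimulus@measurementWindow + 1e-9)
    stop("cmOnsetDelay + stimulus duration exceed the measurement window")
  if (wanderFrequency >= 20)
    warning("baseline wander is meant to be a <20 Hz phenomenon")
  structure(list(stimulus = stimulus, cmAmplitude = cmAmplitude,
                 cmOnsetDelay = cmOnsetDelay, noiseSd = noiseSd,
                 wanderAmplitude = wanderAmplitude,
                 wanderFrequency = wanderFrequency,
                 outlierFraction = outlierFraction,
                 outlierNoiseScale = outlierNoiseScale,
                 stitchAmplitude = stitchAmplitude,
                 stitchSample = stitchSample, nEpochs = nEpochs,
                 samplingRate = samplingRate, seed = seed),
            class = "synthesisParams")
}

#' Synthesize one ECochG recording
#'
#' Generates paired condensation/rarefaction epoch ensembles: every
#' condensation epoch is `s(t) + noise`, every rarefaction epoch
#' `-s(t) + noise`, with `s(t)` the gated CM template of [cmWaveform()].
#' Optional baseline wander, outlier epochs and a stitching step are added
#' per the parameters. Deterministic for a fixed seed.
#'
#' @param params a [synthesisParams()] object.
#' @param recordingId identifier for the new recording.
#' @param electrode,timing recording metadata.
#' @return An [ECochGRecording-class] with `groundTruth = (cmAmplitude > 0)`.
#' @export
synthRecording <- function(params, recordingId = "synthetic",
                           electrode = 1L, timing = "intraoperative") {
  stopifnot(inherits(params, "synthesisParams"))
  p <- params
  s <- cmWaveform(p$stimulus, p$samplingRate, p$cmAmplitude, p$cmOnsetDelay)
  nS <- length(s)
  nE <- p$nEpochs
  withSeed(p$seed, {
    makeEnsemble <- function(sign) {
      m <- matrix(rnorm(nE * nS, sd = p$noiseSd), nrow = nE)
      if (p$wanderAmplitude > 0) {
        t <- (seq_len(nS) - 1) / p$samplingRate
        phase <- runif(nE, 0, 2 * pi)
        m <- m + p$wanderAmplitude *
          sin(outer(phase, 2 * pi * p$wanderFrequency * t, `+`))
      }
      m <- m + rep(sign * s, each = nE)
      k <- floor(p$outlierFraction * nE)
      if (k > 0) {
        idx <- sample.int(nE, k)
        m[idx, ] <- matrix(rnorm(k * nS, sd = p$noiseSd * p$outlierNoiseScale),
                           nrow = k)
      }
      if (p$stitchAmplitude != 0) {
        if (is.na(p$stitchSample) || p$stitchSample < 1 || p$stitchSample > nS)
          stop("stitchSample out of range")
        m[, p$stitchSample:nS] <- m[, p$stitchSample:nS] + p$stitchAmplitude
      }
      m
    }
    conM <- makeEnsemble(+1)
    rarM <- makeEnsemble(-1)
    ecochgRecording(
      con = epochMatrix(conM, p$samplingRate, "CON"),
      rar = epochMatrix(rarM, p$samplingRate, "RAR"),
      stimulus = p$stimulus, recordingId = recordingId,
      electrode = electrode, timing = timing,
      groundTruth = p$cmAmplitude > 0,
      meta = list(cm_amplitude = p$cmAmplitude, noise_sd = p$noiseSd))
  })
}

#' CM amplitude that realizes a target plus-minus SNR
#'
#' Inverts the expected plus-minus SNR of the raw difference-potential
#' ensemble, `SNR(A) = 10 log10( nEpochs * mean(s_A(t)^2) / (noiseSd^2 / 2) )`,
#' by bisection on the amplitude `A`. The difference epoch of a pair is
#' `(CON - RAR)/2 = s + (n1 - n2)/2`, so its noise variance is half the
#' per-polarity variance; averaging `nEpochs` difference epochs divides the
#' residual noise power by `nEpochs`, which is exactly what the plus-minus
#' estimator measures.
#'
#' @param targetSnrDb target SNR in dB.
#' @param stim a [StimulusSpec-class].
#' @param noiseSd per-polarity white-noise SD (microvolts).
#' @param nEpochs epochs per polarity.
#' @param samplingRate Hz.
#' @return Amplitude in microvolts.
#' @export
amplitudeForSnr <- function(targetSnrDb, stim = stimulusSpec(500),
                            noiseSd = 1, nEpochs = 100,
                            samplingRate = 20000) {
  g <- mean(cmWaveform(stim, samplingRate, 1)^2)
  if (g <= 1e-9)
    stop("unreachable SNR target: the gated template has no support ",
         "inside this measurement window")
  snrOf <- function(a) 10 * log10(nEpochs * a^2 * g / (noiseSd^2 / 2))
  lo <- 1e-9; hi <- 1
  while (snrOf(hi) < targetSnrDb) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (snrOf(mid) < targetSnrDb) lo <- mid else hi <- mid
    if (hi - lo < 1e-12 * hi) break
  }
  (lo + hi) / 2
}

#' Synthesize a labelled dataset from a recipe
#'
#' A recipe is a data.frame with one row per cell: columns `frequency`,
#' `category` (`"supra"`, `"near"`, `"sub"`), `n` (recordings in the cell)
#' and optionally `snr_dB` (target SNR of the signal class; defaults to the
#' [snrTargets()] value for the cell) and `signal_fraction` (fraction of the
#' cell carrying a CM, default 0.5). Signal amplitudes are calibrated with
#' [amplitudeForSnr()]; noise-class recordings use `cmAmplitude = 0`. A label
#' table with a single consensus rater `"truth"` is emitted alongside.
#'
#' @param recipe recipe data.frame (see Details).
#' @param noiseSd,nEpochs,samplingRate generator settings shared by all
#'   recordings.
#' @param seed integer seed; the dataset is fully reproducible given the
#'   seed.
#' @return A list with `recordings` (list of [ECochGRecording-class]),
#'   `labels` (data.frame in [readLabels()] layout) and `manifest`
#'   (data.frame with per-recording frequency, category, target SNR, ground
#'   truth and realized raw-DIF SNR).
#' @export
synthDataset <- function(recipe, noiseSd = 1, nEpochs = 100,
                         samplingRate = 20000, seed = NULL) {
  stopifnot(is.data.frame(recipe), all(c("frequency", "category", "n") %in%
                                       names(recipe)))
  recordings <- list()
  manifest <- list()
  idx <- 0L
  for (r in seq_len(nrow(recipe))) {
    freq <- recipe$frequency[r]
    cat_ <- recipe$category[r]
    n <- recipe$n[r]
    sfrac <- if ("signal_fraction" %in% names(recipe))
      recipe$signal_fraction[r] else 0.5
    tgt <- if ("snr_dB" %in% names(recipe) && !is.na(recipe$snr_dB[r]))
      recipe$snr_dB[r]
    else {
      hit <- .snrTargets$snr_dB[.snrTargets$frequency == freq &
                                .snrTargets$category == cat_]
      if (!length(hit)) stop("no default SNR target for ", freq, "/", cat_)
      hit
    }
    stim <- stimulusSpec(freq, thresholdCategory = cat_)
    amp <- amplitudeForSnr(tgt, stim, noiseSd, nEpochs, samplingRate)
    nSig <- round(sfrac * n)
    for (i in seq_len(n)) {
      idx <- idx + 1L
      a <- if (i <= nSig) amp else 0
      id <- sprintf("syn-%04d", idx)
      rec <- synthRecording(
        synthesisParams(stim, cmAmplitude = a, noiseSd = noiseSd,
                        nEpochs = nEpochs, samplingRate = samplingRate,
                        seed = childSeed(seed, idx)),
        recordingId = id)
      recordings[[id]] <- rec
      drv <- deriveDifSum(rec)
      manifest[[id]] <- data.frame(
        recording_id = id, frequency = freq, category = cat_,
        target_snr_dB = if (a > 0) tgt else NA_real_,
        ground_truth = a > 0, realized_snr_dB = drv@snrDb)
    }
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  labels <- data.frame(recording_id = manifest$recording_id,
                       rater_id = "truth", round = 1L,
                       response_present = manifest$ground_truth)
  list(recordings = recordings, labels = labels, manifest = manifest)
}

#' Inject artifacts into an existing recording
#'
#' Adds the defects the preprocessing chain exists to fix: `"stitching"` adds
#' a step discontinuity of the given amplitude at the given sample to every
#' epoch of both polarities; `"outlier_epochs"` replaces a fraction of epochs
#' per polarity either with uncorrelated noise (`mode = "noise"`) or with
#' coherent anti-phase artifact sweeps (`mode = "sign_flip"`): scaled
#' sign-flipped copies of the ensemble mean plus residual-level noise, the
#' large anti-correlated epochs that the correlation-based exclusion rule
#' targets. Pure-noise outliers sit near r = 0 and are deliberately *not*
#' excludable by the r < -0.2 rule.
#'
#' @param rec an [ECochGRecording-class].
#' @param kind `"stitching"` or `"outlier_epochs"`.
#' @param amplitude step amplitude in microvolts (stitching).
#' @param sample sample index of the step (stitching).
#' @param fraction fraction of epochs per polarity to replace (outliers);
#'   exactly `floor(fraction * nEpochs)` epochs are replaced.
#' @param mode `"noise"` or `"sign_flip"` (outliers).
#' @param scale amplitude multiplier of sign-flipped artifact epochs.
#' @param noiseScale SD multiplier for `mode = "noise"` relative to the
#'   ensemble residual SD.
#' @param seed integer seed for the epoch selection / noise draws.
#' @return The modified [ECochGRecording-class].
#' @export
injectArtifacts <- function(rec, kind = c("stitching", "outlier_epochs"),
                            amplitude = 50, sample = NULL, fraction = 0.1,
                            mode = c("noise", "sign_flip"), scale = 3,
                            noiseScale = 2, seed = NULL) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  conM <- rec@con@samples
  rarM <- rec@rar@samples
  nS <- ncol(conM)
  nE <- nrow(conM)
  if (kind == "stitching") {
    if (is.null(sample) || sample < 1 || sample > nS)
      stop("stitching sample index out of range (1..", nS, ")")
    if (amplitude != 0) {
      conM[, sample:nS] <- conM[, sample:nS] + amplitude
      rarM[, sample:nS] <- rarM[, sample:nS] + amplitude
    }
  } else {
    k <- floor(fraction * nE)
    withSeed(seed, {
      for (pol in c("con", "rar")) {
        m <- if (pol == "con") conM else rarM
        if (k > 0) {
          idx <- sample.int(nE, k)
          template <- colMeans(m)
          resid <- m - rep(template, each = nE)
          if (mode == "sign_flip") {
            m[idx, ] <- rep(-scale * template, each = k) +
              matrix(rnorm(k * nS, sd = sd(resid)), nrow = k)
          } else {
            m[idx, ] <- matrix(rnorm(k * nS, sd = noiseScale * sd(resid)),
                               nrow = k)
          }
          if (pol == "con") conM <- m else rarM <- m
        }
      }
    })
  }
  rec@con@samples <- conM
  rec@rar@samples <- rarM
  rec@meta$injected <- c(rec@meta$injected, kind)
  rec
}
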