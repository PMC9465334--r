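## Morlet continuous wavelet transform rendered as a fixed-size image.
##
## Analytic Morlet wavelet with centre frequency omega0 = 6 (the
## conventional choice balancing time and frequency resolution); the CWT is
## evaluated by frequency-domain multiplication, |W| is taken over a
## log-spaced scale grid whose pseudo-frequencies (Torrence-Compo relation
## lambda = 4 pi s / (omega0 + sqrt(2 + omega0^2))) cover the analysis band,
## min-max normalized per image and resampled to 224 x 224, replicated over
## three channels.

.morletCwt <- function(x, nScales, omega0, freqRange, samplingRate) {
  nS <- length(x)
  m <- 2^ceiling(log2(2 * nS))        # zero-pad to reduce wrap-around
  xf <- fft(c(x, numeric(m - nS)))
  omega <- 2 * pi * seq(0, m - 1) / m # per-sample angular frequency
  pos <- omega <= pi
  fourierFactor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  ## scale s (samples) with pseudo-frequency f: f = fs / (s * fourierFactor)
  freqs <- exp(seq(log(freqRange[2]), log(freqRange[1]),
                   length.out = nScales))
  scales <- samplingRate / (freqs * fourierFactor)
  W <- matrix(0, nScales, nS)
  for (i in seq_len(nScales)) {
    s <- scales[i]
    psi <- numeric(m)
    psi[pos] <- pi^(-0.25) * sqrt(s) * exp(-0.5 * (s * omega[pos] - omega0)^2)
    w <- fft(xf * psi, inverse = TRUE) / m
    W[i, ] <- Mod(w[seq_len(nS)])
  }
  list(W = W, freqs = freqs)
}

#' Morlet CWT scalogram of a DIF trace
#'
#' Computes the continuous wavelet transform magnitude of an averaged
#' difference-potential trace over a log-spaced scale grid covering the
#' analysis band, min-max normalizes it, resamples to 224 x 224 and
#' replicates the result across three channels, producing the image the
#' convolutional classifier consumes. An all-zero trace yields an all-zero
#' image (flagged) rather than dividing by a zero range.
#'
#' @param trace numeric waveform (at least 64 samples), typically
#'   [difTrace()] of a [DerivedResponse-class].
#' @param samplingRate Hz.
#' @param nScales number of log-spaced scales before resampling (default
#'   64).
#' @param omega0 Morlet centre frequency (default 6).
#' @param freqRange pseudo-frequency coverage in Hz (default
#'   `c(100, 5000)`, the objective band-pass).
#' @param recordingId identifier carried into the scalogram.
#' @return A [Scalogram-class].
#' @export
cwtScalogram <- function(trace, samplingRate, nScales = 64, omega0 = 6,
                         freqRange = c(100, 5000), recordingId = "") {
  if (length(trace) < 64) stop("trace must have at least 64 samples")
  res <- .morletCwt(as.numeric(trace), nScales, omega0, freqRange,
                    samplingRate)
  W <- res$W
  rng <- range(W)
  allZero <- rng[2] <= 0
  Wn <- if (allZero) W else (W - rng[1]) / (rng[2] - rng[1])
  img224 <- EBImage::resize(Wn, w = 224, h = 224)
  img224 <- pmin(pmax(img224, 0), 1)  # clamp resampling overshoot
  new("Scalogram",
      image = array(rep(img224, 3), dim = c(224L, 224L, 3L)),
      wavelet = "morlet", scaleFreqs = res$freqs,
      recordingId = as.character(recordingId), allZero = allZero)
}

#' Scalogram for one recording
#'
#' Preprocess-and-transform convenience: derives the DIF trace of a
#' (preprocessed) recording and returns its [cwtScalogram()].
#'
#' @param rec an [ECochGRecording-class] (preprocessed) or a
#'   [DerivedResponse-class].
#' @param ... passed to [cwtScalogram()].
#' @return A [Scalogram-class].
#' @export
recordingScalogram <- function(rec, ...) {
  drv <- if (is(rec, "DerivedResponse")) rec else deriveDifSum(rec)
  cwtScalogram(drv@difTrace, drv@samplingRate,
               recordingId = drv@recordingId, ...)
}
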