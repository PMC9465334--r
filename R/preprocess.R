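## The preprocessing chain for one recording, per polarity:
##   stitching-artifact removal -> Gaussian-weighted epoch screening ->
##   correlation-based exclusion (r < -0.2, capped at 10%) -> zero-phase
##   band-pass (100 Hz - 5 kHz objective path) -> DIF/SUM derivation and
##   plus-minus SNR.
##
## The Gaussian-weighted ensemble is the *screening instrument*: weighting
## across neighbouring epochs raises the per-epoch SNR so that artifact
## epochs reveal themselves by their anti-correlation with the ensemble
## mean. Because the sliding kernel correlates adjacent weighted epochs
## (lag-1 r ~ 0.67), the weighted ensemble is not handed to the detectors:
## the Hotelling test assumes independent rows and the alternating-sign
## noise estimate collapses on across-epoch-smoothed data. All downstream
## statistics therefore consume the retained, unweighted, band-passed
## epochs.

#' Gaussian epoch-weighting kernel
#'
#' The five-epoch weight kernel
#' `w(l) = exp(-0.5 * (l / (sigma * (5 - 1) / 2))^2)` for `l = -span..span`,
#' symmetric with maximum 1 at `l = 0`. With the default `sigma = 0.4` the
#' weights are approximately (0.0439, 0.4578, 1, 0.4578, 0.0439).
#'
#' @param sigma unitless SD of the Gaussian window (> 0), default 0.4.
#' @param span half-width of the kernel in epochs (default 2, i.e. five
#'   epochs under the window).
#' @return Numeric vector of length `2 * span + 1`, unnormalized.
#' @export
gaussianWeights <- function(sigma = 0.4, span = 2L) {
  if (sigma <= 0) stop("sigma must be positive")
  if (span < 1) stop("span must be at least 1")
  l <- seq(-span, span)
  exp(-0.5 * (l / (sigma * (2 * span) / 2))^2)
}

#' Gaussian-weighted epochs
#'
#' Replaces each epoch by the normalized weighted mean of itself and its
#' neighbours under the Gaussian kernel of [gaussianWeights()]. At the
#' ensemble edges the kernel is truncated to the available neighbours and
#' renormalized, so the output epoch count equals the input count. The
#' normalization by the sum of used weights keeps amplitudes on the original
#' microvolt scale.
#'
#' @param epochs an [EpochMatrix-class] or matrix with at least 5 epochs.
#' @param sigma,span kernel parameters, see [gaussianWeights()].
#' @return Same kind of object as `epochs`, smoothed across the epoch axis.
#' @export
gaussianWeightedEpochs <- function(epochs, sigma = 0.4, span = 2L) {
  X <- if (is(epochs, "EpochMatrix")) epochs@samples else as.matrix(epochs)
  n <- nrow(X)
  if (n < 2L * span + 1L)
    stop("need at least ", 2L * span + 1L, " epochs for the weighted average")
  w <- gaussianWeights(sigma, span)
  W <- matrix(0, n, n)
  for (l in seq(-span, span)) {
    i <- seq_len(n)
    j <- i + l
    ok <- j >= 1L & j <= n
    W[cbind(i[ok], j[ok])] <- w[l + span + 1L]
  }
  W <- W / rowSums(W)
  Y <- W %*% X
  if (is(epochs, "EpochMatrix")) {
    epochs@samples <- Y
    epochs
  } else Y
}

#' Exclude epochs anti-correlated with the ensemble mean
#'
#' Correlates every (weighted) epoch with the mean of all epochs and drops
#' epochs with Pearson `r` below the threshold. If more sub-threshold epochs
#' exist than the cap `floor(maxFraction * N)`, only the worst-correlated
#' cap-many are discarded. Zero-variance epochs have undefined correlation
#' and are treated as `r = 0` (never excluded by the default threshold).
#'
#' @param weighted an [EpochMatrix-class] or matrix of (typically
#'   Gaussian-weighted) epochs, at least 5.
#' @param threshold exclusion threshold on Pearson r (default -0.2).
#' @param maxFraction cap on the excluded fraction (default 0.1).
#' @return A list with `kept` (same kind as input, retained epochs),
#'   `excluded` (integer indices into the input) and `r` (per-epoch
#'   correlations).
#' @export
excludeUncorrelated <- function(weighted, threshold = -0.2,
                                maxFraction = 0.1) {
  X <- if (is(weighted, "EpochMatrix")) weighted@samples else
    as.matrix(weighted)
  n <- nrow(X)
  if (n < 5L) stop("need at least 5 epochs")
  sApprox <- colMeans(X)
  r <- suppressWarnings(as.vector(cor(t(X), sApprox)))
  bad <- !is.finite(r)
  if (any(bad)) {
    message(sum(bad), " zero-variance epoch(s): correlation undefined, ",
            "treated as r = 0")
    r[bad] <- 0
  }
  below <- which(r < threshold)
  cap <- floor(maxFraction * n)
  excluded <- if (length(below) > cap)
    below[order(r[below])][seq_len(cap)] else below
  excluded <- sort(excluded)
  keptX <- if (length(excluded)) X[-excluded, , drop = FALSE] else X
  kept <- if (is(weighted, "EpochMatrix")) {
    weighted@samples <- keptX
    weighted
  } else keptX
  list(kept = kept, excluded = excluded, r = r)
}

#' Remove stitching artifacts (step discontinuities)
#'
#' Stitching artifacts are step discontinuities introduced where recording
#' buffers are concatenated, so they sit at the same sample in every epoch.
#' They are detected on the ensemble mean trace as first differences
#' exceeding `k` times the median absolute first difference; each step is
#' estimated against the local median difference (averaging across epochs
#' suppresses the noise of the estimate by `sqrt(N)`) and subtracted from
#' every epoch from the discontinuity onward. Clean ensembles pass through
#' unchanged.
#'
#' @param epochs an [EpochMatrix-class] or matrix.
#' @param k detection multiplier on the median absolute first difference
#'   (default 8).
#' @return Same kind of object as `epochs`, with detected steps removed.
#' @export
removeStitchingArtifacts <- function(epochs, k = 8) {
  X <- if (is(epochs, "EpochMatrix")) epochs@samples else as.matrix(epochs)
  nS <- ncol(X)
  d <- diff(colMeans(X))
  m <- median(abs(d))
  if (m <= 0) m <- mean(abs(d))
  if (m > 0) {
    hits <- which(abs(d) > k * m)
    for (j in hits) {
      lo <- max(1L, j - 10L)
      hi <- min(nS - 1L, j + 10L)
      nb <- setdiff(lo:hi, hits)
      step <- d[j] - if (length(nb)) median(d[nb]) else 0
      X[, (j + 1L):nS] <- X[, (j + 1L):nS] - step
    }
  }
  if (is(epochs, "EpochMatrix")) {
    epochs@samples <- X
    epochs
  } else X
}

#' Plus-minus SNR of an epoch ensemble
#'
#' Schimmel-style estimator: the plain ensemble average carries signal plus
#' residual noise, while the alternating-sign average (`+1, -1, +1, ...`
#' over epochs) cancels the stimulus-locked component and retains only
#' residual noise of the same power. The SNR in dB is
#' `10 log10((P_total - P_noise) / P_noise)` with `P_total` the mean power
#' of the plain average and `P_noise` that of the alternating average. When
#' the noise estimate vanishes (identical epochs) the estimate saturates at
#' `cap` and is flagged.
#'
#' @param epochs an [EpochMatrix-class] or matrix with at least 2 epochs.
#' @param cap reporting cap in dB (default 60).
#' @return A list with `snrDb`, `saturated`, `pTotal`, `pNoise`.
#' @export
snrPlusMinus <- function(epochs, cap = 60) {
  X <- if (is(epochs, "EpochMatrix")) epochs@samples else as.matrix(epochs)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 epochs")
  avg <- colMeans(X)
  signs <- rep_len(c(1, -1), n)
  pm <- colMeans(X * signs)
  pTotal <- mean(avg^2)
  pNoise <- mean(pm^2)
  eps <- .Machine$double.eps
  if (pNoise <= eps * max(pTotal, 1)) {
    return(list(snrDb = cap, saturated = TRUE, pTotal = pTotal,
                pNoise = pNoise))
  }
  snr <- 10 * log10(max(pTotal - pNoise, eps * pNoise) / pNoise)
  if (snr >= cap)
    list(snrDb = cap, saturated = TRUE, pTotal = pTotal, pNoise = pNoise)
  else
    list(snrDb = snr, saturated = FALSE, pTotal = pTotal, pNoise = pNoise)
}

#' Derive DIF/SUM responses from a recording
#'
#' Pairs condensation and rarefaction epochs by index and forms the
#' difference epochs `(CON_i - RAR_i)/2` (which carry the polarity-inverting
#' cochlear microphonic) and sum epochs `(CON_i + RAR_i)/2` (which cancel
#' it). Traces are the means over epochs; the recording's SNR is the
#' plus-minus estimate of the difference ensemble.
#'
#' @param rec an [ECochGRecording-class], typically the output of
#'   [preprocessRecording()].
#' @return A [DerivedResponse-class].
#' @export
deriveDifSum <- function(rec) {
  stopifnot(is(rec, "ECochGRecording"))
  conM <- rec@con@samples
  rarM <- rec@rar@samples
  dif <- (conM - rarM) / 2
  sum_ <- (conM + rarM) / 2
  snr <- snrPlusMinus(dif)
  new("DerivedResponse",
      difTrace = colMeans(dif), sumTrace = colMeans(sum_),
      difEpochs = dif, samplingRate = samplingRate(rec),
      snrDb = snr$snrDb, snrSaturated = snr$saturated,
      nExcluded = as.integer(rec@meta$nPairsExcluded %||% 0L),
      stimulus = rec@stimulus, recordingId = rec@recordingId)
}

#' Run the full preprocessing chain on a recording
#'
#' Per polarity: removes stitching steps, forms the Gaussian-weighted
#' screening ensemble, excludes epochs whose weighted version is
#' anti-correlated with the ensemble mean (threshold and cap per
#' [excludeUncorrelated()]), prunes both polarities to the common retained
#' epoch index set, and band-pass filters the retained raw epochs. The
#' returned recording holds detector-ready epochs; exclusion bookkeeping is
#' stored in its `meta` list (`excludedCon`, `excludedRar`,
#' `nPairsExcluded`).
#'
#' @param rec an [ECochGRecording-class].
#' @param band two cutoffs in Hz; `c(100, 5000)` is the objective detection
#'   path, `c(10, 5000)` the visual-display path.
#' @param order band-pass prototype order (default 2).
#' @param sigma,span Gaussian screening kernel parameters.
#' @param threshold,maxFraction exclusion parameters.
#' @param removeStitching logical; run step-discontinuity removal first.
#' @return A preprocessed [ECochGRecording-class].
#' @seealso [deriveDifSum()], [buildTVM()], [corrBufferSplit()]
#' @export
preprocessRecording <- function(rec, band = c(100, 5000), order = 2,
                                sigma = 0.4, span = 2L, threshold = -0.2,
                                maxFraction = 0.1, removeStitching = TRUE) {
  stopifnot(is(rec, "ECochGRecording"))
  nE <- nEpochs(rec)
  screen <- function(em) {
    if (removeStitching) em <- removeStitchingArtifacts(em)
    weighted <- gaussianWeightedEpochs(em, sigma = sigma, span = span)
    excl <- excludeUncorrelated(weighted, threshold = threshold,
                                maxFraction = maxFraction)
    list(clean = em, excluded = excl$excluded)
  }
  sc <- screen(rec@con)
  sr <- screen(rec@rar)
  keep <- setdiff(seq_len(nE), union(sc$excluded, sr$excluded))
  if (length(keep) < 4L)
    stop("fewer than 4 epoch pairs survive exclusion")
  conM <- sc$clean@samples[keep, , drop = FALSE]
  rarM <- sr$clean@samples[keep, , drop = FALSE]
  out <- rec
  out@con@samples <- bandpassFilter(conM, band[1], band[2], order,
                                    samplingRate = samplingRate(rec))
  out@rar@samples <- bandpassFilter(rarM, band[1], band[2], order,
                                    samplingRate = samplingRate(rec))
  out@meta$excludedCon <- sc$excluded
  out@meta$excludedRar <- sr$excluded
  out@meta$nPairsExcluded <- nE - length(keep)
  out@meta$preprocessed <- TRUE
  out@meta$band <- band
  out
}
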