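# shared fixtures, built in code

quickRecording <- function(cmAmplitude = 1, seed = 1, nEpochs = 30,
                           frequency = 500, noiseSd = 1,
                           samplingRate = 20000, ...) {
  synthRecording(synthesisParams(stimulusSpec(frequency),
                                 cmAmplitude = cmAmplitude,
                                 noiseSd = noiseSd, nEpochs = nEpochs,
                                 samplingRate = samplingRate, seed = seed,
                                 ...),
                 recordingId = sprintf("fix-%d", seed))
}

## scalograms of gated-tone traces (signal) vs pure-noise traces, cheap to
## build because they skip the full recording pipeline
toneScalograms <- function(n, amplitude, noiseSd = 0.1, seedBase = 0,
                           frequency = 500, samplingRate = 20000) {
  stim <- stimulusSpec(frequency)
  lapply(seq_len(n), function(i) {
    set.seed(seedBase + i)
    s <- cmWaveform(stim, samplingRate, amplitude)
    tr <- s + rnorm(length(s), sd = noiseSd)
    cwtScalogram(tr, samplingRate, recordingId = sprintf("sg-%d", i))
  })
}

## independent oracle: logistic regression by direct likelihood optimization
logisticOracle <- function(x, y) {
  nll <- function(b) {
    eta <- b[1] + b[2] * x
    sum(log1p(exp(eta))) - sum(eta[y])
  }
  optim(c(0, 0), nll, method = "BFGS",
        control = list(maxit = 1000, reltol = 1e-14))$par
}

## independent oracle: Fleiss' kappa from the pairwise-agreement definition
fleissOracle <- function(ratings) {
  nR <- ncol(ratings)
  cats <- sort(unique(as.vector(ratings)))
  ## observed: fraction of agreeing rater pairs, averaged over items
  pairAgree <- apply(ratings, 1, function(row) {
    pairs <- combn(nR, 2)
    mean(row[pairs[1, ]] == row[pairs[2, ]])
  })
  ## expected: marginal category shares
  pj <- vapply(cats, function(cc) mean(ratings == cc), numeric(1))
  (mean(pairAgree) - sum(pj^2)) / (1 - sum(pj^2))
}
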