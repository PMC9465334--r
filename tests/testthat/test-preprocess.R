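test_that("the Gaussian kernel matches its closed form", {
  w <- gaussianWeights(sigma = 0.4)
  expect_equal(w[3], 1)
  expect_equal(w[2], exp(-0.78125), tolerance = 1e-12)
  expect_equal(w[4], exp(-0.78125), tolerance = 1e-12)
  expect_equal(w[1], exp(-3.125), tolerance = 1e-12)
  expect_equal(unname(w[2]), 0.45783, tolerance = 1e-4)
  expect_equal(unname(w[1]), 0.04394, tolerance = 1e-4)
  expect_identical(w, rev(w))
  expect_error(gaussianWeights(sigma = 0), "positive")
})

test_that("weighted averaging preserves constants, linear trends and the mean", {
  X <- matrix(3.7, 10, 20)
  expect_equal(gaussianWeightedEpochs(X), X, tolerance = 1e-14)

  # linear ramp across epochs: the symmetric kernel preserves interior rows
  ramp <- matrix(rep(1:20, 5), 20, 5)
  sm <- gaussianWeightedEpochs(ramp)
  expect_equal(sm[3:18, ], ramp[3:18, ], tolerance = 1e-12)

  set.seed(1)
  X <- matrix(rnorm(100 * 50), 100, 50)
  sm <- gaussianWeightedEpochs(X)
  # ensemble mean nearly unchanged (edge renormalization only)
  expect_lt(max(abs(colMeans(sm) - colMeans(X))), 0.01)
  expect_error(gaussianWeightedEpochs(X[1:4, ]), "at least 5")
})

test_that("weighted white noise has the analytic variance of a weighted mean", {
  w <- gaussianWeights(0.4)
  ratio <- sum(w^2) / sum(w)^2          # 0.35452 for sigma = 0.4
  expect_equal(ratio, 0.35452, tolerance = 1e-4)
  set.seed(2)
  X <- matrix(rnorm(600 * 120), 600, 120)
  sm <- gaussianWeightedEpochs(X)
  v <- mean(apply(sm[3:598, ], 1, var))
  expect_equal(v, ratio, tolerance = 0.03)
})

test_that("exclusion drops anti-correlated epochs and respects the 10% cap", {
  t <- sin(2 * pi * (1:100) / 25)
  mk <- function(nFlip, seed) {
    set.seed(seed)
    X <- matrix(rep(t, each = 100), 100) + matrix(rnorm(100 * 100, sd = 0.2),
                                                  100)
    X[seq_len(nFlip), ] <- -X[seq_len(nFlip), ]
    X
  }
  # 15 below threshold -> exactly the 10 worst discarded
  X <- mk(15, 3)
  res <- excludeUncorrelated(X)
  expect_equal(length(res$excluded), 10)
  expect_true(all(res$excluded %in% 1:15))
  expect_equal(res$excluded, sort(order(res$r)[1:10]))
  expect_equal(nrow(res$kept), 90)

  # 7 below threshold -> exactly those 7
  res7 <- excludeUncorrelated(mk(7, 4))
  expect_equal(sort(res7$excluded), 1:7)

  # all positively correlated -> none excluded
  res0 <- excludeUncorrelated(mk(0, 5))
  expect_equal(length(res0$excluded), 0)
})

test_that("exclusion never removes more than floor(0.1 N) epochs", {
  t <- sin(2 * pi * (1:60) / 15)
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(20:120, 1)
    nFlip <- sample.int(n %/% 2, 1)
    X <- matrix(rep(t, each = n), n) + matrix(rnorm(n * 60, sd = 0.3), n)
    X[seq_len(nFlip), ] <- -X[seq_len(nFlip), ]
    res <- excludeUncorrelated(X)
    expect_lte(length(res$excluded), floor(0.1 * n))
  }
})

test_that("zero-variance epochs are scored r = 0 and kept", {
  t <- sin(2 * pi * (1:50) / 10)
  X <- matrix(rep(t, each = 10), 10) + 0.1
  X[4, ] <- 0
  expect_message(res <- excludeUncorrelated(X), "zero-variance")
  expect_equal(res$r[4], 0)
  expect_equal(length(res$excluded), 0)
})

test_that("the band-pass removes DC and passes the band with zero phase", {
  fs <- 20000
  # DC is outside the passband
  dc <- matrix(1, 2, 192)
  expect_lt(max(abs(bandpassFilter(dc, samplingRate = fs))), 1e-6)

  # steady-state response to an in-band tone: amplitude within 5%, no lag
  t <- seq_len(4096) / fs
  x <- sin(2 * pi * 500 * t)
  y <- drop(bandpassFilter(rbind(x), samplingRate = fs))
  mid <- 1024:3072
  fit <- lm(y[mid] ~ sin(2 * pi * 500 * t[mid]) + cos(2 * pi * 500 * t[mid]))
  amp <- sqrt(sum(coef(fit)[2:3]^2))
  phase <- atan2(coef(fit)[3], coef(fit)[2])
  expect_equal(amp, 1, tolerance = 0.05)
  expect_equal(unname(phase), 0, tolerance = 0.01)

  # symmetric compact pulse in, symmetric pulse out (zero-phase property)
  n <- 512
  pulse <- exp(-((seq_len(n) - (n + 1) / 2)^2) / 50)
  pulse <- pulse - mean(pulse)
  yp <- drop(bandpassFilter(rbind(pulse), samplingRate = fs))
  expect_lt(max(abs(yp - rev(yp))), 0.02 * max(abs(yp)))
})

test_that("the band-pass is idempotent in the passband within 1%", {
  fs <- 20000
  t <- seq_len(4096) / fs
  x <- rbind(sin(2 * pi * 500 * t) + 0.5 * sin(2 * pi * 1500 * t))
  y1 <- bandpassFilter(x, samplingRate = fs)
  y2 <- bandpassFilter(y1, samplingRate = fs)
  mid <- 1024:3072
  expect_lt(max(abs(y2[mid] - y1[mid])), 0.01 * max(abs(y1[mid])))
})

test_that("cutoffs at or above Nyquist are rejected", {
  X <- matrix(rnorm(8 * 100), 8)
  expect_error(bandpassFilter(X, 100, 10000, samplingRate = 20000),
               "Nyquist")
  expect_error(bandpassFilter(X, 5000, 100, samplingRate = 20000),
               "low < high")
})

test_that("plus-minus SNR saturates on identical epochs and is negative on noise", {
  s <- sin(2 * pi * (1:64) / 16)
  same <- matrix(rep(s, each = 10), 10)
  res <- snrPlusMinus(same)
  expect_true(res$saturated)
  expect_equal(res$snrDb, 60)

  set.seed(3)
  snrs <- vapply(1:1000, function(i)
    snrPlusMinus(matrix(rnorm(100 * 64), 100))$snrDb, numeric(1))
  expect_lt(mean(snrs), 0)

  expect_error(snrPlusMinus(matrix(0, 1, 10)), "at least 2")
})

test_that("the plus-minus estimator is nearly unbiased at a 4.18 dB operating point", {
  # scale the template so the true ensemble SNR is 4.18 dB
  s <- sin(2 * pi * (1:192) / 40)
  n <- 100
  a <- sqrt(10^(4.18 / 10) / n / mean(s^2))
  set.seed(4)
  est <- vapply(1:500, function(i) {
    X <- matrix(rnorm(n * 192), n) + rep(a * s, each = n)
    snrPlusMinus(X)$snrDb
  }, numeric(1))
  expect_equal(mean(est), 4.18, tolerance = 0.5)
})

test_that("stitching removal is a no-op on clean epochs", {
  rec <- quickRecording(seed = 8, nEpochs = 10)
  cleaned <- removeStitchingArtifacts(rec@con)
  expect_identical(cleaned@samples, rec@con@samples)
})

test_that("the full chain prunes polarities consistently and keeps bookkeeping", {
  rec <- quickRecording(cmAmplitude = amplitudeForSnr(12), seed = 9,
                        nEpochs = 50)
  rec <- injectArtifacts(rec, "outlier_epochs", fraction = 0.1,
                         mode = "sign_flip", scale = 3, seed = 10)
  pre <- preprocessRecording(rec)
  expect_identical(dim(pre@con@samples), dim(pre@rar@samples))
  expect_true(pre@meta$preprocessed)
  expect_equal(nrow(pre@con@samples) + pre@meta$nPairsExcluded, 50)
  drv <- deriveDifSum(pre)
  expect_equal(nExcluded(drv), pre@meta$nPairsExcluded)
})

test_that("screening plus exclusion raises the SNR of contaminated ensembles", {
  improved <- vapply(1:25, function(i) {
    rec <- synthRecording(synthesisParams(
      stimulusSpec(500), cmAmplitude = amplitudeForSnr(12),
      nEpochs = 100, seed = 400 + i))
    rec <- injectArtifacts(rec, "outlier_epochs", fraction = 0.15,
                           mode = "sign_flip", scale = 3, seed = 500 + i)
    raw <- snrPlusMinus(difEpochs(deriveDifSum(rec)))$snrDb
    snrDb(deriveDifSum(preprocessRecording(rec))) > raw
  }, logical(1))
  expect_gte(mean(improved), 0.95)
})
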