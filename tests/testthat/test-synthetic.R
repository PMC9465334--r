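test_that("generation is deterministic under a fixed seed", {
  p <- synthesisParams(stimulusSpec(750), cmAmplitude = 2, noiseSd = 1.5,
                      wanderAmplitude = 0.5, outlierFraction = 0.1,
                      nEpochs = 20, seed = 42)
  r1 <- synthRecording(p)
  r2 <- synthRecording(p)
  expect_identical(r1@con@samples, r2@con@samples)
  expect_identical(r1@rar@samples, r2@rar@samples)
})

test_that("polarity algebra: noise-free DIF equals the template, SUM is zero", {
  p <- synthesisParams(stimulusSpec(500), cmAmplitude = 5, noiseSd = 0,
                      nEpochs = 10, seed = 1)
  rec <- synthRecording(p)
  s <- cmWaveform(stimulusSpec(500), 20000, 5)
  drv <- deriveDifSum(rec)
  expect_equal(difTrace(drv), s, tolerance = 1e-14)
  expect_equal(max(abs(sumTrace(drv))), 0, tolerance = 1e-14)
  expect_true(groundTruth(rec))
})

test_that("a zero-amplitude recording is unbiased noise with false ground truth", {
  p <- synthesisParams(stimulusSpec(500), cmAmplitude = 0, nEpochs = 100,
                      seed = 7)
  rec <- synthRecording(p)
  expect_false(groundTruth(rec))
  drv <- deriveDifSum(rec)
  # mean DIF trace should hover around zero at sd/sqrt(2 n)
  expect_lt(max(abs(difTrace(drv))), 5 / sqrt(2 * 100))
})

test_that("the ensemble mean converges to the template at the 1/sqrt(n) rate", {
  stim <- stimulusSpec(500)
  s <- cmWaveform(stim, 20000, 1)
  rmse <- vapply(c(100, 10000), function(n) {
    rec <- synthRecording(synthesisParams(stim, cmAmplitude = 1, noiseSd = 1,
                                          nEpochs = n, seed = 11))
    sqrt(mean((difTrace(deriveDifSum(rec)) - s)^2))
  }, numeric(1))
  # 100x the epochs: rmse should shrink about 10-fold
  expect_gt(rmse[1] / rmse[2], 5)
  expect_lt(rmse[1] / rmse[2], 20)
})

test_that("the SUM trace cancels the polarity-inverting component", {
  rec <- synthRecording(synthesisParams(stimulusSpec(500), cmAmplitude = 3,
                                        noiseSd = 1, nEpochs = 100,
                                        seed = 13))
  drv <- deriveDifSum(rec)
  expect_lt(sqrt(mean(sumTrace(drv)^2)), 3 * 1 / sqrt(100))
})

test_that("realized SNR is monotone in amplitude and matches calibration targets", {
  snrAt <- function(a)
    snrDb(deriveDifSum(synthRecording(synthesisParams(
      stimulusSpec(500), cmAmplitude = a, noiseSd = 1, seed = 21))))
  snrs <- vapply(c(0.05, 0.1, 0.2, 0.4), snrAt, numeric(1))
  expect_true(all(diff(snrs) > 0))

  # reference-cohort target: 500 Hz supra-threshold, 4.41 dB
  ds <- synthDataset(data.frame(frequency = 500, category = "supra",
                                n = 10, signal_fraction = 1), seed = 5)
  expect_equal(mean(ds$manifest$realized_snr_dB), 4.41, tolerance = 1)
})

test_that("dataset recipes label noise-only rows false and are reproducible", {
  recipe <- data.frame(frequency = c(500, 1000), category = "near",
                       n = c(4, 4), signal_fraction = 0)
  d1 <- synthDataset(recipe, seed = 9)
  d2 <- synthDataset(recipe, seed = 9)
  expect_false(any(d1$manifest$ground_truth))
  expect_false(any(d1$labels$response_present))
  expect_identical(d1$manifest$realized_snr_dB, d2$manifest$realized_snr_dB)
  expect_identical(d1$recordings[[1]]@con@samples,
                   d2$recordings[[1]]@con@samples)
})

test_that("outlier injection replaces exactly the requested count", {
  rec <- quickRecording(seed = 3, nEpochs = 100)
  out <- injectArtifacts(rec, "outlier_epochs", fraction = 0.15,
                         mode = "noise", seed = 4)
  changed <- rowSums(out@con@samples != rec@con@samples) > 0
  expect_equal(sum(changed), 15)
  changedR <- rowSums(out@rar@samples != rec@rar@samples) > 0
  expect_equal(sum(changedR), 15)
})

test_that("stitching injection of amplitude zero is the identity", {
  rec <- quickRecording(seed = 5, nEpochs = 8)
  same <- injectArtifacts(rec, "stitching", amplitude = 0, sample = 60)
  expect_identical(same@con@samples, rec@con@samples)
  expect_error(injectArtifacts(rec, "stitching", amplitude = 5,
                               sample = 10000), "out of range")
})

test_that("injected stitching steps are removed to under 1% residual", {
  rec <- quickRecording(cmAmplitude = 1, seed = 6, nEpochs = 100,
                        noiseSd = 0.5)
  dirty <- injectArtifacts(rec, "stitching", amplitude = 50, sample = 60)
  cleaned <- removeStitchingArtifacts(dirty@con)
  resid <- cleaned@samples - rec@con@samples
  expect_lt(max(abs(resid)), 0.01 * 50)

  # two steps per epoch, both corrected
  dirty2 <- injectArtifacts(dirty, "stitching", amplitude = -30,
                            sample = 130)
  cleaned2 <- removeStitchingArtifacts(dirty2@con)
  resid2 <- cleaned2@samples - rec@con@samples
  expect_lt(max(abs(resid2)), 0.02 * 50)
})

test_that("parameter validation catches impossible settings", {
  expect_error(synthesisParams(stimulusSpec(500), outlierFraction = 0.6),
               "outlierFraction")
  expect_error(synthesisParams(stimulusSpec(500), cmAmplitude = -1),
               "cmAmplitude")
  expect_error(synthesisParams(stimulusSpec(500), nEpochs = 3), "nEpochs")
  expect_error(synthesisParams(stimulusSpec(500), cmOnsetDelay = 5),
               "exceed the measurement window")
  # 500 Hz sampled at exactly 1 kHz aliases the template to zero support
  expect_error(amplitudeForSnr(5, stimulusSpec(500), samplingRate = 1000),
               "unreachable")
})
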