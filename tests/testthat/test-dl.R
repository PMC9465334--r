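test_that("scalograms are shape-stable across all stimulus windows", {
  fs <- 20000
  for (f in c(250, 500, 750, 1000, 1500, 2000)) {
    stim <- stimulusSpec(f)
    tr <- cmWaveform(stim, fs, 1)
    sg <- cwtScalogram(tr, fs)
    expect_identical(dim(sg@image), c(224L, 224L, 3L))
    expect_gte(min(sg@image), 0)
    expect_lte(max(sg@image), 1)
  }
  expect_error(cwtScalogram(rnorm(32), fs), "at least 64")
})

test_that("an all-zero trace maps to an all-zero image, flagged", {
  sg <- cwtScalogram(numeric(192), 20000)
  expect_true(sg@allZero)
  expect_equal(max(abs(sg@image)), 0)
})

test_that("a pure tone peaks at the scale matching its frequency", {
  fs <- 20000
  tr <- sin(2 * pi * 500 * seq_len(1024) / fs)
  res <- ecochg:::.morletCwt(tr, 64, 6, c(100, 5000), fs)
  rowEnergy <- rowSums(res$W[, 300:700]^2)  # steady-state region
  peak <- which.max(rowEnergy)
  target <- which.min(abs(res$freqs - 500))
  expect_lte(abs(peak - target), 1)
})

test_that("a gated tone concentrates energy in the gated columns", {
  fs <- 20000
  stim <- stimulusSpec(500)  # 8 ms gate in a 9.6 ms window
  tr <- cmWaveform(stim, fs, 1)
  res <- ecochg:::.morletCwt(tr, 64, 6, c(100, 5000), fs)
  gate <- seq_len(length(tr)) / fs * 1000
  inGate <- gate >= stim@recordingDelay &
    gate <= stim@recordingDelay + stim@stimulusDuration
  expect_gte(sum(res$W[, inGate]^2) / sum(res$W^2), 0.9)
})

test_that("analytic and numeric CNN gradients agree", {
  set.seed(1)
  x <- rnorm(1024, sd = 0.5)
  y <- 1
  w <- ecochg:::.cnnInit()
  fw <- ecochg:::.cnnForward(w, x, keep = TRUE)
  gr <- ecochg:::.cnnBackward(w, fw, y)
  loss <- function(wmod) {
    p <- ecochg:::.cnnForward(wmod, x)
    -(y * log(p) + (1 - y) * log(1 - p))
  }
  h <- 1e-5
  for (nm in c("W1", "W2", "W3", "W4", "b2", "b3")) {
    idx <- sample(length(w[[nm]]), 3)
    for (j in idx) {
      wp <- w; wp[[nm]][j] <- wp[[nm]][j] + h
      wm <- w; wm[[nm]][j] <- wm[[nm]][j] - h
      num <- (loss(wp) - loss(wm)) / (2 * h)
      expect_equal(gr[[nm]][j], num, tolerance = 1e-4)
    }
  }
})

test_that("separable scalogram classes are learned within 25 epochs", {
  sgs <- c(toneScalograms(40, amplitude = 1, seedBase = 0),
           toneScalograms(40, amplitude = 0, seedBase = 100))
  labels <- rep(c(TRUE, FALSE), each = 40)
  model <- trainClassifier(sgs, labels, trainConfig(seed = 5))
  hist <- model$history
  expect_gte(hist$accuracy[nrow(hist)], 0.95)

  # re-predicting the training items matches the bookkeeping direction
  prd <- predict(model, sgs)
  expect_gte(mean(prd$detected == labels), 0.95)

  # duplicated inputs give duplicated outputs
  dup <- predict(model, sgs[c(1, 1, 2)])
  expect_identical(dup$probability[1], dup$probability[2])

  # and higher-amplitude scalograms score at least as high on average
  hi <- predict(model, toneScalograms(20, 1.5, seedBase = 300))$probability
  lo <- predict(model, toneScalograms(20, 0.2, seedBase = 300))$probability
  expect_gte(mean(hi), mean(lo))
})

test_that("training is deterministic given a seed", {
  sgs <- c(toneScalograms(10, 1, seedBase = 40),
           toneScalograms(10, 0, seedBase = 60))
  labels <- rep(c(TRUE, FALSE), each = 10)
  cfg <- trainConfig(maxEpochs = 3, seed = 9)
  m1 <- trainClassifier(sgs, labels, cfg)
  m2 <- trainClassifier(sgs, labels, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history, m2$history)
})

test_that("configuration is validated and the pretrained backbone is gated", {
  cfg <- trainConfig()
  expect_equal(cfg$batchSize, 8L)
  expect_equal(cfg$maxEpochs, 25L)
  expect_equal(cfg$momentum, 0.9)
  expect_equal(trainConfig(backbone = "large-pretrained")$learningRate, 1e-4)
  expect_error(trainConfig(folds = 1), "folds")
  sgs <- c(toneScalograms(3, 1, seedBase = 70),
           toneScalograms(3, 0, seedBase = 80))
  expect_error(trainClassifier(sgs, rep(c(TRUE, FALSE), each = 3),
                               trainConfig(backbone = "large-pretrained")),
               "user-supplied weights")
  expect_error(trainClassifier(sgs, rep(TRUE, 6)), "both classes")
  m <- trainClassifier(sgs, rep(c(TRUE, FALSE), each = 3),
                       trainConfig(maxEpochs = 1, seed = 1))
  expect_error(predict(m, matrix(0, 2, 100)), "shape mismatch")
})

test_that("cross-validation partitions items and flags label noise", {
  sgs <- c(toneScalograms(30, 1, seedBase = 200),
           toneScalograms(30, 0, seedBase = 250))
  labels <- rep(c(TRUE, FALSE), each = 30)
  cfg <- trainConfig(maxEpochs = 6, folds = 5, seed = 13)
  cv <- kfoldCV(sgs, labels, cfg)
  # every item sits in exactly one validation fold
  expect_equal(sort(unique(cv$fold)), 1:5)
  expect_length(cv$fold, 60)
  expect_gte(cv$pooledAuc, 0.95)

  # shuffled labels: CV AUC must collapse to chance
  set.seed(14)
  shuffled <- sample(labels)
  cvNull <- kfoldCV(sgs, shuffled, cfg)
  expect_gte(cvNull$pooledAuc, 0.4 - 0.05)
  expect_lte(cvNull$pooledAuc, 0.6 + 0.05)
})

test_that("pooled CV performance tracks held-out performance", {
  train <- c(toneScalograms(50, 1, seedBase = 400),
             toneScalograms(50, 0, seedBase = 500))
  trainLab <- rep(c(TRUE, FALSE), each = 50)
  test <- c(toneScalograms(25, 1, seedBase = 600),
            toneScalograms(25, 0, seedBase = 700))
  testLab <- rep(c(TRUE, FALSE), each = 25)
  cfg <- trainConfig(maxEpochs = 8, folds = 5, seed = 15)
  cv <- kfoldCV(train, trainLab, cfg)
  heldOut <- rocAuc(predict(cv$model, test)$probability, testLab)$auc
  expect_lt(abs(cv$pooledAuc - heldOut), 0.1)
})

test_that("filtered and unfiltered inputs train to similar accuracy", {
  mkSets <- function(filtered) {
    recs <- c(lapply(1:30, function(i) quickRecording(
        cmAmplitude = amplitudeForSnr(8, nEpochs = 30), seed = 800 + i)),
      lapply(1:30, function(i) quickRecording(0, seed = 900 + i)))
    if (filtered) recs <- lapply(recs, preprocessRecording)
    lapply(recs, recordingScalogram)
  }
  labels <- rep(c(TRUE, FALSE), each = 30)
  cfg <- trainConfig(maxEpochs = 10, seed = 16)
  accOf <- function(sgs) {
    tr <- c(1:20, 31:50)
    te <- setdiff(seq_along(sgs), tr)
    m <- trainClassifier(sgs[tr], labels[tr], cfg)
    mean(predict(m, sgs[te])$detected == labels[te])
  }
  accF <- accOf(mkSets(TRUE))
  accU <- accOf(mkSets(FALSE))
  expect_lte(abs(accF - accU), 0.05 + 1e-9)
})
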