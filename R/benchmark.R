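#' End-to-end detector benchmark on a labelled dataset
#'
#' Runs the full evaluation protocol: a stratified 70/30 train/test split
#' (stratified by stimulus frequency x label so per-frequency metrics stay
#' balanced), all tuning on the training split only (Q tuning for the
#' Hotelling detector, the logistic read-out of the correlation detector,
#' the CNN training), scoring and metrics on the test split only, and
#' pairwise one-sided DeLong comparisons of the test AUCs. Train/test
#' leakage is guarded by an identifier-disjointness assertion.
#'
#' @param recordings list of [ECochGRecording-class] objects (raw; the
#'   benchmark preprocesses them with the objective-path settings).
#' @param labels logical ground-truth vector parallel to `recordings`.
#' @param methods subset of `c("hotelling", "correlation", "dl")`.
#' @param split training fraction (default 0.7).
#' @param seed integer seed driving the split, the correlation splits and
#'   the CNN training.
#' @param alpha Hotelling significance level (default 0.01).
#' @param tuneQGrid grid for Q tuning, or `NULL` to use the per-frequency
#'   [defaultQ()] values without tuning.
#' @param cfg [trainConfig()] for the CNN (its seed is derived from `seed`).
#' @param nRepetitions repetitions of the correlation buffer split.
#' @param groups optional factor-like vector parallel to `recordings`
#'   (e.g. SNR level); the report then includes per-group detection rates
#'   on the test split, split into `power` (truth-positive items) and
#'   `falsePositiveRate` (truth-negative items).
#' @return A list of class `"ecochgEval"`: per-method `metrics`
#'   (confusion), `auc`, `roc`, `scores`; the `delong` p-value matrix
#'   (entry `[i, j]` tests AUC_i > AUC_j one-sided); `split` (train/test
#'   ids); `tuning` (Q table used); and `detectionByGroup` when `groups`
#'   is given.
#' @export
runBenchmark <- function(recordings, labels,
                         methods = c("hotelling", "correlation", "dl"),
                         split = 0.7, seed = 1L, alpha = 0.01,
                         tuneQGrid = seq(5L, 195L, by = 5L),
                         cfg = trainConfig(), nRepetitions = 100,
                         groups = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  n <- length(recordings)
  stopifnot(length(labels) == n, n >= 10)
  labels <- as.logical(labels)
  ids <- vapply(recordings, recordingId, character(1))
  if (anyDuplicated(ids)) stop("recording ids must be unique")
  freqs <- vapply(recordings, function(r) stimulus(r)@frequency, numeric(1))

  ## stratified split by frequency x label
  strata <- interaction(freqs, labels, drop = TRUE)
  trainIdx <- withSeed(childSeed(seed, 1L), {
    unlist(lapply(levels(strata), function(s) {
      idx <- which(strata == s)
      sample(idx, round(split * length(idx)))
    }), use.names = FALSE)
  })
  testIdx <- setdiff(seq_len(n), trainIdx)
  if (length(intersect(ids[trainIdx], ids[testIdx])) > 0L)
    stop("train/test leakage: a recording appears in both splits")
  if (length(unique(labels[testIdx])) < 2L)
    stop("test split contains a single class; enlarge the dataset")

  pre <- lapply(recordings, preprocessRecording)
  scores <- list()
  decisions <- list()
  tuning <- NULL

  if ("hotelling" %in% methods) {
    qTab <- vapply(sort(unique(freqs)), function(f)
      defaultQ(f), integer(1))
    names(qTab) <- sort(unique(freqs))
    if (!is.null(tuneQGrid)) {
      tuned <- tuneQ(pre[trainIdx], labels[trainIdx], alpha = alpha,
                     grid = tuneQGrid)
      qTab[names(tuned$optimal)] <- tuned$optimal
      tuning <- tuned
    }
    p <- vapply(seq_len(n), function(i)
      hotellingDetect(pre[[i]], Q = qTab[[as.character(freqs[i])]],
                      alpha = alpha)$p.value, numeric(1))
    scores$hotelling <- 1 - p     # larger = more response-like
    decisions$hotelling <- p < alpha
  }

  if ("correlation" %in% methods) {
    coeffs <- vapply(seq_len(n), function(i)
      corrBufferSplit(pre[[i]], nRepetitions = nRepetitions,
                      seed = childSeed(seed, 10000L + i))$corrCoeff,
      numeric(1))
    clf <- fitCorrClassifier(coeffs[trainIdx], labels[trainIdx])
    prd <- predict(clf, coeffs)
    scores$correlation <- prd$probability
    decisions$correlation <- prd$detected
  }

  if ("dl" %in% methods) {
    sgs <- lapply(pre, recordingScalogram)
    cfg$seed <- cfg$seed %||% childSeed(seed, 3L)
    model <- trainClassifier(sgs[trainIdx], labels[trainIdx], cfg)
    prd <- predict(model, sgs)
    scores$dl <- prd$probability
    decisions$dl <- prd$detected
  }

  testTruth <- labels[testIdx]
  metrics <- lapply(methods, function(m)
    confusionMetrics(decisions[[m]][testIdx], testTruth))
  names(metrics) <- methods
  roc <- lapply(methods, function(m) rocAuc(scores[[m]][testIdx], testTruth))
  names(roc) <- methods
  auc <- vapply(roc, `[[`, numeric(1), "auc")

  delong <- matrix(NA_real_, length(methods), length(methods),
                   dimnames = list(methods, methods))
  if (length(methods) > 1L)
    for (a in methods) for (b in methods)
      if (a != b)
        delong[a, b] <- delongTest(scores[[a]][testIdx],
                                   scores[[b]][testIdx],
                                   testTruth)$p.value

  detectionByGroup <- NULL
  if (!is.null(groups)) {
    g <- as.character(groups)[testIdx]
    rate <- function(keep) sapply(methods, function(m)
      tapply(decisions[[m]][testIdx][keep], g[keep], mean))
    detectionByGroup <- list(power = rate(testTruth),
                             falsePositiveRate = rate(!testTruth))
  }

  structure(list(methods = methods, metrics = metrics, auc = auc,
                 roc = roc, scores = scores, decisions = decisions,
                 delong = delong, tuning = tuning,
                 split = list(train = ids[trainIdx], test = ids[testIdx]),
                 testIdx = testIdx, labels = labels,
                 detectionByGroup = detectionByGroup),
            class = "ecochgEval")
}

#' @export
print.ecochgEval <- function(x, ...) {
  cat(sprintf("ECochG detector benchmark: %d train / %d test recordings\n",
              length(x$split$train), length(x$split$test)))
  for (m in x$methods) {
    mm <- x$metrics[[m]]
    cat(sprintf(
      "  %-11s AUC %.3f | acc %.3f | sens %s | spec %s\n", m,
      x$auc[[m]], mm$accuracy,
      ifelse(is.na(mm$sensitivity), "NA", sprintf("%.3f", mm$sensitivity)),
      ifelse(is.na(mm$specificity), "NA", sprintf("%.3f", mm$specificity))))
  }
  invisible(x)
}
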