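#' Split-buffer correlation statistic of a recording
#'
#' Quantifies response repeatability: per repetition, the condensation
#' epochs are randomly partitioned into two equal buffers and the
#' rarefaction epochs into two more; each buffer is averaged into a waveform
#' and the Pearson correlation of the two condensation buffer means
#' (CORR_CON) and of the two rarefaction buffer means (CORR_RAR) are
#' averaged into CORR. Repeating the random split (default 100 times) and
#' averaging gives the final correlation coefficient. A coefficient near 1
#' indicates a repeatable response; near 0, noise.
#'
#' @param rec a preprocessed [ECochGRecording-class].
#' @param nRepetitions number of random splits (default 100).
#' @param seed integer seed; the result is deterministic given the seed.
#' @return An object of class `"corrSplit"`: list with `corrCoeff` (the
#'   averaged coefficient), `perRep` (CORR per repetition), `corrCon`,
#'   `corrRar` (per-repetition buffer correlations) and `nRepetitions`.
#'   Odd epoch counts leave one random epoch out per repetition;
#'   zero-variance buffer means contribute r = 0.
#' @export
corrBufferSplit <- function(rec, nRepetitions = 100, seed = NULL) {
  stopifnot(is(rec, "ECochGRecording"))
  conM <- rec@con@samples
  rarM <- rec@rar@samples
  if (nrow(conM) < 4L) stop("need at least 4 epochs per polarity")
  halfCor <- function(M) {
    n <- nrow(M)
    k <- n %/% 2L
    perm <- sample.int(n)          # odd n: epoch perm[2k+1] sits out
    m1 <- colMeans(M[perm[seq_len(k)], , drop = FALSE])
    m2 <- colMeans(M[perm[k + seq_len(k)], , drop = FALSE])
    if (sd(m1) == 0 || sd(m2) == 0) {
      message("zero-variance buffer mean; repetition scored r = 0")
      return(0)
    }
    cor(m1, m2)
  }
  withSeed(seed, {
    corrCon <- numeric(nRepetitions)
    corrRar <- numeric(nRepetitions)
    for (i in seq_len(nRepetitions)) {
      corrCon[i] <- halfCor(conM)
      corrRar[i] <- halfCor(rarM)
    }
    perRep <- (corrCon + corrRar) / 2
    structure(list(corrCoeff = mean(perRep), perRep = perRep,
                   corrCon = corrCon, corrRar = corrRar,
                   nRepetitions = nRepetitions,
                   recordingId = rec@recordingId),
              class = "corrSplit")
  })
}

#' @export
print.corrSplit <- function(x, ...) {
  cat(sprintf("Split-buffer correlation '%s': corr coeff = %.3f (%d reps)\n",
              x$recordingId, x$corrCoeff, x$nRepetitions))
  invisible(x)
}

#' Fit the logistic read-out of the correlation detector
#'
#' Maximum-likelihood logistic regression of the response label on the
#' final correlation coefficient. On separable data (where the ML estimate
#' diverges) the model falls back to a midpoint threshold rule between the
#' class means, flagged in the result.
#'
#' @param coeffs numeric vector of correlation coefficients.
#' @param labels logical vector (response present), same length.
#' @return An object of class `"corrClassifier"`; use [stats::predict()]
#'   with new coefficients to obtain probabilities and decisions at 0.5.
#' @export
fitCorrClassifier <- function(coeffs, labels) {
  stopifnot(length(coeffs) == length(labels))
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to fit the classifier")
  separated <- max(coeffs[!labels]) < min(coeffs[labels]) ||
    max(coeffs[labels]) < min(coeffs[!labels])
  if (separated) {
    thr <- (max(coeffs[!labels]) + min(coeffs[labels])) / 2
    structure(list(type = "threshold", threshold = thr, separated = TRUE,
                   direction = if (mean(coeffs[labels]) >=
                                   mean(coeffs[!labels])) 1 else -1),
              class = "corrClassifier")
  } else {
    fit <- glm(labels ~ coeffs, family = binomial())
    structure(list(type = "logistic", intercept = unname(coef(fit)[1]),
                   slope = unname(coef(fit)[2]), separated = FALSE,
                   fit = fit),
              class = "corrClassifier")
  }
}

#' @param object a `"corrClassifier"`.
#' @param newCoeffs numeric vector of correlation coefficients to score.
#' @param ... unused.
#' @rdname fitCorrClassifier
#' @export
predict.corrClassifier <- function(object, newCoeffs, ...) {
  prob <- if (object$type == "logistic")
    plogis(object$intercept + object$slope * newCoeffs)
  else if (object$direction > 0)
    as.numeric(newCoeffs > object$threshold)
  else
    as.numeric(newCoeffs < object$threshold)
  list(probability = prob, detected = prob > 0.5)
}

#' @export
print.corrClassifier <- function(x, ...) {
  if (x$type == "logistic")
    cat(sprintf("Logistic correlation read-out: logit(p) = %.3f + %.3f * r\n",
                x$intercept, x$slope))
  else
    cat(sprintf(
      "Correlation read-out (separable data): threshold rule at r = %.3f\n",
      x$threshold))
  invisible(x)
}
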