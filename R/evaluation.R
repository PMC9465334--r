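#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity (true-positive rate) and specificity (true-negative
#' rate) of binary decisions against ground truth, with a 95%
#' normal-approximation confidence half-width for the accuracy.
#'
#' @param decisions logical vector of detector decisions.
#' @param truth logical vector of ground truth, same length.
#' @return A list of class `"confusionMetrics"` with `accuracy`,
#'   `sensitivity`, `specificity`, `ci` (half-width) and the counts `tp`,
#'   `fp`, `tn`, `fn`. Sensitivity or specificity is `NA` when the
#'   corresponding truth class is absent.
#' @export
confusionMetrics <- function(decisions, truth) {
  stopifnot(length(decisions) == length(truth))
  decisions <- as.logical(decisions)
  truth <- as.logical(truth)
  tp <- sum(decisions & truth)
  fp <- sum(decisions & !truth)
  tn <- sum(!decisions & !truth)
  fn <- sum(!decisions & truth)
  n <- length(truth)
  acc <- (tp + tn) / n
  structure(list(
    accuracy = acc,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ci = qnorm(0.975) * sqrt(acc * (1 - acc) / n),
    tp = tp, fp = fp, tn = tn, fn = fn, n = n),
    class = "confusionMetrics")
}

#' @export
print.confusionMetrics <- function(x, ...) {
  cat(sprintf("accuracy %.3f (+/- %.3f), sensitivity %s, specificity %s\n",
              x$accuracy, x$ci,
              ifelse(is.na(x$sensitivity), "NA", sprintf("%.3f", x$sensitivity)),
              ifelse(is.na(x$specificity), "NA", sprintf("%.3f", x$specificity))))
  invisible(x)
}

#' Empirical ROC curve and AUC
#'
#' Scores are oriented so that larger means more response-like (Hotelling
#' p-values must be mapped to `1 - p` before entering). The curve is swept
#' over the unique score thresholds; tied scores move the operating point
#' diagonally, and the trapezoidal area then equals the rank-based
#' Mann-Whitney statistic `U / (n1 * n0)` with ties counted one half.
#'
#' @param scores numeric detector scores.
#' @param truth logical ground truth, both classes present.
#' @return A list with `rocPoints` (data.frame of FPR, TPR, threshold) and
#'   `auc`. Constant scores give AUC 0.5 with a warning.
#' @export
rocAuc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  truth <- as.logical(truth)
  if (length(unique(truth)) < 2L)
    stop("both classes must be present")
  if (length(unique(scores)) == 1L)
    warning("constant scores: AUC is 0.5 by convention")
  n1 <- sum(truth)
  n0 <- sum(!truth)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- truth[ord]
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie group
  tpr <- c(0, cumsum(y)[last] / n1)
  fpr <- c(0, cumsum(!y)[last] / n0)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(rocPoints = data.frame(fpr = fpr, tpr = tpr,
                              threshold = c(Inf, s[last])),
       auc = auc)
}

## Placement values of each positive against all negatives (and vice versa)
## for one score vector: the DeLong structural components.
.placements <- function(scores, truth) {
  x <- scores[truth]
  y <- scores[!truth]
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
  v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Paired DeLong comparison of two AUCs
#'
#' Nonparametric comparison of the AUCs of two detectors scored on the same
#' items, using the DeLong placement-value covariance. One-sided by default:
#' small p supports `AUC(scoresA) > AUC(scoresB)`. Comparing a scorer with
#' itself gives p = 0.5 exactly (zero statistic).
#'
#' @param scoresA,scoresB numeric scores of the two detectors on identical
#'   items (larger = more response-like).
#' @param truth logical ground truth.
#' @param alternative `"greater"` (one-sided, default) or `"two.sided"`.
#' @return An `"htest"`-style list with `statistic` (z), `p.value`,
#'   `estimate` (the two AUCs) and `alternative`.
#' @export
delongTest <- function(scoresA, scoresB, truth,
                       alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(scoresA) == length(truth))
  if (length(scoresB) != length(truth))
    stop("scoresA and scoresB must score the same items")
  truth <- as.logical(truth)
  if (length(unique(truth)) < 2L) stop("both classes must be present")
  pa <- .placements(scoresA, truth)
  pb <- .placements(scoresB, truth)
  m <- sum(truth)
  n <- sum(!truth)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
        (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- pa$auc - pb$auc
  z <- if (vd <= 0) {
    if (abs(diff) < .Machine$double.eps^0.5) 0
    else sign(diff) * Inf
  } else diff / sqrt(vd)
  p <- switch(alternative,
              greater = pnorm(z, lower.tail = FALSE),
              two.sided = 2 * pnorm(abs(z), lower.tail = FALSE))
  structure(list(statistic = c(z = z), p.value = p,
                 estimate = c(aucA = pa$auc, aucB = pb$auc),
                 alternative = alternative,
                 method = "Paired DeLong test for two correlated AUCs",
                 data.name = sprintf("%d positives, %d negatives", m, n)),
            class = "htest")
}

#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement of a fixed number of raters assigning
#' categorical labels to items: `kappa = (Pbar - Pe) / (1 - Pe)` with
#' `Pbar` the mean observed pairwise agreement per item and `Pe` the
#' agreement expected from the marginal category frequencies.
#'
#' @param ratings items x raters matrix (logical, character or factor), at
#'   least 2 raters and 2 items; every item rated by every rater.
#' @return Kappa in `[-1, 1]`, or `NA` (with a warning) when every rater
#'   uses a single identical category (`Pe = 1`, agreement undefined).
#' @export
fleissKappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 2L || ncol(ratings) < 2L)
    stop("need at least 2 items and 2 raters")
  if (anyNA(ratings)) stop("all items must be rated by every rater")
  nR <- ncol(ratings)
  cats <- sort(unique(as.vector(ratings)))
  counts <- vapply(cats, function(cc) rowSums(ratings == cc),
                   numeric(nrow(ratings)))
  counts <- matrix(counts, nrow = nrow(ratings))
  pI <- (rowSums(counts^2) - nR) / (nR * (nR - 1))
  pJ <- colSums(counts) / (nrow(ratings) * nR)
  pe <- sum(pJ^2)
  if (1 - pe < .Machine$double.eps) {
    warning("all ratings in a single category: kappa undefined")
    return(NA_real_)
  }
  (mean(pI) - pe) / (1 - pe)
}

#' Multi-rater agreement report
#'
#' Computes Fleiss' kappa from first-round labels, overall and per stimulus
#' frequency, and each rater's false-positive rate against the consensus
#' labels.
#'
#' @param labels label data.frame in [readLabels()] layout (round-1 rows are
#'   used for kappa).
#' @param consensus named logical vector of consensus labels per
#'   recording id (used for the false-positive rates; optional).
#' @param frequencies optional named vector mapping recording id to stimulus
#'   frequency for the per-frequency break-down.
#' @return A list of class `"raterAgreement"` with `kappa`, `kappaByFrequency`
#'   (or `NULL`), and `falsePositiveRate` per rater (or `NULL`).
#' @export
raterAgreement <- function(labels, consensus = NULL, frequencies = NULL) {
  r1 <- labels[labels$round == 1L, ]
  wide <- tapply(r1$response_present, list(r1$recording_id, r1$rater_id),
                 identity)
  wide <- matrix(as.logical(wide), nrow = nrow(wide),
                 dimnames = dimnames(wide))
  if (anyNA(wide)) stop("every rater must label every recording in round 1")
  out <- list(kappa = fleissKappa(wide))
  out$kappaByFrequency <- if (!is.null(frequencies)) {
    fr <- frequencies[rownames(wide)]
    ufr <- sort(unique(fr))
    setNames(vapply(ufr, function(f)
      fleissKappa(wide[fr == f, , drop = FALSE]), numeric(1)),
      as.character(ufr))
  }
  out$falsePositiveRate <- if (!is.null(consensus)) {
    cons <- consensus[rownames(wide)]
    apply(wide, 2L, function(v) {
      neg <- !cons
      if (!any(neg)) return(NA_real_)
      mean(v[neg])
    })
  }
  structure(out, class = "raterAgreement")
}

#' @export
print.raterAgreement <- function(x, ...) {
  cat(sprintf("Fleiss' kappa: %.3f\n", x$kappa))
  if (!is.null(x$kappaByFrequency)) {
    cat("  by frequency:\n")
    for (f in names(x$kappaByFrequency))
      cat(sprintf("    %s Hz: %.3f\n", f, x$kappaByFrequency[[f]]))
  }
  if (!is.null(x$falsePositiveRate)) {
    cat("  rater false-positive rates vs consensus:\n")
    for (r in names(x$falsePositiveRate))
      cat(sprintf("    %s: %.3f\n", r, x$falsePositiveRate[[r]]))
  }
  invisible(x)
}
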