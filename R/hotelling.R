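## Per-frequency defaults for the number of time-voltage means, as tuned on
## the labelled clinical cohort (maximum training accuracy at alpha = 0.01).
.defaultQ <- c("250" = 90L, "500" = 80L, "750" = 100L,
               "1000" = 85L, "1500" = 105L, "2000" = 100L)

#' Default number of time-voltage means per stimulus frequency
#'
#' The per-frequency Q values tuned on the labelled reference cohort
#' (250 Hz: 90, 500: 80, 750: 100, 1000: 85, 1500: 105, 2000: 100), used by
#' [hotellingDetect()] when no tuning result is supplied.
#'
#' @param frequency stimulus frequency in Hz.
#' @return Integer Q.
#' @export
defaultQ <- function(frequency) {
  q <- .defaultQ[as.character(frequency)]
  if (is.na(q)) stop("no default Q for frequency ", frequency)
  unname(q)
}

#' Hotelling detection on one preprocessed recording
#'
#' Convenience wrapper: builds the time-voltage-means matrix and runs the
#' one-sample test against the zero vector.
#'
#' @param rec a preprocessed [ECochGRecording-class].
#' @param Q number of time-voltage means; defaults to [defaultQ()] for the
#'   recording's stimulus frequency.
#' @param alpha significance level (default 0.01).
#' @return A `"hotellingT2"` test object, see [hotellingT2()].
#' @export
hotellingDetect <- function(rec, Q = defaultQ(stimulus(rec)@frequency),
                            alpha = 0.01) {
  hotellingT2(buildTVM(rec, Q), alpha = alpha)
}

#' Tune the number of time-voltage means per frequency
#'
#' Sweeps Q over a grid (default 5 to 195 in steps of 5) and, for each
#' stimulus frequency present in the training set, picks the Q maximizing
#' the accuracy of the detection decision `p < alpha` against the labels.
#' Ties resolve to the smallest Q (fewer parameters, larger error dof).
#' Grid values violating `Q <= N - 1` or exceeding the sample count are
#' skipped with a warning.
#'
#' @param recordings list of preprocessed [ECochGRecording-class] objects.
#' @param labels logical vector of ground-truth labels, parallel to
#'   `recordings`.
#' @param alpha significance level (default 0.01).
#' @param grid candidate Q values.
#' @return An object of class `"qTuning"`: list with `optimal` (named
#'   integer vector per frequency) and `curve` (data.frame frequency x Q x
#'   accuracy).
#' @export
tuneQ <- function(recordings, labels, alpha = 0.01,
                  grid = seq(5L, 195L, by = 5L)) {
  stopifnot(length(recordings) == length(labels), !anyNA(labels))
  freqs <- vapply(recordings, function(r) stimulus(r)@frequency, numeric(1))
  curve <- list()
  optimal <- integer(0)
  for (f in sort(unique(freqs))) {
    sel <- which(freqs == f)
    lab <- labels[sel]
    if (length(unique(lab)) < 2L)
      stop("training set for ", f, " Hz contains a single class")
    P <- vapply(recordings[sel], function(r) {
      M <- rbind(r@con@samples, -r@rar@samples)
      .hotellingSweep(M, grid)
    }, numeric(length(grid)))
    P <- matrix(P, nrow = length(grid))
    usable <- rowSums(is.na(P)) == 0L
    if (!all(usable))
      warning(sum(!usable), " grid value(s) for ", f,
              " Hz violate Q <= N - 1 (or the sample count); skipped")
    if (!any(usable))
      stop("no usable Q grid value for ", f, " Hz")
    acc <- vapply(which(usable), function(i)
      mean((P[i, ] < alpha) == lab), numeric(1))
    qs <- grid[usable]
    best <- qs[which.max(acc)]  # which.max returns the first (smallest Q)
    optimal[as.character(f)] <- as.integer(best)
    curve[[as.character(f)]] <- data.frame(frequency = f, Q = qs,
                                           accuracy = acc)
  }
  structure(list(optimal = optimal,
                 curve = do.call(rbind, c(curve, make.row.names = FALSE)),
                 alpha = alpha, grid = grid),
            class = "qTuning")
}

#' @export
print.qTuning <- function(x, ...) {
  cat("Q tuning (alpha =", x$alpha, ")\n")
  for (f in names(x$optimal)) {
    cv <- x$curve[x$curve$frequency == as.numeric(f), ]
    cat(sprintf("  %5s Hz: optimal Q = %3d (accuracy %.3f)\n", f,
                x$optimal[[f]], max(cv$accuracy)))
  }
  invisible(x)
}
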