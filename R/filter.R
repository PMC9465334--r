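## Zero-phase Butterworth band-pass filtering of epoch ensembles.
##
## Coefficients come from signal::butter; the forward-backward application is
## implemented here because the measurement windows are short (6.5-19.1 ms)
## and edge handling decides everything: each epoch is extended by odd
## reflection and the filter state is initialized at its steady-state
## response to the first extended sample, then the sequence is filtered
## forward and backward. The recursion runs vectorized across all epochs of
## an ensemble at once (direct form II transposed).

## Steady-state initial filter state per unit input (companion-matrix solve).
.lfilterZi <- function(b, a) {
  n <- length(a) - 1L
  A <- rbind(-a[-1] / a[1], cbind(diag(1, n - 1L), 0))
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n) - t(A), B)
}

## One vectorized IIR pass over the columns of X (epochs in rows).
## zi: steady-state state vector; scaled per row by the first column.
.iirPass <- function(b, a, X, zi) {
  n <- length(b) - 1L
  Z <- X[, 1L] %o% zi
  Y <- X
  for (t in seq_len(ncol(X))) {
    xt <- X[, t]
    yt <- b[1L] * xt + Z[, 1L]
    if (n > 1L)
      for (k in seq_len(n - 1L))
        Z[, k] <- b[k + 1L] * xt + Z[, k + 1L] - a[k + 1L] * yt
    Z[, n] <- b[n + 1L] * xt - a[n + 1L] * yt
    Y[, t] <- yt
  }
  Y
}

.filtfiltMatrix <- function(b, a, X) {
  nS <- ncol(X)
  pad <- min(nS - 1L, 3L * max(length(a), length(b)))
  zi <- .lfilterZi(b, a)
  ext <- cbind(2 * X[, 1L] - X[, (pad + 1L):2L, drop = FALSE],
               X,
               2 * X[, nS] - X[, (nS - 1L):(nS - pad), drop = FALSE])
  Y <- .iirPass(b, a, ext, zi)
  Y <- .iirPass(b, a, Y[, ncol(Y):1L, drop = FALSE], zi)
  Y <- Y[, ncol(Y):1L, drop = FALSE]
  Y[, (pad + 1L):(pad + nS), drop = FALSE]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass to every
#' epoch of an ensemble. The default 100 Hz - 5 kHz band is the objective
#' detection path; 10 Hz - 5 kHz is used when preparing traces for visual
#' display. The DC component is outside the passband and is removed.
#'
#' @param epochs an [EpochMatrix-class] (or plain matrix, epochs x samples).
#' @param low,high cutoff frequencies in Hz; `high` must be below Nyquist.
#' @param order filter order of the underlying low/high-pass prototypes
#'   (default 2; the band-pass transfer function has twice that order).
#' @param samplingRate required when `epochs` is a plain matrix.
#' @return Object of the same kind as `epochs` with filtered voltages.
#' @examples
#' em <- epochMatrix(matrix(rnorm(40 * 192), 40), 20000, "CON")
#' filtered <- bandpassFilter(em, 100, 5000)
#' @export
bandpassFilter <- function(epochs, low = 100, high = 5000, order = 2,
                           samplingRate = NULL) {
  if (is(epochs, "EpochMatrix")) {
    fs <- epochs@samplingRate
    X <- epochs@samples
  } else {
    if (is.null(samplingRate))
      stop("samplingRate is required for plain-matrix input")
    fs <- samplingRate
    X <- as.matrix(epochs)
  }
  if (low <= 0 || low >= high) stop("need 0 < low < high")
  if (high >= fs / 2) stop("upper cutoff must be below Nyquist (", fs / 2,
                           " Hz)")
  bt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  Y <- .filtfiltMatrix(bt$b, bt$a, X)
  if (is(epochs, "EpochMatrix")) {
    epochs@samples <- Y
    epochs
  } else Y
}
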