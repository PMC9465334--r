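#' Build the time-voltage-means matrix of a recording
#'
#' Stacks the condensation epochs and the sign-flipped rarefaction epochs of
#' a preprocessed recording (N = n_con + n_rar rows; the cochlear
#' microphonic inverts with polarity, so flipping the rarefaction rows
#' aligns it and the no-response null is a zero mean vector), partitions the
#' measurement window into Q contiguous windows with boundaries at
#' `round(j * T / Q)`, and takes the mean voltage of each window.
#'
#' @param rec a preprocessed [ECochGRecording-class], or a plain matrix of
#'   already-stacked epochs.
#' @param Q number of time-voltage means; `1 <= Q <= N - 1` and `Q <= T`.
#' @return A [TVMMatrix-class].
#' @seealso [hotellingT2()], [defaultQ()]
#' @export
buildTVM <- function(rec, Q) {
  M <- if (is(rec, "ECochGRecording"))
    rbind(rec@con@samples, -rec@rar@samples)
  else as.matrix(rec)
  n <- nrow(M)
  nS <- ncol(M)
  if (Q < 1) stop("Q must be at least 1")
  if (Q > n - 1L)
    stop("Q = ", Q, " exceeds the cap N - 1 = ", n - 1L,
         " (N stacked epochs)")
  if (Q > nS) stop("Q = ", Q, " exceeds the sample count ", nS)
  bounds <- as.integer(round(seq_len(Q) * nS / Q))
  bounds <- c(0L, bounds)
  if (any(diff(bounds) <= 0L)) stop("degenerate window partition")
  ## window membership of every sample -> group means via crossprod
  grp <- rep.int(seq_len(Q), diff(bounds))
  A <- matrix(0, nS, Q)
  A[cbind(seq_len(nS), grp)] <- 1 / diff(bounds)[grp]
  new("TVMMatrix", V = M %*% A, windowBounds = bounds)
}

#' One-sample Hotelling's T-squared test on time-voltage means
#'
#' Multivariate extension of the one-sample t-test: tests whether the mean
#' vector of the N x Q time-voltage-means matrix differs from a hypothesized
#' vector (zeros = noise; band-passed recordings have zero expected mean).
#' `T2 = N (xbar - mu0)' S^-1 (xbar - mu0)` with `S` the unbiased sample
#' covariance; `F = T2 (N - Q) / (Q (N - 1))` is referred to `F(Q, N - Q)`.
#'
#' @param V a [TVMMatrix-class] or plain N x Q matrix.
#' @param mu0 hypothesized mean vector (length Q, or a scalar recycled);
#'   default zeros.
#' @param alpha significance level for the detection decision (default
#'   0.01).
#' @return An object of classes `"hotellingT2"` and `"htest"` with fields
#'   `statistic` (T2), `fStat`, `parameter` (Q and the F dof), `p.value`,
#'   `alpha` and `detected`.
#' @examples
#' hotellingT2(matrix(c(1, 2, 3, 4, 5), ncol = 1))  # T2 = 18, squared t
#' @export
hotellingT2 <- function(V, mu0 = 0, alpha = 0.01) {
  M <- if (is(V, "TVMMatrix")) V@V else as.matrix(V)
  n <- nrow(M)
  q <- ncol(M)
  if (n <= q)
    stop("N (", n, ") must exceed Q (", q, ")")
  mu0 <- rep_len(mu0, q)
  xbar <- colMeans(M)
  S <- cov(M)
  R <- tryCatch(chol(S), error = function(e)
    stop("sample covariance is singular; use a smaller Q"))
  d <- backsolve(R, xbar - mu0, transpose = TRUE)
  t2 <- n * sum(d^2)
  f <- t2 * (n - q) / (q * (n - 1))
  p <- pf(f, q, n - q, lower.tail = FALSE)
  structure(list(
    statistic = c(T2 = t2),
    fStat = f,
    parameter = c(Q = q, df1 = q, df2 = n - q),
    p.value = p,
    alpha = alpha,
    detected = p < alpha,
    method = "One-sample Hotelling's T-squared test on time-voltage means",
    data.name = sprintf("%d x %d voltage-means matrix", n, q)),
    class = c("hotellingT2", "htest"))
}

#' @importFrom stats pf
NULL

## Shared helper: p-values of the Hotelling test across a Q grid for one
## stacked epoch matrix. Exploits linearity: the TVM covariance for any Q is
## the block average of the full T x T sample covariance, so the expensive
## part is computed once.
.hotellingSweep <- function(M, grid, mu0 = 0) {
  n <- nrow(M)
  nS <- ncol(M)
  xbarFull <- colMeans(M)
  SFull <- cov(M)
  vapply(grid, function(q) {
    if (q > n - 1L || q > nS) return(NA_real_)
    bounds <- c(0L, as.integer(round(seq_len(q) * nS / q)))
    grp <- rep.int(seq_len(q), diff(bounds))
    w <- 1 / diff(bounds)
    xbar <- as.vector(rowsum(xbarFull, grp)) * w - rep_len(mu0, q)
    S <- rowsum(t(rowsum(SFull, grp)), grp) * (w %o% w)
    R <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(R)) return(NA_real_)
    d <- backsolve(R, xbar, transpose = TRUE)
    f <- n * sum(d^2) * (n - q) / (q * (n - 1))
    pf(f, q, n - q, lower.tail = FALSE)
  }, numeric(1))
}
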