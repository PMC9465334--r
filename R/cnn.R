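## Compact convolutional network, implemented with im2col matrix kernels.
##
## Architecture (input 32 x 32 grayscale, a 7x7 block-mean reduction of the
## 224 x 224 scalogram):
##   conv 5x5 x 8 -> ReLU -> maxpool 2   (28x28x8 -> 14x14x8)
##   conv 3x3 x 16 -> ReLU -> maxpool 2  (12x12x16 -> 6x6x16)
##   dense 576 -> 32 ReLU -> dense 32 -> 1, sigmoid
## trained with minibatch SGD with momentum on the binary cross-entropy.
## Convolutions are evaluated as patch-matrix products; the patch index
## tables below are precomputed once.

.cnnGeom <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    side <- 32L; k1 <- 5L; f1 <- 8L
    c1 <- side - k1 + 1L            # 28
    p1 <- c1 %/% 2L                 # 14
    k2 <- 3L; f2 <- 16L
    c2 <- p1 - k2 + 1L              # 12
    p2 <- c2 %/% 2L                 # 6
    ## im2col for conv1: output position (r, c) column-major x 25 kernel taps
    r <- rep(seq_len(c1), times = c1)
    c_ <- rep(seq_len(c1), each = c1)
    P1 <- matrix(0L, c1 * c1, k1 * k1)
    for (kk in seq_len(k1 * k1)) {
      kr <- (kk - 1L) %% k1 + 1L
      kc <- (kk - 1L) %/% k1 + 1L
      P1[, kk] <- (r + kr - 1L) + (c_ + kc - 2L) * side
    }
    poolIdx <- function(side) {
      half <- side %/% 2L
      i <- rep(seq_len(half), times = half)
      j <- rep(seq_len(half), each = half)
      lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)), function(d)
        (2L * i - 1L + d[1]) + (2L * j - 2L + d[2]) * side)
    }
    Q1 <- poolIdx(c1)
    ## im2col for conv2 over the 14x14x8 pooled stack (vector layout:
    ## position + (channel - 1) * p1^2)
    r <- rep(seq_len(c2), times = c2)
    c_ <- rep(seq_len(c2), each = c2)
    P2 <- matrix(0L, c2 * c2, k2 * k2 * f1)
    for (ch in seq_len(f1)) for (kc in seq_len(k2)) for (kr in seq_len(k2)) {
      kk <- kr + (kc - 1L) * k2 + (ch - 1L) * k2 * k2
      P2[, kk] <- (r + kr - 1L) + (c_ + kc - 2L) * p1 + (ch - 1L) * p1 * p1
    }
    Q2 <- poolIdx(c2)
    cache <<- list(side = side, k1 = k1, f1 = f1, c1 = c1, p1 = p1,
                   k2 = k2, f2 = f2, c2 = c2, p2 = p2,
                   flat = p2 * p2 * f2, hidden = 32L,
                   P1 = P1, Q1 = Q1, P2 = P2, Q2 = Q2)
    cache
  }
})

.cnnInit <- function() {
  g <- .cnnGeom()
  he <- function(nin, nout) matrix(rnorm(nin * nout, sd = sqrt(2 / nin)),
                                   nin, nout)
  list(W1 = he(g$k1^2, g$f1), b1 = numeric(g$f1),
       W2 = he(g$k2^2 * g$f1, g$f2), b2 = numeric(g$f2),
       W3 = he(g$flat, g$hidden), b3 = numeric(g$hidden),
       W4 = he(g$hidden, 1L)[, 1L], b4 = 0)
}

.maxPool <- function(C, Q) {
  best <- C[Q[[1]], , drop = FALSE]
  arg <- matrix(1L, nrow(best), ncol(best))
  for (m in 2:4) {
    cand <- C[Q[[m]], , drop = FALSE]
    upd <- cand > best
    best[upd] <- cand[upd]
    arg[upd] <- m
  }
  list(best = best, arg = arg)
}

## scatter the pooled gradient back to the argmax positions
.unPool <- function(dPool, arg, Q, nPos) {
  out <- matrix(0, nPos, ncol(dPool))
  rows <- matrix(0L, nrow(dPool), ncol(dPool))
  for (m in 1:4) rows[arg == m] <- Q[[m]][row(arg)[arg == m]]
  idx <- cbind(as.vector(rows), as.vector(col(rows)))
  out[idx] <- as.vector(dPool)
  out
}

.cnnForward <- function(w, x, keep = FALSE) {
  g <- .cnnGeom()
  Pm1 <- matrix(x[g$P1], nrow(g$P1), ncol(g$P1))
  z1 <- Pm1 %*% w$W1 + rep(w$b1, each = nrow(g$P1))
  a1 <- pmax(z1, 0)
  pl1 <- .maxPool(a1, g$Q1)
  v <- as.vector(pl1$best)
  Pm2 <- matrix(v[g$P2], nrow(g$P2), ncol(g$P2))
  z2 <- Pm2 %*% w$W2 + rep(w$b2, each = nrow(g$P2))
  a2 <- pmax(z2, 0)
  pl2 <- .maxPool(a2, g$Q2)
  x3 <- as.vector(pl2$best)
  z3 <- drop(crossprod(w$W3, x3)) + w$b3
  a3 <- pmax(z3, 0)
  z4 <- sum(w$W4 * a3) + w$b4
  p <- plogis(z4)
  if (!keep) return(p)
  list(p = p, Pm1 = Pm1, z1 = z1, pl1 = pl1, Pm2 = Pm2, z2 = z2,
       pl2 = pl2, x3 = x3, z3 = z3, a3 = a3)
}

.cnnBackward <- function(w, fw, y) {
  g <- .cnnGeom()
  dz4 <- fw$p - y
  dW4 <- fw$a3 * dz4
  db4 <- dz4
  dz3 <- (w$W4 * dz4) * (fw$z3 > 0)
  dW3 <- fw$x3 %o% dz3
  db3 <- dz3
  dx3 <- w$W3 %*% dz3                       # flat x 1
  dPool2 <- matrix(dx3, g$p2 * g$p2, g$f2)
  dA2 <- .unPool(dPool2, fw$pl2$arg, g$Q2, g$c2 * g$c2)
  dz2 <- dA2 * (fw$z2 > 0)
  dW2 <- crossprod(fw$Pm2, dz2)
  db2 <- colSums(dz2)
  dPm2 <- dz2 %*% t(w$W2)                   # 144 x 72
  dv <- rowsum(as.vector(dPm2), as.vector(g$P2))[, 1L]
  dPool1 <- matrix(dv, g$p1 * g$p1, g$f1)
  dA1 <- .unPool(dPool1, fw$pl1$arg, g$Q1, g$c1 * g$c1)
  dz1 <- dA1 * (fw$z1 > 0)
  dW1 <- crossprod(fw$Pm1, dz1)
  db1 <- colSums(dz1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
       W3 = dW3, b3 = db3, W4 = dW4, b4 = db4)
}

.cnnTrain <- function(X, y, cfg) {
  ## X: n x 1024 feature matrix; y: 0/1
  n <- nrow(X)
  w <- .cnnInit()
  vel <- lapply(w, function(z) z * 0)
  lr <- cfg$learningRate
  mom <- cfg$momentum
  bs <- cfg$batchSize
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  for (ep in seq_len(cfg$maxEpochs)) {
    ord <- sample.int(n)
    lossSum <- 0
    correct <- 0
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      grad <- NULL
      for (i in idx) {
        fw <- .cnnForward(w, X[i, ], keep = TRUE)
        p <- min(max(fw$p, 1e-12), 1 - 1e-12)
        lossSum <- lossSum - (y[i] * log(p) + (1 - y[i]) * log(1 - p))
        correct <- correct + ((fw$p > 0.5) == (y[i] > 0.5))
        gi <- .cnnBackward(w, fw, y[i])
        grad <- if (is.null(grad)) gi else
          Map(`+`, grad, gi)
      }
      scale <- 1 / length(idx)
      for (nm in names(w)) {
        vel[[nm]] <- mom * vel[[nm]] - lr * grad[[nm]] * scale
        w[[nm]] <- w[[nm]] + vel[[nm]]
      }
    }
    history <- rbind(history, data.frame(epoch = ep, loss = lossSum / n,
                                         accuracy = correct / n))
  }
  list(weights = w, history = history)
}
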