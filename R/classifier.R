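#' Training configuration for the scalogram classifier
#'
#' Bundles the optimizer settings: minibatch SGD with momentum, batch size
#' 8, at most 25 epochs, momentum 0.9 and 10 cross-validation folds. The
#' learning rate is resolved per backbone when not given: the
#' `"large-pretrained"` transfer path uses the fine-tuning rate 1e-4, while
#' the `"compact"` from-scratch network uses 0.05 (a freshly initialized
#' small network needs a much larger step to converge within 25 epochs than
#' a pretrained one being nudged).
#'
#' @param batchSize minibatch size (default 8).
#' @param maxEpochs maximum training epochs (default 25).
#' @param learningRate SGD step size; `NULL` resolves per backbone.
#' @param momentum SGD momentum (default 0.9).
#' @param folds cross-validation folds (default 10, >= 2).
#' @param backbone `"compact"` (default) or `"large-pretrained"`.
#' @param seed integer seed controlling initialization, shuffling and fold
#'   assignment.
#' @return A list of class `"trainConfig"`.
#' @export
trainConfig <- function(batchSize = 8, maxEpochs = 25, learningRate = NULL,
                        momentum = 0.9, folds = 10,
                        backbone = c("compact", "large-pretrained"),
                        seed = NULL) {
  backbone <- match.arg(backbone)
  if (folds < 2) stop("folds must be at least 2")
  if (is.null(learningRate))
    learningRate <- if (backbone == "large-pretrained") 1e-4 else 0.05
  structure(list(batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs),
                 learningRate = learningRate, momentum = momentum,
                 folds = as.integer(folds), backbone = backbone,
                 seed = seed),
            class = "trainConfig")
}

## 224 x 224 scalogram channel -> 32 x 32 block-mean features, centred per
## image.
.scalogramFeatures <- function(scalograms) {
  feat <- function(s) {
    stopifnot(is(s, "Scalogram"))
    m <- s@image[, , 1L]
    idx <- rep(seq_len(32L), each = 7L)
    m <- rowsum(m, idx)
    m <- t(rowsum(t(m), idx)) / 49
    as.vector(m - mean(m))
  }
  t(vapply(scalograms, feat, numeric(1024L)))
}

#' Train the scalogram classifier
#'
#' Trains the binary CM-response classifier on CWT scalograms. The default
#' compact backbone is a small convolutional network (two convolutional and
#' two dense layers) trained from scratch with minibatch SGD with momentum;
#' it keeps the whole pipeline self-contained and CPU-sized. The
#' `"large-pretrained"` backbone slot mirrors the transfer-learning variant
#' (an ImageNet-pretrained image classifier with its final layers replaced
#' for binary output); it requires user-supplied pretrained weights and a
#' compatible backend and is not bundled, so requesting it errors.
#'
#' @param scalograms list of [Scalogram-class] objects.
#' @param labels logical vector of ground-truth labels.
#' @param cfg a [trainConfig()].
#' @return An object of class `"compactCNN"` with the trained weights and
#'   the per-epoch training history. Deterministic given `cfg$seed`.
#' @seealso [predict.compactCNN()], [kfoldCV()]
#' @export
trainClassifier <- function(scalograms, labels, cfg = trainConfig()) {
  stopifnot(inherits(cfg, "trainConfig"))
  if (cfg$backbone == "large-pretrained")
    stop("the large-pretrained backbone requires user-supplied weights ",
         "and a compatible backend; use backbone = 'compact'")
  labels <- as.logical(labels)
  stopifnot(length(scalograms) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("both classes must be present for training")
  X <- .scalogramFeatures(scalograms)
  fit <- withSeed(cfg$seed, .cnnTrain(X, as.numeric(labels), cfg))
  structure(list(weights = fit$weights, history = fit$history, cfg = cfg),
            class = "compactCNN")
}

#' Predict with the scalogram classifier
#'
#' @param object a trained `"compactCNN"`.
#' @param scalograms list of [Scalogram-class] objects (or an n x 1024
#'   feature matrix as produced internally).
#' @param ... unused.
#' @return A list with `probability` (in `[0, 1]` per input) and `detected`
#'   (decision at 0.5).
#' @export
predict.compactCNN <- function(object, scalograms, ...) {
  X <- if (is.matrix(scalograms)) scalograms else
    .scalogramFeatures(scalograms)
  if (ncol(X) != 1024L)
    stop("feature shape mismatch: expected 1024 columns, got ", ncol(X))
  prob <- vapply(seq_len(nrow(X)), function(i)
    .cnnForward(object$weights, X[i, ]), numeric(1))
  list(probability = prob, detected = prob > 0.5)
}

#' @export
print.compactCNN <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "Compact CNN scalogram classifier: %d epochs, final loss %.4f, train accuracy %.3f\n",
    nrow(h), h$loss[nrow(h)], h$accuracy[nrow(h)]))
  invisible(x)
}

#' Stratified k-fold cross-validation of the scalogram classifier
#'
#' Splits the items into `cfg$folds` stratified folds (class proportions
#' preserved), trains on each complement and scores the held-out fold, then
#' retrains the final model on the full set. Used to detect overfitting
#' before committing to the full training run.
#'
#' @param scalograms list of [Scalogram-class] objects.
#' @param labels logical labels.
#' @param cfg a [trainConfig()].
#' @return An object of class `"cnnCV"`: per-fold accuracy/AUC, the fold
#'   assignment, pooled out-of-fold AUC and the final full-data model.
#' @export
kfoldCV <- function(scalograms, labels, cfg = trainConfig()) {
  labels <- as.logical(labels)
  n <- length(labels)
  if (n < cfg$folds) stop("need at least as many items as folds")
  fold <- integer(n)
  withSeed(childSeed(cfg$seed, 7919L) %||% NULL, {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(cfg$folds), length(idx))
    }
  })
  if (any(vapply(seq_len(cfg$folds), function(k)
    length(unique(labels[fold == k])) < 2L, logical(1))))
    warning("some folds contain a single class; their AUC is undefined")
  X <- .scalogramFeatures(scalograms)
  pooledProb <- numeric(n)
  perFold <- data.frame(fold = seq_len(cfg$folds), accuracy = NA_real_,
                        auc = NA_real_)
  for (k in seq_len(cfg$folds)) {
    tr <- fold != k
    cfgK <- cfg
    cfgK$seed <- childSeed(cfg$seed, k)
    fit <- withSeed(cfgK$seed, .cnnTrain(X[tr, , drop = FALSE],
                                         as.numeric(labels[tr]), cfgK))
    model <- structure(list(weights = fit$weights, history = fit$history,
                            cfg = cfgK), class = "compactCNN")
    pr <- predict(model, X[!tr, , drop = FALSE])$probability
    pooledProb[!tr] <- pr
    perFold$accuracy[k] <- mean((pr > 0.5) == labels[!tr])
    if (length(unique(labels[!tr])) == 2L)
      perFold$auc[k] <- rocAuc(pr, labels[!tr])$auc
  }
  final <- trainClassifier(scalograms, labels, cfg)
  structure(list(perFold = perFold, fold = fold,
                 pooledAuc = rocAuc(pooledProb, labels)$auc,
                 pooledProb = pooledProb, model = final),
            class = "cnnCV")
}

#' @export
print.cnnCV <- function(x, ...) {
  cat(sprintf("%d-fold CV: pooled AUC %.3f, mean fold accuracy %.3f\n",
              nrow(x$perFold), x$pooledAuc,
              mean(x$perFold$accuracy, na.rm = TRUE)))
  invisible(x)
}
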