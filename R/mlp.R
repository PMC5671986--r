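# Softmax multilayer perceptron for probabilistic microstate labeling.
#
# Architecture: C inputs -> H tanh hidden units -> k softmax outputs,
# trained full-batch on a categorical cross-entropy loss with scaled
# conjugate gradients (default) or gradient descent with backtracking
# line search. Inputs are the z-normalized peak topographies; targets are
# the cluster labels. Early stopping watches the validation loss and the
# returned weights are those of the best-validation epoch, so the trained
# network generalizes the cluster assignment to every EEG timepoint as a
# probability distribution over microstates.

#' MLP training configuration
#'
#' @param hiddenUnits hidden layer width (default 15).
#' @param maxEpochs maximum training epochs (default 2000); training
#'   normally stops much earlier via the validation criterion.
#' @param splitFractions train/validation/test fractions, summing to 1
#'   (default 0.70/0.15/0.15, drawn uniformly at random by seed).
#' @param patience consecutive epochs the validation loss may exceed its
#'   running minimum before training stops (default 6).
#' @param seed integer seed controlling split, weight init and training.
#' @param optimizer `"scg"` (scaled conjugate gradient, default) or
#'   `"gdls"` (full-batch gradient descent with line search).
#' @return list of class `mlpConfig`.
#' @export
mlpConfig <- function(hiddenUnits = 15L, maxEpochs = 2000L,
                      splitFractions = c(train = 0.70, val = 0.15,
                                         test = 0.15),
                      patience = 6L, seed = NULL,
                      optimizer = c("scg", "gdls")) {
  optimizer <- match.arg(optimizer)
  stopifnot(hiddenUnits >= 1L, maxEpochs >= 1L, patience >= 1L,
            length(splitFractions) == 3L)
  if (any(splitFractions <= 0) || any(splitFractions >= 1) ||
      abs(sum(splitFractions) - 1) > 1e-9) {
    stop("splitFractions must lie in (0,1) and sum to 1")
  }
  structure(list(hiddenUnits = as.integer(hiddenUnits),
                 maxEpochs = as.integer(maxEpochs),
                 splitFractions = splitFractions,
                 patience = as.integer(patience), seed = seed,
                 optimizer = optimizer),
            class = "mlpConfig")
}

# pack/unpack the network weights into a single parameter vector
.mlpUnpack <- function(w, C, H, k) {
  i <- 0L
  W1 <- matrix(w[i + seq_len(C * H)], C, H); i <- i + C * H
  b1 <- w[i + seq_len(H)]; i <- i + H
  W2 <- matrix(w[i + seq_len(H * k)], H, k); i <- i + H * k
  b2 <- w[i + seq_len(k)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

.mlpForward <- function(X, W1, b1, W2, b2) {
  Z <- tanh(sweep(X %*% W1, 2L, b1, "+"))
  P <- softmaxRows(sweep(Z %*% W2, 2L, b2, "+"))
  list(Z = Z, P = P)
}

.crossEntropy <- function(P, yIdx) {
  -mean(log(pmax(P[yIdx], 1e-300)))
}

# loss and gradient of the cross entropy over (X, Y one-hot)
.mlpLossGrad <- function(w, X, Y, C, H, k) {
  par <- .mlpUnpack(w, C, H, k)
  fwd <- .mlpForward(X, par$W1, par$b1, par$W2, par$b2)
  N <- nrow(X)
  yIdx <- cbind(seq_len(N), max.col(Y, ties.method = "first"))
  loss <- .crossEntropy(fwd$P, yIdx)
  dA2 <- (fwd$P - Y) / N
  gW2 <- crossprod(fwd$Z, dA2)
  gb2 <- colSums(dA2)
  dZ <- tcrossprod(dA2, par$W2)
  dA1 <- dZ * (1 - fwd$Z^2)
  gW1 <- crossprod(X, dA1)
  gb1 <- colSums(dA1)
  list(loss = loss, grad = c(gW1, gb1, gW2, gb2))
}

# One full run of scaled conjugate gradients (Moller-style), calling
# `report(epoch, w)` after every weight update; stops when report()
# returns FALSE or maxEpochs is reached.
.scgOptimize <- function(w, fn, gr, maxEpochs, report) {
  sigma0 <- 1e-4
  lambda <- 1e-6; lambdaBar <- 0
  fw <- fn(w); g <- gr(w)
  r <- -g; p <- r
  success <- TRUE
  nPar <- length(w)
  delta <- 0; cnt <- 0L
  for (epoch in seq_len(maxEpochs)) {
    if (success) {
      pp <- sum(p * p)
      if (pp < 1e-300) break
      sigma <- sigma0 / sqrt(pp)
      s <- (gr(w + sigma * p) - g) / sigma
      delta <- sum(p * s)
    }
    pp <- sum(p * p)
    delta2 <- delta + (lambda - lambdaBar) * pp
    if (delta2 <= 0) {
      lambdaBar <- 2 * (lambda - delta2 / pp)
      delta2 <- -delta2 + lambda * pp
      lambda <- lambdaBar
    }
    mu <- sum(p * r)
    alpha <- mu / delta2
    wNew <- w + alpha * p
    fNew <- fn(wNew)
    if (!is.finite(fNew)) stop("MLP training diverged: non-finite loss")
    Delta <- 2 * delta2 * (fw - fNew) / (mu^2)
    if (Delta >= 0) {
      w <- wNew; fw <- fNew
      g <- gr(w)
      rNew <- -g
      lambdaBar <- 0; success <- TRUE
      cnt <- cnt + 1L
      if (cnt %% nPar == 0L) {
        p <- rNew
      } else {
        beta <- (sum(rNew * rNew) - sum(rNew * r)) / mu
        p <- rNew + beta * p
      }
      r <- rNew
      if (Delta >= 0.75) lambda <- lambda / 4
    } else {
      lambdaBar <- lambda
      success <- FALSE
    }
    if (Delta < 0.25) lambda <- lambda + delta2 * (1 - Delta) / pp
    if (lambda > 1e100) break
    if (!report(epoch, w)) break
  }
  w
}

.gdlsOptimize <- function(w, fn, gr, maxEpochs, report) {
  step <- 1
  fw <- fn(w)
  for (epoch in seq_len(maxEpochs)) {
    g <- gr(w)
    gn <- sum(g * g)
    if (gn < 1e-300) break
    # backtracking line search with Armijo condition
    step <- min(step * 2, 1e3)
    repeat {
      wNew <- w - step * g
      fNew <- fn(wNew)
      if (is.finite(fNew) && fNew <= fw - 1e-4 * step * gn) break
      step <- step / 2
      if (step < 1e-16) { wNew <- w; fNew <- fw; break }
    }
    w <- wNew; fw <- fNew
    if (!is.finite(fw)) stop("MLP training diverged: non-finite loss")
    if (!report(epoch, w)) break
  }
  w
}

#' Train a softmax MLP on cluster-labeled peak maps
#'
#' Minimizes the categorical cross entropy of the softmax outputs against
#' the cluster labels. The data are split uniformly at random into
#' train/validation/test by the configured fractions; training stops when
#' the validation loss has exceeded its running minimum for `patience`
#' consecutive epochs (or at `maxEpochs`), and the weights of the
#' best-validation epoch are returned. The whole procedure (split,
#' initialization, optimization) is reproducible from `cfg$seed`.
#'
#' @param maps N x C matrix of z-normalized maps (N >= 10 k).
#' @param labels integer cluster labels, one per row of `maps`.
#' @param cfg an [mlpConfig()].
#' @return an [MLPModel-class].
#' @export
trainMLP <- function(maps, labels, cfg = mlpConfig()) {
  X <- as.matrix(maps)
  labels <- as.integer(labels)
  N <- nrow(X)
  stopifnot(length(labels) == N)
  classIds <- sort(unique(labels))
  k <- length(classIds)
  if (N < 10L * k) {
    stop("need at least 10 labeled maps per class (have ", N, " for ",
         k, " classes)")
  }
  y <- match(labels, classIds)
  C <- ncol(X); H <- cfg$hiddenUnits

  withSeed(cfg$seed, {
    # uniformly random split
    idx <- sample.int(N)
    nTrain <- floor(cfg$splitFractions[[1L]] * N)
    nVal <- floor(cfg$splitFractions[[2L]] * N)
    trainIdx <- idx[seq_len(nTrain)]
    valIdx <- idx[nTrain + seq_len(nVal)]
    testIdx <- idx[(nTrain + nVal + 1L):N]
    if (length(unique(y[trainIdx])) < k) {
      stop("a class is absent from the training split; re-seed or use a ",
           "stratified split")
    }

    Y <- matrix(0, N, k)
    Y[cbind(seq_len(N), y)] <- 1
    Xtr <- X[trainIdx, , drop = FALSE]; Ytr <- Y[trainIdx, , drop = FALSE]
    Xva <- X[valIdx, , drop = FALSE]
    yvaIdx <- cbind(seq_along(valIdx), y[valIdx])

    # fan-in scaled uniform init
    w0 <- c(stats::runif(C * H, -1, 1) / sqrt(C),
            rep(0, H),
            stats::runif(H * k, -1, 1) / sqrt(H),
            rep(0, k))

    fn <- function(w) .mlpLossGrad(w, Xtr, Ytr, C, H, k)$loss
    gr <- function(w) .mlpLossGrad(w, Xtr, Ytr, C, H, k)$grad
    valLossOf <- function(w) {
      par <- .mlpUnpack(w, C, H, k)
      fwd <- .mlpForward(Xva, par$W1, par$b1, par$W2, par$b2)
      .crossEntropy(fwd$P, yvaIdx)
    }

    trainLoss <- numeric(0L); valLoss <- numeric(0L)
    bestVal <- Inf; bestW <- w0; bestEpoch <- 0L; bad <- 0L
    report <- function(epoch, w) {
      trainLoss[epoch] <<- fn(w)
      valLoss[epoch] <<- valLossOf(w)
      if (valLoss[epoch] < bestVal) {
        bestVal <<- valLoss[epoch]; bestW <<- w; bestEpoch <<- epoch
        bad <<- 0L
      } else {
        bad <<- bad + 1L
      }
      bad < cfg$patience
    }

    optim <- if (cfg$optimizer == "scg") .scgOptimize else .gdlsOptimize
    optim(w0, fn, gr, cfg$maxEpochs, report)

    par <- .mlpUnpack(bestW, C, H, k)
    new("MLPModel", W1 = par$W1, b1 = par$b1, W2 = par$W2, b2 = par$b2,
        classIds = as.integer(classIds), config = unclass(cfg),
        trainingReport = list(
          trainLoss = trainLoss, valLoss = valLoss,
          chosenEpoch = bestEpoch, epochs = length(trainLoss),
          splits = list(train = trainIdx, val = valIdx, test = testIdx),
          seed = cfg$seed))
  })
}

#' Probabilistic microstate labeling of a full EEG timecourse
#'
#' Every timepoint's scalp map is z-normalized across channels with the
#' same rule used for the training maps and passed through the network,
#' yielding a probability distribution over microstates per timepoint.
#' Zero-variance timepoints get the uniform distribution, are marked
#' unlabeled, and trigger a warning.
#'
#' @param model a trained [MLPModel-class].
#' @param rec an [EEGRecording-class] whose channel count matches the
#'   model's input width.
#' @return a [StateSequence-class].
#' @export
predictStateProbabilities <- function(model, rec) {
  stopifnot(is(model, "MLPModel"), is(rec, "EEGRecording"))
  X <- t(rec@data)
  if (ncol(X) != nrow(model@W1)) {
    stop("channel count (", ncol(X), ") does not match model input width (",
         nrow(model@W1), ")")
  }
  Z <- zNormalizeRows(X)
  degenerate <- attr(Z, "degenerate")
  attr(Z, "degenerate") <- NULL
  fwd <- .mlpForward(Z, model@W1, model@b1, model@W2, model@b2)
  P <- fwd$P
  if (any(degenerate)) {
    warning(sum(degenerate),
            " zero-variance timepoint(s) assigned the uniform distribution")
    P[degenerate, ] <- 1 / ncol(P)
  }
  .StateSequence(P, labeled = !degenerate,
                 templateRef = configHash(list(model@classIds, model@config)))
}

# ROC by threshold sweep for one class (one-vs-rest)
.rocCurve <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  pos <- positive[ord]
  nP <- sum(positive); nN <- length(positive) - nP
  tp <- cumsum(pos); fp <- cumsum(!pos)
  # collapse tied thresholds to their last point
  keep <- c(diff(scores[ord]) != 0, TRUE)
  tpr <- c(0, tp[keep] / nP)
  fpr <- c(0, fp[keep] / nN)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate a trained MLP per data split
#'
#' Computes, for each of the training/validation/test splits recorded in
#' the model's training report, the confusion matrix of the MLE labels and
#' one-vs-rest ROC curves (threshold sweep over the class probability)
#' with trapezoidal AUC per class. A class absent from a split has its ROC
#' flagged undefined (`NA` AUC).
#'
#' @param model a trained [MLPModel-class].
#' @param maps,labels the full data the model was trained on.
#' @return named list (`train`, `val`, `test`); each element has
#'   `confusion` (k x k matrix, rows = true class), `roc` (per-class list
#'   of `fpr`/`tpr` data.frames) and `auc` (named numeric).
#' @export
evaluateMLP <- function(model, maps, labels) {
  X <- as.matrix(maps)
  labels <- as.integer(labels)
  splits <- model@trainingReport$splits
  if (is.null(splits)) stop("model has no recorded splits")
  k <- length(model@classIds)
  y <- match(labels, model@classIds)

  out <- lapply(splits, function(idx) {
    Xi <- X[idx, , drop = FALSE]
    yi <- y[idx]
    P <- .mlpForward(Xi, model@W1, model@b1, model@W2, model@b2)$P
    pred <- max.col(P, ties.method = "first")
    confusion <- table(factor(yi, levels = seq_len(k)),
                       factor(pred, levels = seq_len(k)))
    confusion <- matrix(as.integer(confusion), k, k,
                        dimnames = list(true = model@classIds,
                                        predicted = model@classIds))
    roc <- vector("list", k); auc <- rep(NA_real_, k)
    names(roc) <- names(auc) <- model@classIds
    for (j in seq_len(k)) {
      positive <- yi == j
      if (any(positive) && !all(positive)) {
        r <- .rocCurve(P[, j], positive)
        roc[[j]] <- r$curve
        auc[j] <- r$auc
      }
    }
    list(confusion = confusion, roc = roc, auc = auc,
         accuracy = mean(pred == yi))
  })
  names(out) <- names(splits)
  out
}
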