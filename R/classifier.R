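## Cluster stabilization: a supervised classifier trained to imitate a
## reference clustering, so that new recordings receive consistent labels.

.softmax <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

## Single-hidden-layer ReLU network with inverted dropout and a softmax
## output, trained by RMSprop on the categorical cross-entropy.
.trainMlp <- function(X, y, nClasses, hiddenWidth, dropoutRate, epochs,
                      batchSize, learningRate, seed) {
  n <- nrow(X); d <- ncol(X); K <- nClasses
  Yhot <- matrix(0, n, K); Yhot[cbind(seq_len(n), y)] <- 1
  .withSeed(seed, {
    W1 <- matrix(stats::rnorm(d * hiddenWidth, sd = sqrt(2 / d)), d)
    b1 <- rep(0, hiddenWidth)
    W2 <- matrix(stats::rnorm(hiddenWidth * K, sd = sqrt(2 / hiddenWidth)),
                 hiddenWidth)
    b2 <- rep(0, K)
    cache <- lapply(list(W1, b1, W2, b2), function(p) p * 0)
    rho <- 0.9; eps <- 1e-8
    lossLog <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      epLoss <- 0
      for (start in seq(1L, n, by = batchSize)) {
        idx <- ord[start:min(start + batchSize - 1L, n)]
        Xb <- X[idx, , drop = FALSE]; Yb <- Yhot[idx, , drop = FALSE]
        nb <- length(idx)
        H <- Xb %*% W1
        H <- sweep(H, 2, b1, "+")
        A <- pmax(H, 0)
        if (dropoutRate > 0) {
          mask <- matrix(stats::runif(nb * hiddenWidth) >= dropoutRate,
                         nb) / (1 - dropoutRate)
          A <- A * mask
        }
        S <- sweep(A %*% W2, 2, b2, "+")
        P <- .softmax(S)
        epLoss <- epLoss - sum(Yb * log(pmax(P, 1e-12)))
        dS <- (P - Yb) / nb
        gW2 <- t(A) %*% dS; gb2 <- colSums(dS)
        dA <- dS %*% t(W2)
        if (dropoutRate > 0) dA <- dA * mask
        dH <- dA * (H > 0)
        gW1 <- t(Xb) %*% dH; gb1 <- colSums(dH)
        g <- list(gW1, gb1, gW2, gb2)
        for (pi in 1:4) cache[[pi]] <- rho * cache[[pi]] + (1 - rho) * g[[pi]]^2
        W1 <- W1 - learningRate * g[[1]] / (sqrt(cache[[1]]) + eps)
        b1 <- b1 - learningRate * g[[2]] / (sqrt(cache[[2]]) + eps)
        W2 <- W2 - learningRate * g[[3]] / (sqrt(cache[[3]]) + eps)
        b2 <- b2 - learningRate * g[[4]] / (sqrt(cache[[4]]) + eps)
      }
      lossLog[ep] <- epLoss / n
    }
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, lossLog = lossLog)
  })
}

#' Train a cluster-imitation classifier
#'
#' Fits a probabilistic multi-class model to reproduce reference cluster
#' labels from standardized feature rows. The default `"mlp"` backend is a
#' single-hidden-layer rectified-linear network (1,024 units, dropout 0.4,
#' softmax output) trained for 30 epochs with batch size 512 by RMSprop on
#' the categorical cross-entropy, with the data shuffled each epoch. The
#' `"multinom"` backend is a lightweight multinomial logistic regression
#' for fast runs.
#'
#' @param X numeric matrix of standardized feature rows.
#' @param labels integer reference cluster labels in 1..nClusters.
#' @param nClusters number of clusters (defaults to `max(labels)`). Clusters
#'   absent from `labels` are kept in the output layer with zero support,
#'   with a warning.
#' @param backend `"mlp"` or `"multinom"`.
#' @param hiddenWidth,dropoutRate,epochs,batchSize,learningRate mlp
#'   hyperparameters (defaults 1024, 0.4, 30, 512, 1e-3).
#' @param seed integer seed: training is fully reproducible.
#' @return A [ClusterClassifier-class].
#' @export
trainClassifier <- function(X, labels, nClusters = max(labels),
                            backend = c("mlp", "multinom"),
                            hiddenWidth = 1024, dropoutRate = 0.4,
                            epochs = 30, batchSize = 512,
                            learningRate = 1e-3, seed = 1L) {
  backend <- match.arg(backend)
  labels <- as.integer(labels)
  nClusters <- as.integer(nClusters)
  stopifnot(nrow(X) == length(labels), all(labels >= 1L),
            all(labels <= nClusters))
  absent <- setdiff(seq_len(nClusters), unique(labels))
  if (length(absent))
    warning("clusters absent from training labels (kept with zero ",
            "support): ", paste(absent, collapse = ", "))
  meta <- list(epochs = epochs, batchSize = batchSize,
               hiddenWidth = hiddenWidth, dropoutRate = dropoutRate,
               learningRate = learningRate, seed = as.integer(seed))
  if (backend == "mlp") {
    fit <- .trainMlp(X, labels, nClusters, hiddenWidth, dropoutRate,
                     epochs, batchSize, learningRate, seed)
    meta$lossLog <- fit$lossLog
    model <- fit[c("W1", "b1", "W2", "b2")]
  } else {
    if (length(unique(labels)) == 1L) {
      model <- list(fit = NULL, seen = unique(labels))
      return(new("ClusterClassifier", backend = backend,
                 inputWidth = ncol(X), outputWidth = nClusters,
                 model = model, trainingMeta = meta))
    }
    df <- data.frame(.y = factor(labels, levels = seq_len(nClusters)))
    df$.y <- droplevels(df$.y)
    Xdf <- as.data.frame(X)
    names(Xdf) <- paste0("V", seq_len(ncol(X)))
    fit <- .withSeed(seed, nnet::multinom(
      .y ~ ., data = cbind(df, Xdf), trace = FALSE,
      MaxNWts = 1e6, maxit = 200))
    model <- list(fit = fit, seen = sort(unique(labels)))
  }
  new("ClusterClassifier", backend = backend,
      inputWidth = ncol(X), outputWidth = nClusters,
      model = model, trainingMeta = meta)
}

#' Class-probability predictions
#'
#' @param classifier a [ClusterClassifier-class].
#' @param X numeric matrix of standardized feature rows (width must match
#'   the classifier input width).
#' @return n x nClusters matrix of probabilities; rows sum to 1.
#' @export
predictProb <- function(classifier, X) {
  X <- as.matrix(X)
  if (ncol(X) != classifier@inputWidth)
    stop("feature width ", ncol(X), " does not match classifier input ",
         classifier@inputWidth)
  K <- classifier@outputWidth
  if (classifier@backend == "mlp") {
    m <- classifier@model
    A <- pmax(sweep(X %*% m$W1, 2, m$b1, "+"), 0)
    .softmax(sweep(A %*% m$W2, 2, m$b2, "+"))
  } else {
    m <- classifier@model
    if (is.null(m$fit)) {  # degenerate single-class training set
      out <- matrix(0, nrow(X), K)
      out[, m$seen] <- 1
      return(out)
    }
    newdata <- as.data.frame(X)
    names(newdata) <- paste0("V", seq_len(ncol(X)))
    pr <- stats::predict(m$fit, newdata = newdata, type = "probs")
    if (is.null(dim(pr))) {
      if (length(m$seen) == 2L) pr <- cbind(1 - pr, pr)  # two-class vector
      else pr <- matrix(pr, nrow = 1L)                   # single probe row
    }
    out <- matrix(0, nrow(X), K)
    out[, m$seen] <- pr
    out
  }
}

#' Apply a classifier to an expanded feature matrix
#'
#' Standardizes the rows with the persisted standardizer of the reference
#' clustering, then labels each frame by the highest-probability cluster
#' (ties broken by the lowest cluster id). Frame offsets propagate from the
#' expanded matrix.
#'
#' @param classifier a [ClusterClassifier-class].
#' @param standardizer the [ColumnStandardizer-class] of the reference fit.
#' @param X a [TemporalFeatureMatrix-class] or plain matrix.
#' @param fps frames per second for the label sequence.
#' @return A [LabelSequence-class].
#' @export
applyClassifier <- function(classifier, standardizer, X, fps = 25) {
  tfm <- NULL
  if (is(X, "TemporalFeatureMatrix")) { tfm <- X; X <- tfm@values }
  Z <- applyStandardizer(standardizer, X)
  P <- predictProb(classifier, Z)
  labels <- as.integer(max.col(P, ties.method = "first"))
  new("LabelSequence",
      recordingId = if (is.null(tfm)) "rows" else tfm@recordingId,
      labels = labels, alphabet = seq_len(classifier@outputWidth),
      fps = fps, frameOffset = if (is.null(tfm)) 0L else tfm@frameOffset)
}

## Per-cluster precision/recall/F1 from predicted and true labels over a
## fixed alphabet.
.perClusterMetrics <- function(truth, pred, nClusters) {
  cm <- table(factor(truth, levels = seq_len(nClusters)),
              factor(pred, levels = seq_len(nClusters)))
  tp <- diag(cm)
  predTot <- colSums(cm)
  truthTot <- rowSums(cm)
  precision <- ifelse(predTot > 0, tp / predTot, NA_real_)
  recall <- ifelse(truthTot > 0, tp / truthTot, NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  data.frame(cluster = seq_len(nClusters), precision = as.numeric(precision),
             recall = as.numeric(recall), f1 = as.numeric(f1),
             support = as.numeric(truthTot))
}

#' Recording-level cross-validation of the cluster classifier
#'
#' Shuffles the recordings, sets aside a different subset for validation in
#' each fold, trains on the remainder and scores per-cluster precision,
#' recall and F1 on the held-out frames. Folds are formed at the recording
#' level, so no validation recording contributes any frame to its fold's
#' training set.
#'
#' @param recordings named list; each element is a list with `X`
#'   (standardized feature matrix) and `labels` (integer reference labels).
#' @param folds number of folds (default 10; must not exceed the number of
#'   recordings).
#' @param nClusters cluster count (defaults to the max label observed).
#' @param seed integer seed for the shuffle and the trainings.
#' @param ... passed to [trainClassifier()] (e.g. `backend`,
#'   `hiddenWidth`, `epochs`).
#' @return A [CVReport-class].
#' @export
crossvalidate <- function(recordings, folds = 10, nClusters = NULL,
                          seed = 1L, ...) {
  nrec <- length(recordings)
  if (folds > nrec)
    stop("more folds (", folds, ") than recordings (", nrec, ")")
  ids <- names(recordings)
  if (is.null(ids)) ids <- as.character(seq_len(nrec))
  if (is.null(nClusters))
    nClusters <- max(vapply(recordings, function(r) max(r$labels), 1L))
  ord <- .withSeed(seed, sample.int(nrec))
  foldOf <- rep(NA_integer_, nrec)
  foldOf[ord] <- rep(seq_len(folds), length.out = nrec)
  rows <- list(); foldIds <- vector("list", folds)
  for (f in seq_len(folds)) {
    val <- which(foldOf == f)
    trn <- which(foldOf != f)
    foldIds[[f]] <- ids[val]
    Xtr <- do.call(rbind, lapply(recordings[trn], `[[`, "X"))
    ytr <- unlist(lapply(recordings[trn], `[[`, "labels"))
    clf <- trainClassifier(Xtr, ytr, nClusters = nClusters,
                           seed = seed + f, ...)
    Xva <- do.call(rbind, lapply(recordings[val], `[[`, "X"))
    yva <- unlist(lapply(recordings[val], `[[`, "labels"))
    pred <- as.integer(max.col(predictProb(clf, Xva), ties.method = "first"))
    tab <- .perClusterMetrics(yva, pred, nClusters)
    tab <- cbind(fold = f, tab)
    rows[[f]] <- tab
  }
  new("CVReport", perCluster = do.call(rbind, rows), folds = foldIds)
}

#' Summarize a cross-validation report
#'
#' @param report a [CVReport-class].
#' @return list with `perFold` (mean precision/recall/F1 per fold) and
#'   `pooled` (means over all fold-cluster entries), both ignoring
#'   unsupported clusters.
#' @export
cvSummary <- function(report) {
  tab <- report@perCluster
  agg <- stats::aggregate(tab[c("precision", "recall", "f1")],
                          by = list(fold = tab$fold), FUN = mean,
                          na.rm = TRUE)
  pooled <- colMeans(tab[c("precision", "recall", "f1")], na.rm = TRUE)
  list(perFold = agg, pooled = pooled)
}
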