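## Shared fixture builders. Everything is generated in code; no data files.

## A minimal recording: points moving on straight lines inside a square
## arena whose four corners are tracked, all likelihoods 1.
squareRecording <- function(n = 100, fps = 25, side = 400, margin = 50,
                            pts = c("bodycentre", "nose")) {
  lo <- margin; hi <- margin + side
  x <- y <- lk <- matrix(1, n, length(pts) + 4L,
                         dimnames = list(NULL, c(pts, paste0("corner", 1:4))))
  ctr <- (lo + hi) / 2
  for (p in seq_along(pts)) {
    x[, p] <- ctr + seq(0, 20, length.out = n) + 3 * (p - 1)
    y[, p] <- ctr + 3 * (p - 1)
  }
  corners <- rbind(c(lo, lo), c(hi, lo), c(hi, hi), c(lo, hi))
  for (cpt in 1:4) {
    x[, length(pts) + cpt] <- corners[cpt, 1]
    y[, length(pts) + cpt] <- corners[cpt, 2]
  }
  TrackingRecording(x, y, lk, fps = fps, recordingId = "square")
}

withArena <- function(rec, realSizeCm2 = 1600) {
  rec@arena <- inferArena(rec, paste0("corner", 1:4), realSizeCm2)
  rec
}

## Random label sequences for oracle sweeps.
randomLabelSeq <- function(len, nc, fps = 25) {
  LabelSequence(sample.int(nc, len, replace = TRUE),
                alphabet = seq_len(nc), fps = fps)
}

## Brute-force transition counting: walk consecutive distinct labels.
bruteTransitions <- function(labels, alphabet) {
  nc <- length(alphabet)
  m <- matrix(0L, nc, nc, dimnames = list(alphabet, alphabet))
  prev <- labels[1]
  for (f in labels[-1]) {
    if (f != prev) {
      i <- match(prev, alphabet); j <- match(f, alphabet)
      m[i, j] <- m[i, j] + 1L
      prev <- f
    }
  }
  m
}

## Brute-force windowed mode with smallest-id tie break.
bruteSmooth <- function(labels, h) {
  n <- length(labels)
  out <- integer(n)
  for (f in seq_len(n)) {
    win <- labels[max(1, f - h):min(n, f + h)]
    tab <- table(win)
    cand <- as.integer(names(tab)[tab == max(tab)])
    out[f] <- min(cand)
  }
  out
}

## Deterministic "disjoint pattern" groups: control cycles over the lower
## clusters, test over the upper ones, with per-recording length variation.
disjointPatternGroups <- function(nPer = 15, nc = 25, reps = 30) {
  lower <- seq_len(floor(nc / 2))
  upper <- setdiff(seq_len(nc), lower)
  mk <- function(states, id, extra) {
    lab <- rep(rep(states, each = 3), reps + extra)
    transitionMatrix(LabelSequence(lab, alphabet = seq_len(nc),
                                   recordingId = id))
  }
  groupedTransitionSet(
    lapply(seq_len(nPer), function(i) mk(lower, paste0("c", i), i %% 3)),
    lapply(seq_len(nPer), function(i) mk(upper, paste0("t", i), i %% 3)))
}

## 60 synthetic recordings whose feature rows form `nc` well-separated
## clusters with known labels (for classifier CV).
separableRecordings <- function(nRec = 60, nc = 25, dim = 8,
                                framesPer = 5, sepScale = 12, noise = 1,
                                seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(nc * dim), nc) * sepScale
  recs <- list()
  for (r in seq_len(nRec)) {
    labels <- rep(seq_len(nc), framesPer)
    X <- centers[labels, ] + matrix(rnorm(length(labels) * dim, sd = noise),
                                    length(labels))
    recs[[sprintf("rec%02d", r)]] <- list(X = X, labels = labels)
  }
  recs
}

## Full pose-to-BFA pipeline on a synthetic experiment: simulate pose from
## each recording's labels, extract/normalize/expand features, k-means with
## k = number of generative states on a thinned row subset, assign every
## frame, smooth, count transitions, and run the BFA permutation test.
poseStateTemplates <- function() list(
  "1" = list(speedRange = c(0, 1), bodyLength = 4),
  "2" = list(speedRange = c(14, 17), bodyLength = 9),
  "3" = list(speedRange = c(38, 44), bodyLength = 14))

runPosePipeline <- function(ex, seed, halfwidth = 5, thin = 8,
                            nPerm = 500) {
  templates <- poseStateTemplates()
  tfms <- list()
  for (id in names(ex@labels)) {
    rec <- simulatePose(ex@labels[[id]], templates = templates,
                        jitterSd = 0.5,
                        seed = seed * 1000 + match(id, names(ex@labels)))
    rec@arena <- inferArena(rec, paste0("corner", 1:4), 1600)
    rec <- preprocessRecording(rec)
    fm <- normalizeFeatures(extractFeatures(rec), defaultFeatureRegistry())
    tfms[[id]] <- temporalExpand(fm, halfwidth)
  }
  X <- do.call(rbind, lapply(tfms, function(t)
    t@values[seq(1, nrow(t@values), by = thin), ]))
  nStates <- length(ex@kernels[[1]]@meanRun)
  fit <- fitKmeans(X, k = nStates, seed = seed, restarts = 10)
  tms <- lapply(names(tfms), function(id)
    transitionMatrix(smoothLabels(
      assignClusters(fit$model, fit$standardizer, tfms[[id]]), 5)))
  names(tms) <- names(tfms)
  g <- groupedTransitionSet(unname(tms[ex@groups == "control"]),
                            unname(tms[ex@groups == "treated"]))
  bfaPermutation(g, nPerm = nPerm, seed = seed)
}
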