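#' Construct a LabelSequence
#'
#' @param labels integer cluster ids, one per frame.
#' @param alphabet full cluster-id set of the analysis (default
#'   `1..max(labels)`).
#' @param fps frames per second.
#' @param recordingId identifier.
#' @param frameOffset frames dropped at the start by temporal expansion.
#' @return A [LabelSequence-class].
#' @export
LabelSequence <- function(labels, alphabet = NULL, fps = 25,
                          recordingId = "recording", frameOffset = 0L) {
  labels <- as.integer(labels)
  if (is.null(alphabet)) alphabet <- seq_len(max(labels))
  new("LabelSequence", recordingId = recordingId, labels = labels,
      alphabet = as.integer(alphabet), fps = fps,
      frameOffset = as.integer(frameOffset))
}

#' Modal smoothing of a label sequence
#'
#' Replaces every frame's label with the most abundant label in a sliding
#' window of +/- `halfwidth` frames around it. Windows shrink at the
#' sequence edges; ties go to the smallest cluster id. Removes single-frame
#' misclassification spikes while leaving long runs untouched.
#'
#' @param seq a [LabelSequence-class].
#' @param halfwidth window half width in frames (default 5).
#' @return The smoothed [LabelSequence-class].
#' @export
smoothLabels <- function(seq, halfwidth = 5) {
  h <- as.integer(halfwidth)
  if (h < 0L) stop("halfwidth must be nonnegative")
  if (h == 0L) return(seq)
  lab <- seq@labels
  n <- length(lab)
  alpha <- sort(seq@alphabet)
  ## cumulative per-cluster counts allow O(n * NC) window modes
  out <- integer(n)
  counts <- matrix(0L, n + 1L, length(alpha))
  for (j in seq_along(alpha))
    counts[, j] <- c(0L, cumsum(lab == alpha[j]))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  win <- counts[hi + 1L, , drop = FALSE] - counts[lo, , drop = FALSE]
  best <- max.col(win, ties.method = "first")  # first = smallest id
  out <- alpha[best]
  new("LabelSequence", recordingId = seq@recordingId, labels = out,
      alphabet = seq@alphabet, fps = seq@fps, frameOffset = seq@frameOffset)
}

## Occurrence vector: the label sequence with consecutive repeats removed.
.occurrenceVector <- function(labels) rle(labels)$values

#' Transition matrix of a label sequence
#'
#' Removes consecutive repeats from the label vector to form the occurrence
#' vector, then counts lag-1 pairs of that vector into an NC x NC
#' contingency table over the declared alphabet. The diagonal is
#' structurally zero and the total count equals (number of runs) - 1.
#'
#' @param seq a [LabelSequence-class].
#' @return A [TransitionMatrix-class].
#' @export
transitionMatrix <- function(seq) {
  alpha <- seq@alphabet
  if (!all(seq@labels %in% alpha))
    stop("labels outside the declared alphabet")
  occ <- .occurrenceVector(seq@labels)
  f <- factor(occ, levels = alpha)
  if (length(occ) > 1L) {
    counts <- table(from = f[-length(f)], to = f[-1])
  } else {
    counts <- table(from = f[0], to = f[0])
  }
  counts <- matrix(as.integer(counts), length(alpha), length(alpha),
                   dimnames = list(from = alpha, to = alpha))
  new("TransitionMatrix", counts = counts, recordingId = seq@recordingId,
      alphabet = alpha)
}

#' Per-cluster usage metrics of a label sequence
#'
#' @param seq a [LabelSequence-class].
#' @return data.frame per cluster of the alphabet: `occurrences` (number of
#'   runs), `frames`, `seconds`, plus a list-columns pair `onsets`/`offsets`
#'   with the run boundary frame indices (1-based, relative to the
#'   sequence).
#' @export
computeMetrics <- function(seq) {
  lab <- seq@labels
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  alpha <- seq@alphabet
  occurrences <- frames <- integer(length(alpha))
  onsets <- offsets <- vector("list", length(alpha))
  for (i in seq_along(alpha)) {
    sel <- r$values == alpha[i]
    occurrences[i] <- sum(sel)
    frames[i] <- sum(r$lengths[sel])
    onsets[[i]] <- starts[sel]
    offsets[[i]] <- ends[sel]
  }
  out <- data.frame(cluster = alpha, occurrences = occurrences,
                    frames = frames, seconds = frames / seq@fps)
  out$onsets <- onsets
  out$offsets <- offsets
  out
}

#' Stabilize a transition matrix against a control group
#'
#' Subtracts the elementwise mean of the control recordings' transition
#' matrices, so that the stabilized matrices of the control set itself
#' average exactly to zero.
#'
#' @param T a [TransitionMatrix-class].
#' @param controls nonempty list of [TransitionMatrix-class] on the same
#'   alphabet.
#' @return A [StabilizedTransitionMatrix-class].
#' @export
stabilize <- function(T, controls) {
  if (length(controls) == 0L) stop("control set must be nonempty")
  for (ctl in controls)
    if (!identical(ctl@alphabet, T@alphabet))
      stop("alphabet mismatch between matrix and controls")
  ctlMean <- Reduce(`+`, lapply(controls, function(m) m@counts)) /
    length(controls)
  new("StabilizedTransitionMatrix",
      values = T@counts - ctlMean,
      recordingId = T@recordingId, alphabet = T@alphabet,
      controlReference = vapply(controls, function(m) m@recordingId,
                                character(1)))
}

#' Cross-tabulate two label sequences
#'
#' Frame-by-frame contingency table of the labels of a source and a target
#' labeling of the same recording (e.g. two segmentation methods), after
#' aligning their frame offsets.
#'
#' @param seqA,seqB [LabelSequence-class] objects over the same frames.
#' @return Integer matrix; cell (a, b) counts frames labeled a in A and b
#'   in B.
#' @export
crossTabulate <- function(seqA, seqB) {
  offA <- seqA@frameOffset; offB <- seqB@frameOffset
  endA <- offA + length(seqA@labels); endB <- offB + length(seqB@labels)
  if (endA != endB)
    stop("label sequences cannot be aligned: they end at original frames ",
         endA, " vs ", endB)
  ## trim to the common frame range of the two labelings
  lead <- max(offA, offB)
  a <- seqA@labels[(lead - offA + 1L):length(seqA@labels)]
  b <- seqB@labels[(lead - offB + 1L):length(seqB@labels)]
  tab <- table(factor(a, levels = seqA@alphabet),
               factor(b, levels = seqB@alphabet))
  matrix(as.integer(tab), length(seqA@alphabet), length(seqB@alphabet),
         dimnames = list(source = seqA@alphabet, target = seqB@alphabet))
}

#' Split a label sequence into time bins
#'
#' Cuts the sequence into contiguous non-overlapping bins of `binLength`
#' seconds. Per-bin metrics and transition matrices are computed
#' independently, so a run spanning a bin boundary contributes no
#' cross-boundary transition.
#'
#' @param seq a [LabelSequence-class].
#' @param binLength bin length in seconds.
#' @return List of [LabelSequence-class] bins.
#' @export
binLabels <- function(seq, binLength) {
  if (binLength <= 0) stop("binLength must be positive")
  framesPerBin <- as.integer(round(binLength * seq@fps))
  n <- length(seq@labels)
  if (framesPerBin > n)
    warning("bin longer than the recording; returning a single bin")
  starts <- seq.int(1L, n, by = framesPerBin)
  lapply(seq_along(starts), function(i) {
    idx <- starts[i]:min(starts[i] + framesPerBin - 1L, n)
    new("LabelSequence",
        recordingId = paste0(seq@recordingId, "_bin", i),
        labels = seq@labels[idx], alphabet = seq@alphabet, fps = seq@fps,
        frameOffset = seq@frameOffset + starts[i] - 1L)
  })
}

#' Read a label sequence from CSV
#'
#' Accepts the two-column dialect (`frame`, `cluster`) or a single `cluster`
#' column, as written by [writeLabelSequence()] or by external segmentation
#' tools.
#'
#' @param path CSV path.
#' @param alphabet full cluster-id set (default: observed ids).
#' @param fps frames per second.
#' @param recordingId identifier; defaults to the file base name.
#' @return A [LabelSequence-class].
#' @export
readLabelSequence <- function(path, alphabet = NULL, fps = 25,
                              recordingId = NULL) {
  df <- utils::read.csv(path)
  col <- if ("cluster" %in% names(df)) df$cluster else df[[ncol(df)]]
  if (is.null(recordingId))
    recordingId <- sub("\\.[^.]*$", "", basename(path))
  LabelSequence(col, alphabet = alphabet, fps = fps,
                recordingId = recordingId)
}

#' Write a label sequence to CSV
#' @param seq a [LabelSequence-class].
#' @param path output path.
#' @export
writeLabelSequence <- function(seq, path) {
  utils::write.csv(
    data.frame(frame = seq@frameOffset + seq_along(seq@labels),
               cluster = seq@labels),
    path, row.names = FALSE)
  invisible(path)
}

#' Write a transition matrix as square CSV
#' @param T a [TransitionMatrix-class] or
#'   [StabilizedTransitionMatrix-class].
#' @param path output path.
#' @export
writeTransitionMatrix <- function(T, path) {
  m <- if (is(T, "TransitionMatrix")) T@counts else T@values
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
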