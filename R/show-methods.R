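#' @describeIn TrackingRecording-class compact display
#' @param object the object.
#' @export
setMethod("show", "TrackingRecording", function(object) {
  cat("TrackingRecording '", object@recordingId, "': ",
      nFrames(object), " frames, ", ncol(object@x), " points @ ",
      object@fps, " fps\n", sep = "")
  cat("  arena: ", if (is.null(object@arena)) "not inferred" else
    sprintf("%d-corner polygon, %.3f px/cm", nrow(object@arena@corners),
            object@arena@pxPerCm), "\n", sep = "")
  cat("  kinematics: ",
      if (nrow(object@speed) > 0) "available" else "not computed",
      "\n", sep = "")
})

#' @describeIn LabelSequence-class compact display
#' @param object the object.
#' @export
setMethod("show", "LabelSequence", function(object) {
  cat("LabelSequence '", object@recordingId, "': ",
      length(object@labels), " frames over ", length(object@alphabet),
      " clusters (offset ", object@frameOffset, ", ", object@fps,
      " fps)\n", sep = "")
})

#' @describeIn TransitionMatrix-class compact display
#' @param object the object.
#' @export
setMethod("show", "TransitionMatrix", function(object) {
  cat("TransitionMatrix '", object@recordingId, "': ",
      length(object@alphabet), "x", length(object@alphabet),
      ", total transitions ", sum(object@counts), "\n", sep = "")
})

#' @describeIn BFAResult-class structured report
#' @param object the object.
#' @export
setMethod("show", "BFAResult", function(object) {
  cat("Behavioral flow analysis (", object@nPerm, " permutations)\n",
      sep = "")
  cat(sprintf("  Manhattan distance : %.4g\n", object@distance))
  cat(sprintf("  percentile         : %.1f\n", object@percentile))
  cat(sprintf("  z                  : %.2f\n", object@z))
  cat(sprintf("  right-tailed P     : %.3g\n", object@p))
})

#' @describeIn BFLScores-class compact display
#' @param object the object.
#' @export
setMethod("show", "BFLScores", function(object) {
  cat("BFL scores for", nrow(object@table), "samples",
      sprintf("(%d degenerate)\n", sum(object@table$degenerate)))
  print(utils::head(object@table, 10))
  if (nrow(object@table) > 10) cat("  ...\n")
})

#' @describeIn PowerCurve-class compact display
#' @param object the object.
#' @export
setMethod("show", "PowerCurve", function(object) {
  cat(sprintf("Power curve: d = %.3g, alpha = %.3g\n", object@d,
              object@alpha))
  print(object@table, row.names = FALSE)
})

#' @describeIn EmbeddingResult-class compact display
#' @param object the object.
#' @export
setMethod("show", "EmbeddingResult", function(object) {
  cat("2D embedding of", nrow(object@coords), "recordings (",
      object@params$method, ")\n")
})

#' Access the per-animal score table
#' @param scores a [BFLScores-class].
#' @return data.frame of per-sample scores.
#' @export
bflTable <- function(scores) scores@table

#' Access transition counts
#' @param T a [TransitionMatrix-class].
#' @return Integer NC x NC count matrix.
#' @export
transitionCounts <- function(T) T@counts

#' Access embedding coordinates
#' @param embedding an [EmbeddingResult-class].
#' @return n x 2 coordinate matrix.
#' @export
embeddingCoords <- function(embedding) embedding@coords

#' Access the labels of a LabelSequence
#' @param seq a [LabelSequence-class].
#' @return Integer label vector.
#' @export
labelValues <- function(seq) seq@labels

#' Access the cluster alphabet of a LabelSequence
#' @param seq a [LabelSequence-class].
#' @return Integer alphabet.
#' @export
labelAlphabet <- function(seq) seq@alphabet

#' Access the values of a feature matrix
#' @param fm a [FeatureMatrix-class] or [TemporalFeatureMatrix-class].
#' @return Numeric matrix.
#' @export
featureValues <- function(fm) fm@values
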