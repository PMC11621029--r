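#' @import methods
NULL

## ---------------------------------------------------------------------------
## Tracking containers
## ---------------------------------------------------------------------------

#' Arena geometry and calibration
#'
#' Describes the arena of a recording in image coordinates (origin top-left,
#' y increasing downward): the corner polygon, named zone polygons, the
#' pixel-to-centimeter conversion factor and the scale factor of the existence
#' polygon used to reject tracking points outside the arena.
#'
#' @slot corners numeric matrix (vertices x 2) of the arena corner polygon,
#'   ordered along the boundary.
#' @slot zones named list of polygon matrices (vertices x 2).
#' @slot pxPerCm linear conversion factor, pixels per centimeter.
#' @slot existenceScale scale factor applied about the polygon centroid to
#'   obtain the existence polygon (default 1.3).
#' @exportClass ArenaGeometry
setClass("ArenaGeometry",
  representation(
    corners = "matrix",
    zones = "list",
    pxPerCm = "numeric",
    existenceScale = "numeric"
  ),
  prototype(zones = list(), pxPerCm = 1, existenceScale = 1.3)
)

setValidity("ArenaGeometry", function(object) {
  msg <- NULL
  if (nrow(object@corners) < 3L)
    msg <- c(msg, "corner polygon needs at least 3 vertices")
  if (ncol(object@corners) != 2L)
    msg <- c(msg, "corners must be a two-column (x, y) matrix")
  if (nrow(object@corners) >= 3L && polygonArea(object@corners) <= 0)
    msg <- c(msg, "corner polygon has zero area (collinear vertices?)")
  if (length(object@pxPerCm) != 1L || object@pxPerCm <= 0)
    msg <- c(msg, "pxPerCm must be a single positive number")
  if (length(object@existenceScale) != 1L || object@existenceScale <= 0)
    msg <- c(msg, "existenceScale must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' Pose-estimation tracking recording
#'
#' Holds per-frame x/y coordinates and tracking likelihoods for a set of
#' named body points, the frame rate, the inferred arena geometry and (after
#' preprocessing) per-point kinematics. Coordinates follow the image
#' convention (origin top-left, y downward), as emitted by markerless
#' pose-estimation tools.
#'
#' @slot recordingId character identifier.
#' @slot fps frames per second.
#' @slot x,y,likelihood numeric N x P matrices, one column per body point
#'   (column names are the point names).
#' @slot arena an [ArenaGeometry-class] or `NULL` before calibration.
#' @slot speed,acceleration numeric N x P matrices in cm/s and cm/s^2,
#'   empty (0 x 0) before preprocessing.
#' @exportClass TrackingRecording
setClass("TrackingRecording",
  representation(
    recordingId = "character",
    fps = "numeric",
    x = "matrix",
    y = "matrix",
    likelihood = "matrix",
    arena = "ANY",
    speed = "matrix",
    acceleration = "matrix"
  ),
  prototype(
    recordingId = "recording", fps = 25,
    arena = NULL,
    speed = matrix(numeric(), 0, 0),
    acceleration = matrix(numeric(), 0, 0)
  )
)

setValidity("TrackingRecording", function(object) {
  msg <- NULL
  dims <- list(object@x, object@y, object@likelihood)
  if (length(unique(vapply(dims, nrow, 1L))) != 1L ||
      length(unique(vapply(dims, ncol, 1L))) != 1L)
    msg <- c(msg, "x, y and likelihood must share dimensions")
  if (!identical(colnames(object@x), colnames(object@y)) ||
      !identical(colnames(object@x), colnames(object@likelihood)))
    msg <- c(msg, "x, y and likelihood must share column (point) names")
  lk <- object@likelihood
  if (length(lk) && any(lk < 0 | lk > 1, na.rm = TRUE))
    msg <- c(msg, "likelihoods must lie in [0, 1]")
  if (length(object@fps) != 1L || object@fps <= 0)
    msg <- c(msg, "fps must be a single positive number")
  for (kin in list(object@speed, object@acceleration)) {
    if (nrow(kin) > 0L && nrow(kin) != nrow(object@x))
      msg <- c(msg, "kinematics must align with the frame count")
  }
  if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## Features
## ---------------------------------------------------------------------------

#' Ordered registry of per-frame features
#'
#' Fixed, ordered list of feature definitions over the tracked body points.
#' Five kinds are supported: `point_acceleration`, `pair_distance`,
#' `pairpair_angle`, `border_proximity` and `polygon_area`. Each feature
#' carries its normalization rule: z-score for distances and areas, raw for
#' angles, and fixed linear factors for border proximity (0.1) and point
#' acceleration (4).
#'
#' @slot specs data.frame with columns `name`, `kind`, `operands`
#'   (comma-separated body-point names), `normalization`
#'   (`"zscore"`, `"raw"` or `"linear"`) and `factor` (the linear factor,
#'   `NA` otherwise).
#' @exportClass FeatureRegistry
setClass("FeatureRegistry", representation(specs = "data.frame"))

.kindOperandCount <- function(kind, n) {
  switch(kind,
    point_acceleration = n == 1L,
    border_proximity = n == 1L,
    pair_distance = n == 2L,
    pairpair_angle = n == 4L,  # two point pairs
    polygon_area = n >= 3L,
    FALSE
  )
}

setValidity("FeatureRegistry", function(object) {
  sp <- object@specs
  need <- c("name", "kind", "operands", "normalization", "factor")
  if (!all(need %in% names(sp)))
    return(sprintf("specs must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(sp$name))
    return("duplicate feature names in registry")
  kinds <- c("point_acceleration", "pair_distance", "pairpair_angle",
             "border_proximity", "polygon_area")
  if (!all(sp$kind %in% kinds))
    return("unknown feature kind in registry")
  for (i in seq_len(nrow(sp))) {
    n <- length(.splitOperands(sp$operands[i]))
    if (!.kindOperandCount(sp$kind[i], n))
      return(sprintf("feature '%s': operand count %d invalid for kind '%s'",
                     sp$name[i], n, sp$kind[i]))
  }
  TRUE
})

#' Per-frame feature matrix
#'
#' @slot recordingId character identifier.
#' @slot values numeric N x m matrix; column names follow the registry order.
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(recordingId = "character", values = "matrix"))

#' Temporally expanded feature matrix
#'
#' Rows concatenate the per-frame feature vectors over a symmetric window of
#' +/- `halfwidth` frames, offset-major (all m features at offset -h, then
#' -h+1, ...). Frames lacking a full window are dropped; `frameOffset` records
#' the number of leading frames removed so labels can be re-aligned.
#'
#' @slot recordingId character identifier.
#' @slot values numeric N' x (m * (2*halfwidth + 1)) matrix.
#' @slot m number of base features.
#' @slot halfwidth window half width h in frames.
#' @slot frameOffset 0-based index of the first retained original frame.
#' @exportClass TemporalFeatureMatrix
setClass("TemporalFeatureMatrix",
  representation(recordingId = "character", values = "matrix",
                 m = "integer", halfwidth = "integer",
                 frameOffset = "integer"))

setValidity("TemporalFeatureMatrix", function(object) {
  t <- 2L * object@halfwidth + 1L
  if (ncol(object@values) != object@m * t)
    return("column count must equal m * (2 * halfwidth + 1)")
  TRUE
})

## ---------------------------------------------------------------------------
## Labels and transitions
## ---------------------------------------------------------------------------

#' Per-frame behavioral cluster labels
#'
#' @slot recordingId character identifier.
#' @slot labels integer vector of cluster ids, one per frame.
#' @slot alphabet integer vector: the full fixed set of cluster ids for the
#'   analysis (size NC), so that clusters unobserved in this recording still
#'   yield zero rows/columns in its transition matrix.
#' @slot fps frames per second.
#' @slot frameOffset frames dropped at the start by temporal expansion.
#' @exportClass LabelSequence
setClass("LabelSequence",
  representation(recordingId = "character", labels = "integer",
                 alphabet = "integer", fps = "numeric",
                 frameOffset = "integer"),
  prototype(recordingId = "recording", fps = 25, frameOffset = 0L))

setValidity("LabelSequence", function(object) {
  if (length(object@labels) == 0L) return("label sequence must be non-empty")
  if (!all(object@labels %in% object@alphabet))
    return("labels outside the declared alphabet")
  if (anyDuplicated(object@alphabet)) return("alphabet has duplicate ids")
  TRUE
})

#' Cluster-to-cluster transition count matrix
#'
#' NC x NC nonnegative integer counts of transitions between behavioral
#' clusters, computed after run-length compression of the label sequence
#' (so the diagonal is structurally zero).
#'
#' @slot counts integer NC x NC matrix, dimnames = alphabet ids.
#' @slot recordingId character identifier.
#' @slot alphabet integer cluster-id set.
#' @exportClass TransitionMatrix
setClass("TransitionMatrix",
  representation(counts = "matrix", recordingId = "character",
                 alphabet = "integer"))

setValidity("TransitionMatrix", function(object) {
  nc <- length(object@alphabet)
  if (!all(dim(object@counts) == c(nc, nc)))
    return("counts must be NC x NC for the declared alphabet")
  if (any(object@counts < 0)) return("counts must be nonnegative")
  if (any(diag(object@counts) != 0))
    return("diagonal must be structurally zero")
  TRUE
})

#' Stabilized (control-referenced) transition matrix
#'
#' A recording's transition matrix minus the elementwise mean of the control
#' group's transition matrices, so that the mean over the control reference
#' set is exactly zero.
#'
#' @slot values numeric NC x NC matrix.
#' @slot recordingId character identifier.
#' @slot alphabet integer cluster-id set.
#' @slot controlReference character ids of the control recordings used.
#' @exportClass StabilizedTransitionMatrix
setClass("StabilizedTransitionMatrix",
  representation(values = "matrix", recordingId = "character",
                 alphabet = "integer", controlReference = "character"))

#' Two-group collection of transition matrices
#'
#' @slot control,test lists of [TransitionMatrix-class] objects.
#' @slot alphabet shared integer cluster-id set.
#' @exportClass GroupedTransitionSet
setClass("GroupedTransitionSet",
  representation(control = "list", test = "list", alphabet = "integer"))

setValidity("GroupedTransitionSet", function(object) {
  all_m <- c(object@control, object@test)
  if (length(all_m) == 0L) return("no matrices")
  ok <- vapply(all_m, function(m)
    is(m, "TransitionMatrix") && identical(m@alphabet, object@alphabet),
    logical(1))
  if (!all(ok)) return("all members must be TransitionMatrix on the shared alphabet")
  TRUE
})

## ---------------------------------------------------------------------------
## Clustering and classification models
## ---------------------------------------------------------------------------

#' Column-wise z-score standardizer
#'
#' Means and standard deviations fitted on the clustering subset and reused
#' verbatim for every later assignment or classifier application. Columns
#' with zero standard deviation are standardized to 0 (the sd is kept, and
#' flagged, rather than the column dropped).
#'
#' @slot means,sds numeric vectors of length mt.
#' @exportClass ColumnStandardizer
setClass("ColumnStandardizer",
  representation(means = "numeric", sds = "numeric"))

setValidity("ColumnStandardizer", function(object) {
  if (length(object@means) != length(object@sds))
    return("means and sds must have equal length")
  if (any(object@sds < 0)) return("sds must be nonnegative")
  TRUE
})

#' Fitted k-means cluster model
#'
#' @slot k number of clusters.
#' @slot centers k x mt matrix of centers in standardized space.
#' @slot seed integer seed used for the fit.
#' @slot inertia total within-cluster sum of squared distances.
#' @exportClass ClusterModel
setClass("ClusterModel",
  representation(k = "integer", centers = "matrix", seed = "integer",
                 inertia = "numeric"))

setValidity("ClusterModel", function(object) {
  if (object@k < 2L) return("k must be at least 2")
  if (nrow(object@centers) != object@k) return("centers must have k rows")
  if (any(!is.finite(object@centers))) return("centers must be finite")
  TRUE
})

#' Supervised cluster-imitation classifier
#'
#' A probabilistic multi-class model trained to imitate a reference
#' clustering so that new recordings receive consistent cluster labels.
#' Two backends are provided: `"mlp"`, a single-hidden-layer rectified-linear
#' network with dropout and a softmax output trained by RMSprop on the
#' categorical cross-entropy; and `"multinom"`, a lightweight multinomial
#' logistic regression.
#'
#' @slot backend `"mlp"` or `"multinom"`.
#' @slot inputWidth,outputWidth input feature width and number of clusters.
#' @slot model fitted parameters (backend-specific).
#' @slot trainingMeta list: epochs, batch size, hidden width, dropout rate,
#'   learning rate, seed, per-epoch training loss.
#' @exportClass ClusterClassifier
setClass("ClusterClassifier",
  representation(backend = "character", inputWidth = "integer",
                 outputWidth = "integer", model = "ANY",
                 trainingMeta = "list"))

#' Recording-level cross-validation report
#'
#' @slot perCluster data.frame: fold, cluster, precision, recall, f1, support.
#' @slot folds list of character vectors: validation recording ids per fold.
#' @exportClass CVReport
setClass("CVReport",
  representation(perCluster = "data.frame", folds = "list"))

## ---------------------------------------------------------------------------
## Statistics results
## ---------------------------------------------------------------------------

#' Behavioral flow analysis (BFA) permutation-test result
#'
#' @slot distance Manhattan distance between the two group-mean transition
#'   matrices.
#' @slot percentile permutation percentile on the 0-100 scale, computed with
#'   the (N+1) denominator and strict inequality, hence bounded above by
#'   100 * N / (N + 1).
#' @slot z standardized distance against the permutation null.
#' @slot p right-tailed parametric p-value from the standard-normal upper
#'   tail of z.
#' @slot null numeric vector of permuted distances.
#' @slot nPerm,seed permutation count and seed.
#' @exportClass BFAResult
setClass("BFAResult",
  representation(distance = "numeric", percentile = "numeric",
                 z = "numeric", p = "numeric", null = "numeric",
                 nPerm = "integer", seed = "integer"))

#' Per-animal behavioral flow likeness (BFL) scores
#'
#' For each sample, the Manhattan distances of its transition matrix to the
#' leave-one-out elementwise-median matrices of groups A and B, and the score
#' log(dA / dB). Scores are infinite when one distance is zero; such rows are
#' flagged.
#'
#' @slot table data.frame: sampleId, group, dA, dB, score, degenerate.
#' @exportClass BFLScores
setClass("BFLScores", representation(table = "data.frame"))

#' Power curve for a two-sample t-test
#'
#' @slot d Cohen's d effect size.
#' @slot alpha significance level.
#' @slot table data.frame: n (per group), power.
#' @exportClass PowerCurve
setClass("PowerCurve",
  representation(d = "numeric", alpha = "numeric", table = "data.frame"))

## ---------------------------------------------------------------------------
## Fingerprinting
## ---------------------------------------------------------------------------

#' 2D behavioral flow fingerprint (BFF) embedding
#'
#' @slot coords numeric n x 2 matrix, rownames = recording ids.
#' @slot seed integer seed.
#' @slot params list of embedding hyperparameters.
#' @exportClass EmbeddingResult
setClass("EmbeddingResult",
  representation(coords = "matrix", seed = "integer", params = "list"))

## ---------------------------------------------------------------------------
## Synthetic data
## ---------------------------------------------------------------------------

#' Markovian behavioral kernel
#'
#' Generative model of a label sequence: geometric dwell times per state
#' (memoryless run lengths with the stated mean) and an inter-state
#' transition probability matrix with zero diagonal and rows summing to 1.
#'
#' @slot transition numeric NC x NC inter-state transition probabilities.
#' @slot meanRun numeric vector: mean run length (frames) per state.
#' @exportClass BehaviorKernel
setClass("BehaviorKernel",
  representation(transition = "matrix", meanRun = "numeric"))

setValidity("BehaviorKernel", function(object) {
  tr <- object@transition
  if (nrow(tr) != ncol(tr)) return("transition matrix must be square")
  if (any(tr < 0 | tr > 1)) return("probabilities must lie in [0, 1]")
  if (any(abs(diag(tr)) > 0)) return("diagonal must be zero")
  if (any(abs(rowSums(tr) - 1) > 1e-12))
    return("rows must sum to 1 (within 1e-12)")
  if (length(object@meanRun) != nrow(tr)) return("meanRun length must be NC")
  if (any(object@meanRun < 1)) return("mean run lengths must be >= 1 frame")
  TRUE
})

#' Group-effect specification for synthetic experiments
#'
#' Multiplicative factors applied to selected ordered state-pair transition
#' probabilities of a kernel, with affected rows renormalized.
#'
#' @slot pairs integer k x 2 matrix of (from, to) state pairs.
#' @slot factors positive numeric multipliers, length k.
#' @exportClass GroupEffectSpec
setClass("GroupEffectSpec",
  representation(pairs = "matrix", factors = "numeric"))

setValidity("GroupEffectSpec", function(object) {
  if (ncol(object@pairs) != 2L) return("pairs must be a two-column matrix")
  if (nrow(object@pairs) != length(object@factors))
    return("one factor per pair required")
  if (any(object@factors <= 0)) return("factors must be positive")
  if (any(object@pairs[, 1] == object@pairs[, 2]))
    return("self-transitions cannot carry effects")
  TRUE
})

#' Synthetic two-group experiment with ground truth
#'
#' @slot labels list of [LabelSequence-class], one per recording.
#' @slot groups named character vector: recording id -> "control"/"treated".
#' @slot kernels list of per-animal [BehaviorKernel-class] ground truth.
#' @slot seed master seed.
#' @exportClass SyntheticExperiment
setClass("SyntheticExperiment",
  representation(labels = "list", groups = "character",
                 kernels = "list", seed = "integer"))
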