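.FEATURE_KINDS <- c("point_acceleration", "pair_distance", "pairpair_angle",
                    "border_proximity", "polygon_area")

## The 13 standard tracked body points.
.STANDARD_POINTS <- c("nose", "headcentre", "neck", "earr", "earl",
                      "bodycentre", "bcl", "bcr", "hipl", "hipr",
                      "tailbase", "tailcentre", "tailtip")

#' Construct a feature registry
#'
#' Builds a deterministic, canonically ordered [FeatureRegistry-class] from a
#' specification table. Normalization defaults follow the feature kind:
#' distances and areas are z-scored per recording, angles are left raw, and
#' border proximities and point accelerations are scaled linearly by 0.1 and
#' 4 respectively.
#'
#' @param specs data.frame with columns `name`, `kind`, `operands`
#'   (comma-separated body-point names); optional `normalization`, `factor`.
#' @param points character vector of tracked point names the registry may
#'   reference (default: the 13 standard points).
#' @return A [FeatureRegistry-class]. Entries are re-ordered canonically
#'   (by kind, then name) so shuffled inputs yield identical registries.
#' @export
featureRegistry <- function(specs, points = .STANDARD_POINTS) {
  specs <- as.data.frame(specs, stringsAsFactors = FALSE)
  if (is.null(specs$normalization)) {
    specs$normalization <- vapply(specs$kind, function(k) switch(k,
      pair_distance = "zscore", polygon_area = "zscore",
      pairpair_angle = "raw",
      border_proximity = "linear", point_acceleration = "linear"),
      character(1))
  }
  if (is.null(specs$factor)) specs$factor <- NA_real_
  lin <- specs$normalization == "linear" & is.na(specs$factor)
  specs$factor[lin] <- ifelse(specs$kind[lin] == "border_proximity", 0.1,
                              ifelse(specs$kind[lin] == "point_acceleration",
                                     4, NA_real_))
  ops <- unique(unlist(lapply(specs$operands, .splitOperands)))
  unknown <- setdiff(ops, points)
  if (length(unknown))
    stop("registry references untracked points: ",
         paste(unknown, collapse = ", "))
  if (anyDuplicated(specs$name))
    stop("duplicate feature names: ",
         paste(unique(specs$name[duplicated(specs$name)]), collapse = ", "))
  ord <- order(match(specs$kind, .FEATURE_KINDS), specs$name)
  specs <- specs[ord, , drop = FALSE]
  rownames(specs) <- NULL
  new("FeatureRegistry", specs = specs)
}

#' Number of features in a registry
#' @param registry a [FeatureRegistry-class].
#' @export
nFeatures <- function(registry) nrow(registry@specs)

#' The default 41-feature registry
#'
#' A fixed set of m = 41 per-frame features over the 13 standard body points,
#' covering the five feature kinds: 13 point accelerations, 12 pairwise
#' distances, 6 signed angles between point-pair vectors, 6 border
#' proximities and 4 polygon areas.
#'
#' @return A [FeatureRegistry-class] with `nFeatures() == 41`.
#' @export
defaultFeatureRegistry <- function() {
  pts <- .STANDARD_POINTS
  acc <- data.frame(name = paste0("acc_", pts), kind = "point_acceleration",
                    operands = pts)
  pairs <- list(
    c("nose", "neck"), c("nose", "tailbase"), c("neck", "bodycentre"),
    c("bodycentre", "tailbase"), c("earl", "earr"), c("hipl", "hipr"),
    c("bcl", "bcr"), c("nose", "bodycentre"), c("neck", "tailbase"),
    c("tailbase", "tailcentre"), c("tailcentre", "tailtip"),
    c("headcentre", "bodycentre"))
  dst <- data.frame(
    name = vapply(pairs, function(p) paste0("dist_", p[1], "_", p[2]),
                  character(1)),
    kind = "pair_distance",
    operands = vapply(pairs, paste, character(1), collapse = ","))
  angles <- list(
    c("nose", "neck", "neck", "bodycentre"),
    c("neck", "bodycentre", "bodycentre", "tailbase"),
    c("nose", "headcentre", "headcentre", "neck"),
    c("earl", "earr", "hipl", "hipr"),
    c("bodycentre", "tailbase", "tailbase", "tailcentre"),
    c("tailbase", "tailcentre", "tailcentre", "tailtip"))
  ang <- data.frame(
    name = paste0("angle_", vapply(angles, function(a)
      paste0(a[1], a[2], "_", a[3], a[4]), character(1))),
    kind = "pairpair_angle",
    operands = vapply(angles, paste, character(1), collapse = ","))
  bp <- c("nose", "headcentre", "bodycentre", "tailbase", "hipl", "hipr")
  bor <- data.frame(name = paste0("border_", bp), kind = "border_proximity",
                    operands = bp)
  polys <- list(
    body = c("neck", "bcr", "hipr", "tailbase", "hipl", "bcl"),
    head = c("nose", "earr", "neck", "earl"),
    hind = c("bcl", "bcr", "hipr", "hipl"),
    full = c("nose", "earr", "bcr", "hipr", "tailbase", "hipl", "bcl",
             "earl"))
  pol <- data.frame(
    name = paste0("area_", names(polys)), kind = "polygon_area",
    operands = vapply(polys, paste, character(1), collapse = ","))
  featureRegistry(rbind(acc, dst, ang, bor, pol))
}

#' Evaluate per-frame features
#'
#' Computes the registry's features for every frame of a preprocessed
#' recording. Pair distances are Euclidean (cm); angles are the signed angle
#' in radians, in (-pi, pi], between the two operand point-pair vectors;
#' border proximity is the distance (cm) to the nearest arena edge; polygon
#' areas are shoelace areas (cm^2); point accelerations come from the
#' recording's kinematics (cm/s^2).
#'
#' @param recording a preprocessed [TrackingRecording-class] (kinematics
#'   available).
#' @param registry a [FeatureRegistry-class] (default the 41-feature set).
#' @return A [FeatureMatrix-class] with one row per frame.
#' @export
extractFeatures <- function(recording, registry = defaultFeatureRegistry()) {
  if (nrow(recording@acceleration) == 0L)
    stop("recording lacks kinematics; run preprocessRecording() first")
  arena <- recording@arena
  ppc <- arena@pxPerCm
  n <- nFrames(recording)
  sp <- registry@specs
  out <- matrix(NA_real_, n, nrow(sp), dimnames = list(NULL, sp$name))
  X <- recording@x; Y <- recording@y
  for (i in seq_len(nrow(sp))) {
    ops <- .splitOperands(sp$operands[i])
    out[, i] <- switch(sp$kind[i],
      point_acceleration = recording@acceleration[, ops],
      pair_distance = sqrt((X[, ops[1]] - X[, ops[2]])^2 +
                           (Y[, ops[1]] - Y[, ops[2]])^2) / ppc,
      pairpair_angle = {
        v1x <- X[, ops[2]] - X[, ops[1]]; v1y <- Y[, ops[2]] - Y[, ops[1]]
        v2x <- X[, ops[4]] - X[, ops[3]]; v2y <- Y[, ops[4]] - Y[, ops[3]]
        atan2(v1x * v2y - v1y * v2x, v1x * v2x + v1y * v2y)
      },
      border_proximity = .distToPolygonBorder(
        arena@corners, cbind(X[, ops], Y[, ops])) / ppc,
      polygon_area = {
        k <- length(ops)
        nxt <- c(ops[-1], ops[1])
        a <- 0
        for (e in seq_len(k))
          a <- a + X[, ops[e]] * Y[, nxt[e]] - X[, nxt[e]] * Y[, ops[e]]
        abs(a) / 2 / ppc^2
      })
  }
  new("FeatureMatrix", recordingId = recording@recordingId, values = out)
}

#' Normalize a feature matrix per recording
#'
#' Applies each feature's normalization rule within the recording: z-score
#' for distance and area features, raw for angles, and the fixed linear
#' factors for border proximity (0.1) and acceleration (4). A zero-variance
#' z-score column is set to 0 with a warning rather than dividing by zero.
#'
#' @param fm a [FeatureMatrix-class].
#' @param registry the [FeatureRegistry-class] that produced it.
#' @return The normalized [FeatureMatrix-class].
#' @export
normalizeFeatures <- function(fm, registry) {
  sp <- registry@specs
  stopifnot(identical(colnames(fm@values), sp$name))
  v <- fm@values
  for (i in seq_len(nrow(sp))) {
    v[, i] <- switch(sp$normalization[i],
      raw = v[, i],
      linear = v[, i] * sp$factor[i],
      zscore = {
        s <- stats::sd(v[, i])
        if (!is.finite(s) || s == 0) {
          warning("zero-variance column '", sp$name[i],
                  "' standardized to 0")
          rep(0, nrow(v))
        } else (v[, i] - mean(v[, i])) / s
      })
  }
  new("FeatureMatrix", recordingId = fm@recordingId, values = v)
}

#' Temporal expansion of a feature matrix
#'
#' Expands each frame's m-vector over a symmetric window of +/- `halfwidth`
#' frames (t = 2*halfwidth + 1 frames in total), concatenating offset-major:
#' all m features at offset -h, then -h+1, and so on. Frames lacking a full
#' window are dropped and the resulting frame offset recorded. With the
#' default m = 41 and halfwidth 15 the expanded width is 41 * 31 = 1,271.
#'
#' @param fm a (normalized) [FeatureMatrix-class].
#' @param halfwidth window half width h in frames (default 15).
#' @return A [TemporalFeatureMatrix-class] with N - 2h rows.
#' @export
temporalExpand <- function(fm, halfwidth = 15) {
  h <- as.integer(halfwidth)
  v <- fm@values
  n <- nrow(v); m <- ncol(v)
  if (n <= 2L * h)
    stop("recording too short for temporal expansion: ", n,
         " frames <= 2 * ", h)
  np <- n - 2L * h
  offs <- seq.int(-h, h)
  out <- matrix(NA_real_, np, m * length(offs))
  cn <- character(m * length(offs))
  for (j in seq_along(offs)) {
    idx <- seq.int(1L + h + offs[j], length.out = np)
    cols <- seq.int((j - 1L) * m + 1L, length.out = m)
    out[, cols] <- v[idx, , drop = FALSE]
    cn[cols] <- paste0(colnames(v), "@", offs[j])
  }
  colnames(out) <- cn
  new("TemporalFeatureMatrix", recordingId = fm@recordingId, values = out,
      m = m, halfwidth = h, frameOffset = h)
}
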