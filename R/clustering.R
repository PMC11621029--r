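#' Assemble a multi-experiment clustering subset
#'
#' Reproducibly samples `nPerExperiment` recordings from each experiment and
#' stacks their temporally expanded feature rows into one large matrix for
#' k-means clustering.
#'
#' @param experiments named list: experiment -> list of
#'   [TemporalFeatureMatrix-class] objects (names = recording ids).
#' @param nPerExperiment recordings sampled per experiment (default 20).
#' @param seed integer seed for the sampling.
#' @return A list with `X` (stacked matrix), `recordingIds`, `rowRecording`
#'   (recording id per row), `provenance` (experiment -> sampled ids) and
#'   `seed`.
#' @export
assembleClusteringSubset <- function(experiments, nPerExperiment = 20,
                                     seed = 1L) {
  stopifnot(length(experiments) > 0L)
  rng <- .seededRNG(seed)
  picked <- list()
  for (ex in names(experiments)) {
    recs <- experiments[[ex]]
    if (length(recs) < nPerExperiment)
      stop("experiment '", ex, "' has only ", length(recs),
           " recordings; need ", nPerExperiment)
    ids <- names(recs)
    if (is.null(ids)) ids <- as.character(seq_along(recs))
    picked[[ex]] <- sort(rng$sample(ids, nPerExperiment))
  }
  blocks <- list(); rowRec <- character(0)
  for (ex in names(experiments)) {
    recs <- experiments[[ex]]
    ids <- names(recs)
    if (is.null(ids)) ids <- as.character(seq_along(recs))
    for (id in picked[[ex]]) {
      tfm <- recs[[match(id, ids)]]
      blocks[[length(blocks) + 1L]] <- tfm@values
      rowRec <- c(rowRec, rep(id, nrow(tfm@values)))
    }
  }
  list(X = do.call(rbind, blocks),
       recordingIds = unlist(picked, use.names = FALSE),
       rowRecording = rowRec,
       provenance = picked,
       seed = as.integer(seed))
}

#' Fit a column standardizer
#' @param X numeric matrix.
#' @return A [ColumnStandardizer-class] with per-column means and sds.
#' @export
fitStandardizer <- function(X) {
  new("ColumnStandardizer",
      means = colMeans(X),
      sds = apply(X, 2, stats::sd))
}

#' Apply a column standardizer
#'
#' Zero-sd columns map to 0 rather than NaN, preserving the column count.
#'
#' @param standardizer a [ColumnStandardizer-class].
#' @param X numeric matrix with matching column count.
#' @return The standardized matrix.
#' @export
applyStandardizer <- function(standardizer, X) {
  if (ncol(X) != length(standardizer@means))
    stop("column count mismatch: ", ncol(X), " vs ",
         length(standardizer@means))
  sds <- standardizer@sds
  sds[sds == 0] <- Inf  # zero-variance columns standardize to 0
  sweep(sweep(X, 2, standardizer@means, "-"), 2, sds, "/")
}

## k-means++ style seeded center spreading.
.kmeansPlusPlusInit <- function(X, k, rng) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  idx <- rng$sampleInt(n, 1L)
  centers[1L, ] <- X[idx, ]
  d2 <- rowSums(sweep(X, 2, centers[1L, ], "-")^2)
  for (j in seq_len(k - 1L) + 1L) {
    prob <- d2 / sum(d2)
    if (!all(is.finite(prob)) || sum(d2) == 0)
      idx <- rng$sampleInt(n, 1L)
    else idx <- rng$sampleIntProb(n, prob)
    centers[j, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ], "-")^2))
  }
  centers
}

#' k-means clustering of a standardized subset
#'
#' Z-scores the subset matrix across columns, then fits k-means with seeded
#' k-means++-style center spreading and a fixed number of restarts (best
#' inertia kept). The standardizer is returned with the model and must be
#' reused verbatim for all later assignment and classification.
#'
#' @param subset output of [assembleClusteringSubset()], or a plain matrix.
#' @param k number of clusters (>= 2; default 25).
#' @param seed integer seed.
#' @param restarts independent seeded initializations (default 3).
#' @param iterMax Lloyd iterations per restart (default 50).
#' @return list(model = [ClusterModel-class],
#'   standardizer = [ColumnStandardizer-class],
#'   assignments = integer row labels).
#' @export
fitKmeans <- function(subset, k = 25, seed = 1L, restarts = 3,
                      iterMax = 50) {
  X <- if (is.list(subset)) subset$X else subset
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (nrow(X) < k) stop("fewer rows than clusters")
  standardizer <- fitStandardizer(X)
  Z <- applyStandardizer(standardizer, X)
  if (nrow(unique(Z)) < k)
    stop("fewer distinct rows than clusters (k = ", k, ")")
  rng <- .seededRNG(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- .kmeansPlusPlusInit(Z, k, rng)
    fit <- suppressWarnings(stats::kmeans(Z, centers = init,
                                          iter.max = iterMax,
                                          algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  model <- new("ClusterModel", k = k, centers = unname(best$centers),
               seed = as.integer(seed), inertia = best$tot.withinss)
  list(model = model, standardizer = standardizer,
       assignments = as.integer(best$cluster))
}

#' Assign cluster labels to new feature rows
#'
#' Rows are standardized with the persisted standardizer of the fit, then
#' labeled by the nearest model center (Euclidean distance, ties broken by
#' the lowest cluster id).
#'
#' @param model a [ClusterModel-class].
#' @param standardizer the [ColumnStandardizer-class] persisted with it.
#' @param X a [TemporalFeatureMatrix-class] or plain matrix.
#' @param fps frames per second for the resulting label sequence.
#' @return A [LabelSequence-class] over the alphabet 1..k.
#' @export
assignClusters <- function(model, standardizer, X, fps = 25) {
  tfm <- NULL
  if (is(X, "TemporalFeatureMatrix")) { tfm <- X; X <- tfm@values }
  if (ncol(X) != ncol(model@centers))
    stop("feature width ", ncol(X), " does not match model width ",
         ncol(model@centers))
  Z <- applyStandardizer(standardizer, X)
  labels <- .nearestCenter(Z, model@centers)
  new("LabelSequence",
      recordingId = if (is.null(tfm)) "rows" else tfm@recordingId,
      labels = labels, alphabet = seq_len(model@k), fps = fps,
      frameOffset = if (is.null(tfm)) 0L else tfm@frameOffset)
}

## argmin over centers; ties -> lowest id. ||z - c||^2 = ||z||^2 - 2 z.c + ||c||^2
.nearestCenter <- function(Z, centers) {
  cross <- Z %*% t(centers)
  cn <- rowSums(centers^2)
  d2 <- sweep(-2 * cross, 2, cn, "+")  # row-constant ||z||^2 omitted
  as.integer(max.col(-d2, ties.method = "first"))
}

#' Choose the cluster count from a high-k fit
#'
#' Sorts per-cluster frame proportions from high to low and returns the
#' smallest number of clusters whose cumulative proportion reaches the
#' coverage target (default 95% of frames).
#'
#' @param proportions per-cluster frame fractions (must sum to 1 within
#'   1e-6), typically from a k = 100 fit.
#' @param coverage target cumulative fraction (default 0.95).
#' @return Integer cluster count.
#' @export
selectClusterCount <- function(proportions, coverage = 0.95) {
  if (abs(sum(proportions) - 1) > 1e-6)
    stop("proportions must sum to 1 (got ", format(sum(proportions)), ")")
  cum <- cumsum(sort(proportions, decreasing = TRUE))
  as.integer(which(cum >= coverage - 1e-12)[1])
}
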