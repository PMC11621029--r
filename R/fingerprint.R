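#' Behavioral flow fingerprinting: 2D embedding of transition matrices
#'
#' Projects per-recording (stabilized) transition matrices into two
#' dimensions for visual comparison of individual animals. Each matrix is
#' flattened row-major into an NC^2-vector; pairwise Manhattan distances
#' are then embedded by Kruskal non-metric multidimensional scaling, a
#' nonlinear projection that preserves the rank order of neighborhood
#' distances, initialized from the (deterministic) classical MDS solution.
#' The result is a pure function of the inputs, the seed and the
#' hyperparameters.
#'
#' When comparing recordings across experiments, stabilize each recording
#' against its own experiment's internal control group first (see
#' [stabilize()]).
#'
#' @param matrices list (>= 4) of [StabilizedTransitionMatrix-class] or
#'   [TransitionMatrix-class] objects on one alphabet.
#' @param seed integer seed (used only to break exact-tie degeneracies;
#'   default 42).
#' @param maxit maximum stress-minimization iterations (default 50).
#' @return An [EmbeddingResult-class] with one coordinate pair per matrix.
#' @export
bffEmbed <- function(matrices, seed = 42L, maxit = 50) {
  n <- length(matrices)
  if (n < 4L)
    stop("need at least 4 matrices to embed; got ", n,
         " (add recordings or skip the embedding)")
  alpha <- if (is(matrices[[1]], "TransitionMatrix"))
    matrices[[1]]@alphabet else matrices[[1]]@alphabet
  X <- t(vapply(matrices, function(m) {
    v <- if (is(m, "TransitionMatrix")) m@counts else m@values
    as.numeric(t(v))
  }, numeric(length(alpha)^2)))
  ids <- vapply(matrices, function(m) m@recordingId, character(1))
  D <- stats::dist(X, method = "manhattan")
  coords <- if (max(D) < 1e-12) {
    matrix(0, n, 2)  # all inputs identical: degenerate but finite
  } else {
    eps <- min(D[D > 0]) * 1e-6
    D[D < eps] <- eps
    init <- stats::cmdscale(D, k = 2)
    if (ncol(init) < 2 || any(!is.finite(init)) ||
        any(apply(init, 2, stats::sd) == 0)) {
      jit <- .withSeed(seed, matrix(stats::rnorm(n * 2, sd = eps), n))
      if (ncol(init) < 2)
        init <- cbind(init, matrix(0, n, 2 - ncol(init)))
      init <- init + jit
    }
    fit <- MASS::isoMDS(D, y = init, k = 2, maxit = maxit, trace = FALSE)
    fit$points
  }
  rownames(coords) <- ids
  colnames(coords) <- c("dim1", "dim2")
  new("EmbeddingResult", coords = coords, seed = as.integer(seed),
      params = list(method = "nonmetric-mds", distance = "manhattan",
                    maxit = maxit))
}

#' Group summary of an embedding
#'
#' Per-group mean coordinates with standard errors of the mean (sd /
#' sqrt(n)) on both axes, computed only from that group's members.
#' Singleton groups get `NA` standard errors.
#'
#' @param embedding an [EmbeddingResult-class].
#' @param assignment group labels, one per embedded recording.
#' @return data.frame: group, n, mean1, mean2, sem1, sem2.
#' @export
groupSummary <- function(embedding, assignment) {
  co <- embedding@coords
  stopifnot(length(assignment) == nrow(co))
  out <- lapply(sort(unique(assignment)), function(g) {
    sel <- assignment == g
    m <- co[sel, , drop = FALSE]
    n <- nrow(m)
    data.frame(group = g, n = n,
               mean1 = mean(m[, 1]), mean2 = mean(m[, 2]),
               sem1 = if (n > 1) stats::sd(m[, 1]) / sqrt(n) else NA_real_,
               sem2 = if (n > 1) stats::sd(m[, 2]) / sqrt(n) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
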