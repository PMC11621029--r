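#' Construct a two-group transition set
#'
#' @param control,test lists of [TransitionMatrix-class] objects sharing one
#'   alphabet.
#' @return A [GroupedTransitionSet-class].
#' @export
groupedTransitionSet <- function(control, test) {
  stopifnot(length(control) > 0L, length(test) > 0L)
  alpha <- control[[1]]@alphabet
  new("GroupedTransitionSet", control = control, test = test,
      alphabet = alpha)
}

## Flatten a grouped set into an n x NC^2 matrix (row-major cells) plus a
## group indicator (TRUE = test).
.flattenSet <- function(groups) {
  allm <- c(groups@control, groups@test)
  X <- t(vapply(allm, function(m) as.numeric(t(m@counts)),
                numeric(length(groups@alphabet)^2)))
  list(X = X,
       isTest = c(rep(FALSE, length(groups@control)),
                  rep(TRUE, length(groups@test))),
       ids = vapply(allm, function(m) m@recordingId, character(1)))
}

.manhattan <- function(X, isTest) {
  sum(abs(colMeans(X[!isTest, , drop = FALSE]) -
          colMeans(X[isTest, , drop = FALSE])))
}

#' Manhattan distance between group-mean transition matrices
#'
#' Sum over all matrix cells of the absolute difference between the
#' elementwise means of the control and test groups' transition matrices.
#' Symmetric in its group arguments and zero iff the group means are equal.
#'
#' @param groups a [GroupedTransitionSet-class].
#' @return The distance (a nonnegative number).
#' @export
manhattanGroupDistance <- function(groups) {
  fl <- .flattenSet(groups)
  .manhattan(fl$X, fl$isTest)
}

#' Right-tailed p-value from a standardized distance
#'
#' Converts a z score into the right-tailed parametric p-value
#' (1 - erf(z / sqrt(2))) / 2, i.e. the standard-normal upper-tail
#' probability. Evaluated through the complementary (upper-tail) normal
#' distribution function, which keeps relative precision for large z where
#' the erf difference would underflow.
#'
#' @param z standardized distance (finite; vectorized).
#' @return p in (0, 1].
#' @export
erfPvalue <- function(z) {
  stopifnot(all(is.finite(z)))
  stats::pnorm(z, lower.tail = FALSE)
}

#' Behavioral flow analysis: permutation test on group transition matrices
#'
#' Computes the Manhattan distance between the two group-mean transition
#' matrices, then builds a permutation null by shuffling the group
#' assignment vector `nPerm` times (group sizes preserved) and recomputing
#' the distance. Reports the nonparametric percentile (strict inequality,
#' denominator nPerm + 1, on the 0-100 scale), the standardized distance z
#' against the null mean and standard deviation, and the right-tailed
#' parametric p-value from [erfPvalue()].
#'
#' @param groups a [GroupedTransitionSet-class] with at least 4 recordings
#'   in total.
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed for the shuffles.
#' @return A [BFAResult-class].
#' @export
bfaPermutation <- function(groups, nPerm = 1000, seed = 1L) {
  fl <- .flattenSet(groups)
  n <- nrow(fl$X)
  if (n < 4L) stop("need at least 4 recordings in total")
  dist <- .manhattan(fl$X, fl$isTest)
  nTest <- sum(fl$isTest)
  null <- .withSeed(seed, vapply(seq_len(nPerm), function(b) {
    idx <- sample.int(n, nTest)
    isTestPerm <- logical(n); isTestPerm[idx] <- TRUE
    .manhattan(fl$X, isTestPerm)
  }, numeric(1)))
  s <- stats::sd(null)
  if (s == 0) stop("degenerate permutation null (zero variance)")
  z <- (dist - mean(null)) / s
  new("BFAResult", distance = dist,
      percentile = 100 * sum(null < dist) / (nPerm + 1),
      z = z, p = erfPvalue(z), null = null,
      nPerm = as.integer(nPerm), seed = as.integer(seed))
}

## Two-sample t-test over many units at once; skips units with zero
## variance in both groups. xC, xT: recordings x units matrices.
.unitTTests <- function(xC, xT, unitNames, varEqual = FALSE) {
  keep <- logical(ncol(xC))
  stat <- p <- mC <- mT <- rep(NA_real_, ncol(xC))
  skipped <- character(0)
  for (j in seq_len(ncol(xC))) {
    a <- xC[, j]; b <- xT[, j]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      skipped <- c(skipped, unitNames[j])
      next
    }
    tt <- stats::t.test(a, b, var.equal = varEqual)
    keep[j] <- TRUE
    stat[j] <- unname(tt$statistic)
    p[j] <- tt$p.value
    mC[j] <- mean(a); mT[j] <- mean(b)
  }
  if (length(skipped))
    message("skipped ", length(skipped),
            " zero-variance unit(s): ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "")
  out <- data.frame(unit = unitNames[keep], t = stat[keep], p = p[keep],
                    pAdjusted = stats::p.adjust(p[keep], method = "BY"),
                    meanControl = mC[keep], meanTest = mT[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-unit t-tests with Benjamini-Yekutieli correction
#'
#' Two-tailed two-sample t-tests on each unit, corrected for multiple
#' testing with the Benjamini-Yekutieli procedure over the tested family.
#' For `units = "transitions"` the input is a [GroupedTransitionSet-class]
#' and the family consists of the observed transitions: off-diagonal cells
#' with a nonzero total count over all recordings. For cluster-level
#' metrics (occurrences, time spent), pass two recordings-by-clusters
#' matrices instead.
#'
#' @param x a [GroupedTransitionSet-class], or the control group's
#'   recordings-by-units numeric matrix.
#' @param y the test group's matrix when `x` is a matrix; ignored otherwise.
#' @param varEqual use the pooled-variance Student test instead of Welch
#'   (default FALSE).
#' @return data.frame: unit, t, p, pAdjusted, meanControl, meanTest.
#' @export
perUnitTests <- function(x, y = NULL, varEqual = FALSE) {
  if (is(x, "GroupedTransitionSet")) {
    fl <- .flattenSet(x)
    nc <- length(x@alphabet)
    cellNames <- as.vector(t(outer(x@alphabet, x@alphabet,
                                   function(a, b) paste0(a, "->", b))))
    offDiag <- as.vector(t(outer(seq_len(nc), seq_len(nc), `!=`)))
    observed <- colSums(fl$X) > 0
    fam <- which(offDiag & observed)
    .unitTTests(fl$X[!fl$isTest, fam, drop = FALSE],
                fl$X[fl$isTest, fam, drop = FALSE],
                cellNames[fam], varEqual)
  } else {
    stopifnot(is.matrix(x), is.matrix(y), ncol(x) == ncol(y))
    nm <- colnames(x)
    if (is.null(nm)) nm <- as.character(seq_len(ncol(x)))
    .unitTTests(x, y, nm, varEqual)
  }
}

#' Behavioral flow likeness (BFL) scores
#'
#' For each sample, the elementwise median transition matrices of the two
#' groups are computed over all OTHER samples (the sample is excluded from
#' its own group), the Manhattan distances dA and dB of the sample's matrix
#' to the two medians are taken, and the score is log(dA / dB) (natural
#' log). Scores are invariant to a global positive rescaling of all
#' matrices. A zero distance yields an infinite score, flagged in the
#' `degenerate` column.
#'
#' @param groups a [GroupedTransitionSet-class]; group A is the control
#'   list, group B the test list. Each group needs at least 2 members so
#'   leave-one-out medians exist.
#' @return A [BFLScores-class].
#' @export
bflScores <- function(groups) {
  if (length(groups@control) < 2L || length(groups@test) < 2L)
    stop("each group needs at least 2 samples for leave-one-out medians")
  fl <- .flattenSet(groups)
  X <- fl$X
  n <- nrow(X)
  dA <- dB <- numeric(n)
  for (i in seq_len(n)) {
    inA <- !fl$isTest; inA[i] <- FALSE
    inB <- fl$isTest; inB[i] <- FALSE
    mA <- apply(X[inA, , drop = FALSE], 2, stats::median)
    mB <- apply(X[inB, , drop = FALSE], 2, stats::median)
    dA[i] <- sum(abs(X[i, ] - mA))
    dB[i] <- sum(abs(X[i, ] - mB))
  }
  score <- log(dA / dB)
  new("BFLScores", table = data.frame(
    sampleId = fl$ids,
    group = ifelse(fl$isTest, "B", "A"),
    dA = dA, dB = dB, score = score,
    degenerate = !is.finite(score),
    stringsAsFactors = FALSE))
}

#' Cohen's d from BFL scores
#'
#' Absolute standardized mean difference of the scores between the two
#' groups, with classic (n-1)-weighted pooled standard deviation. Infinite
#' scores are excluded with a message.
#'
#' @param scores a [BFLScores-class], or a numeric vector when `assignment`
#'   is given.
#' @param assignment two-level group labels aligned with a numeric
#'   `scores` vector.
#' @return Absolute Cohen's d.
#' @export
cohensDFromBfl <- function(scores, assignment = NULL) {
  if (is(scores, "BFLScores")) {
    v <- scores@table$score
    g <- scores@table$group
  } else {
    v <- scores; g <- assignment
  }
  fin <- is.finite(v)
  if (any(!fin))
    message("excluded ", sum(!fin), " infinite score(s)")
  v <- v[fin]; g <- g[fin]
  lev <- unique(g)
  stopifnot(length(lev) == 2L)
  a <- v[g == lev[1]]; b <- v[g == lev[2]]
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  sp <- sqrt(((length(a) - 1) * stats::var(a) +
              (length(b) - 1) * stats::var(b)) /
             (length(a) + length(b) - 2))
  abs(mean(a) - mean(b)) / sp
}

#' Power curve for a two-sample t-test at a given effect size
#'
#' Exact two-sided two-sample t-test power from the noncentral t
#' distribution, evaluated per group size over a grid of n.
#'
#' @param d Cohen's d (finite).
#' @param alpha significance level (default 0.05).
#' @param nGrid per-group sample sizes (default 3:7, 12, 20, 30, 50, 60).
#' @return A [PowerCurve-class]; its `table` has columns `n`, `power`.
#'   At d = 0 the power equals alpha at every n.
#' @export
powerCurve <- function(d, alpha = 0.05,
                       nGrid = c(3:7, 12, 20, 30, 50, 60)) {
  stopifnot(is.finite(d), all(nGrid >= 2))
  ## at zero effect the two-sided power is alpha identically
  pw <- if (d == 0) rep(alpha, length(nGrid)) else
    vapply(nGrid, function(n)
      stats::power.t.test(n = n, delta = abs(d), sd = 1, sig.level = alpha,
                          type = "two.sample", alternative = "two.sided",
                          strict = TRUE)$power, numeric(1))
  new("PowerCurve", d = d, alpha = alpha,
      table = data.frame(n = nGrid, power = pw))
}

#' Stratify treated animals into responders and nonresponders
#'
#' A treated animal is a nonresponder iff its BFL score lies within the
#' closed full range of the control group's BFL scores; otherwise it is a
#' responder. Boundary values count as nonresponders.
#'
#' @param treatedScores numeric BFL scores of treated animals (finite).
#' @param controlScores numeric BFL scores of control animals (finite,
#'   nonempty).
#' @return Character vector `"responder"`/`"nonresponder"` along
#'   `treatedScores`.
#' @export
stratifyResponders <- function(treatedScores, controlScores) {
  if (length(controlScores) == 0L) stop("control score set is empty")
  stopifnot(all(is.finite(treatedScores)), all(is.finite(controlScores)))
  lo <- min(controlScores); hi <- max(controlScores)
  ifelse(treatedScores >= lo & treatedScores <= hi,
         "nonresponder", "responder")
}

#' In silico sensitivity assay
#'
#' Stepwise reduces the group sizes: for each size, repeatedly subsamples
#' both groups to that (equal) size, runs the BFA permutation test on the
#' subsample, and summarizes -log10 of the resulting p-values by their mean
#' and standard deviation.
#'
#' @param groups a [GroupedTransitionSet-class].
#' @param sizes group sizes to test (default 25, 20, 15, 10, 5); sizes
#'   exceeding a group are skipped with a warning.
#' @param reps subsamples per size (default 50).
#' @param nPerm permutations per BFA run (default 1000).
#' @param seed integer master seed.
#' @return data.frame: size, meanNegLog10P, sdNegLog10P, reps.
#' @export
sensitivityAssay <- function(groups, sizes = c(25, 20, 15, 10, 5),
                             reps = 50, nPerm = 1000, seed = 1L) {
  nC <- length(groups@control); nT <- length(groups@test)
  rng <- .seededRNG(seed)
  rows <- list()
  for (s in sizes) {
    if (s > nC || s > nT) {
      warning("size ", s, " exceeds a group (", nC, ", ", nT, "); skipped")
      next
    }
    nl <- vapply(seq_len(reps), function(r) {
      idxC <- sort(rng$sampleInt(nC, s))
      idxT <- sort(rng$sampleInt(nT, s))
      sub <- groupedTransitionSet(groups@control[idxC], groups@test[idxT])
      ## derive the permutation seed from the subset itself, so identical
      ## subsamples (e.g. size = full group) give identical results
      bfaSeed <- (as.integer(seed) +
                  sum(sort(idxC) * 31L) + sum(sort(idxT) * 131L)) %%
        .Machine$integer.max
      res <- bfaPermutation(sub, nPerm = nPerm, seed = bfaSeed)
      -log10(res@p)
    }, numeric(1))
    rows[[length(rows) + 1L]] <-
      data.frame(size = s, meanNegLog10P = mean(nl),
                 sdNegLog10P = stats::sd(nl), reps = reps)
  }
  do.call(rbind, rows)
}

#' Log-linear dose-response model for a transition count
#'
#' Fits ordinary least squares to the natural logs of dose and transition
#' occurrence. Zero doses or counts are excluded before the log transform
#' (with a message).
#'
#' @param doses positive numeric doses, one per recording.
#' @param counts transition occurrence counts aligned with `doses`.
#' @return list: slope, intercept, r.squared, f, df1, df2, p, n.
#' @export
logLinearDoseModel <- function(doses, counts) {
  stopifnot(length(doses) == length(counts))
  use <- doses > 0 & counts > 0
  if (any(!use))
    message("excluded ", sum(!use), " recording(s) with zero dose or count")
  if (sum(use) < 3L)
    stop("need at least 3 recordings with positive dose and count")
  fit <- stats::lm(log(counts[use]) ~ log(doses[use]))
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r.squared = sm$r.squared,
       f = unname(fstat[1]), df1 = unname(fstat[2]),
       df2 = unname(fstat[3]),
       p = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                            lower.tail = FALSE)),
       n = sum(use))
}

#' Dose-response models across all observed transitions
#'
#' Applies [logLinearDoseModel()] to each observed (nonzero-total)
#' off-diagonal transition of a set of recordings and adjusts the p-values
#' with Benjamini-Yekutieli across the fitted family.
#'
#' @param doses positive numeric doses, one per transition matrix.
#' @param matrices list of [TransitionMatrix-class] aligned with `doses`.
#' @return data.frame: transition, slope, r.squared, f, df2, p, pAdjusted,
#'   n (rows only for transitions with >= 3 usable recordings).
#' @export
doseModelTable <- function(doses, matrices) {
  stopifnot(length(doses) == length(matrices))
  alpha <- matrices[[1]]@alphabet
  X <- t(vapply(matrices, function(m) as.numeric(t(m@counts)),
                numeric(length(alpha)^2)))
  cellNames <- as.vector(t(outer(alpha, alpha,
                                 function(a, b) paste0(a, "->", b))))
  offDiag <- as.vector(t(outer(seq_along(alpha), seq_along(alpha), `!=`)))
  fam <- which(offDiag & colSums(X) > 0)
  rows <- list()
  for (j in fam) {
    fit <- tryCatch(suppressMessages(logLinearDoseModel(doses, X[, j])),
                    error = function(e) NULL)
    if (is.null(fit)) next
    rows[[length(rows) + 1L]] <- data.frame(
      transition = cellNames[j], slope = fit$slope,
      r.squared = fit$r.squared, f = fit$f, df2 = fit$df2, p = fit$p,
      n = fit$n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$pAdjusted <- stats::p.adjust(out$p, method = "BY")
  out
}
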