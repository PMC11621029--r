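## Synthetic data with the statistical structure the pipeline assumes:
## Markovian behavioral states with geometric dwell times, per-animal
## kernel variability, group effects on selected transitions, and coarse
## 13-point pose kinematics.

#' Construct a behavioral kernel
#'
#' @param transition NC x NC inter-state transition probabilities (zero
#'   diagonal, rows summing to 1).
#' @param meanRun mean dwell (run length, frames) per state; scalar values
#'   are recycled. Default 20 frames, long enough that +/-5-frame modal
#'   smoothing rarely destroys a true run.
#' @return A [BehaviorKernel-class].
#' @export
behaviorKernel <- function(transition, meanRun = 20) {
  transition <- as.matrix(transition)
  if (length(meanRun) == 1L) meanRun <- rep(meanRun, nrow(transition))
  new("BehaviorKernel", transition = transition, meanRun = meanRun)
}

#' Uniform behavioral kernel
#'
#' All inter-state transitions equally likely.
#'
#' @param nStates number of states.
#' @param meanRun mean run length in frames (default 20).
#' @return A [BehaviorKernel-class].
#' @export
uniformKernel <- function(nStates, meanRun = 20) {
  tr <- matrix(1 / (nStates - 1), nStates, nStates)
  diag(tr) <- 0
  behaviorKernel(tr, meanRun)
}

#' Apply a group effect to a kernel
#'
#' Multiplies the selected ordered state-pair transition probabilities by
#' their factors and renormalizes the affected rows.
#'
#' @param kernel a [BehaviorKernel-class].
#' @param effect a [GroupEffectSpec-class], or NULL for no effect.
#' @return The modified [BehaviorKernel-class].
#' @export
applyGroupEffect <- function(kernel, effect) {
  if (is.null(effect)) return(kernel)
  tr <- kernel@transition
  for (i in seq_len(nrow(effect@pairs))) {
    tr[effect@pairs[i, 1], effect@pairs[i, 2]] <-
      tr[effect@pairs[i, 1], effect@pairs[i, 2]] * effect@factors[i]
  }
  rows <- unique(effect@pairs[, 1])
  tr[rows, ] <- tr[rows, , drop = FALSE] / rowSums(tr[rows, , drop = FALSE])
  behaviorKernel(tr, kernel@meanRun)
}

#' Group effect specification
#'
#' @param pairs integer k x 2 matrix (or vector of length 2) of (from, to)
#'   state pairs.
#' @param factors positive multiplicative factors, length k.
#' @return A [GroupEffectSpec-class].
#' @export
groupEffect <- function(pairs, factors) {
  if (is.null(dim(pairs))) pairs <- matrix(pairs, ncol = 2, byrow = TRUE)
  new("GroupEffectSpec", pairs = pairs, factors = factors)
}

## Dirichlet perturbation of each kernel row; concentration -> Inf leaves
## the kernel unchanged.
.jitterKernel <- function(kernel, concentration, rng) {
  if (!is.finite(concentration)) return(kernel)
  if (concentration <= 0) stop("jitter concentration must be positive")
  tr <- kernel@transition
  nc <- nrow(tr)
  for (i in seq_len(nc)) {
    idx <- which(tr[i, ] > 0)
    g <- rng$rgamma(length(idx), shape = concentration * tr[i, idx])
    if (sum(g) == 0) g <- tr[i, idx]  # extreme underflow guard
    tr[i, idx] <- g / sum(g)
  }
  behaviorKernel(tr, kernel@meanRun)
}

#' Simulate a behavioral label sequence
#'
#' Markov state sequence with geometric dwell times: each visit to a state
#' lasts a geometric number of frames with the kernel's mean run length,
#' then jumps according to the inter-state transition probabilities.
#'
#' @param kernel a [BehaviorKernel-class].
#' @param nFrames frames to generate (default 15000, a typical recording).
#' @param seed integer seed.
#' @param fps frames per second (default 25).
#' @param recordingId identifier.
#' @return A [LabelSequence-class] over alphabet 1..NC.
#' @export
simulateLabels <- function(kernel, nFrames = 15000, seed = 1L, fps = 25,
                           recordingId = "sim") {
  tr <- kernel@transition
  nc <- nrow(tr)
  labels <- .withSeed(seed, {
    out <- integer(0)
    s <- sample.int(nc, 1L)
    while (length(out) < nFrames) {
      run <- stats::rgeom(1L, 1 / kernel@meanRun[s]) + 1L
      out <- c(out, rep(s, run))
      s <- sample.int(nc, 1L, prob = tr[s, ])
    }
    out[seq_len(nFrames)]
  })
  new("LabelSequence", recordingId = recordingId, labels = labels,
      alphabet = seq_len(nc), fps = fps, frameOffset = 0L)
}

#' Simulate a two-group behavioral experiment
#'
#' Control animals draw their kernels by Dirichlet perturbation of the base
#' kernel; treated animals perturb the effect-modified kernel with the same
#' scheme. Label sequences are then simulated per animal. The ground-truth
#' kernels, group assignment and master seed travel with the result.
#'
#' @param nPerGroup animals per group (>= 2); a length-2 vector gives
#'   (control, treated) sizes.
#' @param baseKernel a [BehaviorKernel-class].
#' @param effect a [GroupEffectSpec-class] or NULL for a null experiment.
#' @param jitterConcentration Dirichlet concentration of the per-animal
#'   kernel variability (default 100; Inf disables jitter).
#' @param nFrames frames per recording (default 15000).
#' @param seed integer master seed.
#' @param fps frames per second.
#' @return A [SyntheticExperiment-class].
#' @export
simulateExperiment <- function(nPerGroup, baseKernel, effect = NULL,
                               jitterConcentration = 100, nFrames = 15000,
                               seed = 1L, fps = 25) {
  if (length(nPerGroup) == 1L) nPerGroup <- rep(nPerGroup, 2L)
  stopifnot(all(nPerGroup >= 2L))
  treatedKernel <- applyGroupEffect(baseKernel, effect)
  rng <- .seededRNG(seed)
  labels <- list(); kernels <- list(); groups <- character(0)
  for (g in 1:2) {
    base <- if (g == 1L) baseKernel else treatedKernel
    gname <- c("control", "treated")[g]
    for (a in seq_len(nPerGroup[g])) {
      id <- sprintf("%s_%02d", gname, a)
      k <- .jitterKernel(base, jitterConcentration, rng)
      sd <- rng$sampleInt(.Machine$integer.max, 1L)
      labels[[id]] <- simulateLabels(k, nFrames = nFrames, seed = sd,
                                     fps = fps, recordingId = id)
      kernels[[id]] <- k
      groups[id] <- gname
    }
  }
  new("SyntheticExperiment", labels = labels, groups = groups,
      kernels = kernels, seed = as.integer(seed))
}

#' Grouped transition set of a synthetic experiment
#'
#' Convenience: transition matrices of all recordings, split by group.
#'
#' @param experiment a [SyntheticExperiment-class].
#' @param smooth halfwidth for modal smoothing before counting (default 0:
#'   no smoothing).
#' @return A [GroupedTransitionSet-class].
#' @export
experimentTransitions <- function(experiment, smooth = 0) {
  mk <- function(seq) {
    if (smooth > 0) seq <- smoothLabels(seq, smooth)
    transitionMatrix(seq)
  }
  ctl <- lapply(experiment@labels[experiment@groups == "control"], mk)
  trt <- lapply(experiment@labels[experiment@groups == "treated"], mk)
  groupedTransitionSet(unname(ctl), unname(trt))
}

## Canonical 13-point body template: (along-axis, perpendicular) offsets as
## fractions of the body length, image convention.
.BODY_TEMPLATE <- matrix(c(
   0.55,  0.00,   # nose
   0.42,  0.00,   # headcentre
   0.32,  0.00,   # neck
   0.40,  0.08,   # earr
   0.40, -0.08,   # earl
   0.10,  0.00,   # bodycentre
   0.10, -0.12,   # bcl
   0.10,  0.12,   # bcr
  -0.12, -0.10,   # hipl
  -0.12,  0.10,   # hipr
  -0.20,  0.00,   # tailbase
  -0.35,  0.00,   # tailcentre
  -0.50,  0.00),  # tailtip
  ncol = 2, byrow = TRUE,
  dimnames = list(.STANDARD_POINTS, c("along", "perp")))

#' Default per-state kinematic templates
#'
#' Spreads state speed ranges over 0-30 cm/s and body elongation over
#' 0.7-1.3 of an 8 cm body, so states differ in locomotion and posture.
#'
#' @param nStates number of behavioral states.
#' @return Named list: per state, `speedRange` (cm/s) and `bodyLength` (cm).
#' @export
defaultPoseTemplates <- function(nStates) {
  out <- lapply(seq_len(nStates), function(s) {
    frac <- (s - 1) / max(1, nStates - 1)
    list(speedRange = c(25 * frac, 25 * frac + 5),
         bodyLength = 8 * (0.7 + 0.6 * frac))
  })
  names(out) <- as.character(seq_len(nStates))
  out
}

#' Simulate a pose recording from a label sequence
#'
#' Generates 13 tracked body points following state-dependent kinematics: a
#' body-center random walk whose per-frame speed is drawn from the active
#' state's speed range, a smoothly drifting heading, and a rigid body-shape
#' template scaled by the state's body length. Gaussian positional jitter
#' is added, likelihoods dip below 0.95 at the stated rate, and four
#' jittered but static corner points span a square arena.
#'
#' @param labels a [LabelSequence-class] defining the per-frame state.
#' @param templates per-state kinematics (see [defaultPoseTemplates()]);
#'   every state in the alphabet must be covered.
#' @param arenaPx arena side length in pixels (default 500, with corners
#'   inset 50 px).
#' @param realSizeCm2 physical arena area in cm^2 (default 1600, a 40 x 40
#'   cm open field).
#' @param jitterSd positional tracking noise, px (default 1).
#' @param dipRate per-frame probability of a likelihood dip below 0.95
#'   (default 0.02).
#' @param seed integer seed.
#' @return A raw [TrackingRecording-class] with the 13 body points plus
#'   `corner1..corner4`.
#' @export
simulatePose <- function(labels, templates = NULL, arenaPx = 500,
                         realSizeCm2 = 1600, jitterSd = 1,
                         dipRate = 0.02, seed = 1L) {
  states <- labels@alphabet
  if (is.null(templates)) templates <- defaultPoseTemplates(length(states))
  missing <- setdiff(as.character(states), names(templates))
  if (length(missing))
    stop("templates missing state(s): ", paste(missing, collapse = ", "))
  n <- length(labels@labels)
  margin <- arenaPx / 10
  lo <- margin; hi <- arenaPx - margin
  pxPerCm <- sqrt((hi - lo)^2 / realSizeCm2)
  fps <- labels@fps
  .withSeed(seed, {
    pos <- matrix(NA_real_, n, 2)
    pos[1, ] <- c(mean(c(lo, hi)), mean(c(lo, hi)))
    heading <- stats::runif(1, 0, 2 * pi)
    headings <- numeric(n); headings[1] <- heading
    for (f in 2:n) {
      tpl <- templates[[as.character(labels@labels[f])]]
      sp <- stats::runif(1, tpl$speedRange[1], tpl$speedRange[2])
      step <- sp / fps * pxPerCm
      ## a stationary animal keeps its heading (and hence its posture)
      if (step > 0) heading <- heading + stats::rnorm(1, 0, 0.3)
      cand <- pos[f - 1, ] + step * c(cos(heading), sin(heading))
      ## bounce off the walls (kept inside the tracked corner square)
      for (dch in 1:2) {
        if (cand[dch] < lo) { cand[dch] <- 2 * lo - cand[dch]
                              heading <- heading + pi / 2 }
        if (cand[dch] > hi) { cand[dch] <- 2 * hi - cand[dch]
                              heading <- heading + pi / 2 }
      }
      cand <- pmin(pmax(cand, lo), hi)
      pos[f, ] <- cand
      headings[f] <- heading
    }
    pts <- .STANDARD_POINTS
    x <- y <- lk <- matrix(NA_real_, n, length(pts) + 4L,
                           dimnames = list(NULL, c(pts, paste0("corner",
                                                               1:4))))
    bl <- vapply(as.character(labels@labels), function(s)
      templates[[s]]$bodyLength, numeric(1)) * pxPerCm
    ca <- cos(headings); sa <- sin(headings)
    for (p in seq_along(pts)) {
      a <- .BODY_TEMPLATE[p, 1] * bl; b <- .BODY_TEMPLATE[p, 2] * bl
      x[, p] <- pos[, 1] + a * ca - b * sa +
        stats::rnorm(n, 0, jitterSd)
      y[, p] <- pos[, 2] + a * sa + b * ca +
        stats::rnorm(n, 0, jitterSd)
      dip <- stats::runif(n) < dipRate
      lk[, p] <- ifelse(dip, stats::runif(n, 0, 0.95),
                        stats::runif(n, 0.95, 1))
    }
    corners <- rbind(c(lo, lo), c(hi, lo), c(hi, hi), c(lo, hi))
    for (cpt in 1:4) {
      j <- length(pts) + cpt
      x[, j] <- corners[cpt, 1] + stats::rnorm(n, 0, 0.5)
      y[, j] <- corners[cpt, 2] + stats::rnorm(n, 0, 0.5)
      lk[, j] <- stats::runif(n, 0.97, 1)
    }
    TrackingRecording(x, y, lk, fps = fps,
                      recordingId = labels@recordingId)
  })
}
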