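---
title: "Behavioral flow analysis: model, parameters and design choices"
author: "bflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral flow analysis: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bflow)
```

## The problem

Unsupervised segmentation of rodent open-field behavior into short motifs
("behavioral clusters" or syllables) produces rich per-frame descriptions,
but group comparisons on individual clusters or individual cluster-to-cluster
transitions lose power to multiple-testing correction: with NC clusters there
are NC^2 cells of the transition matrix and typically hundreds of observed
transitions. `bflow` instead treats the *whole* transition matrix — the
animal's behavioral flow — as one observation per animal and compares groups
with a single permutation test, recovering power while keeping the per-frame
resolution of the clustering.

The package covers the full path from raw pose-estimation tables to group
statistics:

1. **Tracking** (`readPoseTable`, `inferArena`, `preprocessRecording`,
   `classicalReadouts`): import, arena calibration, likelihood/existence
   filtering with interpolation, kinematics, and the classical readouts
   (distance moved, zone times, zone transitions).
2. **Features** (`defaultFeatureRegistry`, `extractFeatures`,
   `normalizeFeatures`, `temporalExpand`): a fixed registry of m = 41
   per-frame features of five kinds, per-recording normalization, and
   temporal expansion over ±15 frames to mt = 1,271 columns.
3. **Clustering** (`assembleClusteringSubset`, `fitKmeans`,
   `assignClusters`, `selectClusterCount`): k-means over a standardized
   multi-experiment subset, nearest-center assignment for new data, and the
   95%-coverage rule for choosing the cluster count.
4. **Stabilization** (`trainClassifier`, `applyClassifier`,
   `crossvalidate`): a supervised classifier that imitates the reference
   clustering so new recordings receive consistent labels.
5. **Flow** (`smoothLabels`, `transitionMatrix`, `computeMetrics`,
   `stabilize`, `crossTabulate`, `binLabels`): label smoothing, run-length
   transition counting, control-referenced stabilization, and time bins.
6. **Statistics** (`bfaPermutation`, `perUnitTests`, `bflScores`,
   `cohensDFromBfl`, `powerCurve`, `stratifyResponders`,
   `sensitivityAssay`, `logLinearDoseModel`): the permutation test, per-unit
   t-tests with Benjamini–Yekutieli correction, likeness scores, effect
   sizes, power, responder stratification and dose modeling.
7. **Fingerprinting** (`bffEmbed`, `groupSummary`): 2D embedding of
   per-animal matrices.
8. **Synthetic data** (`simulateLabels`, `simulateExperiment`,
   `simulatePose`): generative models for validating every stage.

## The statistical model

### Transition matrices

A label sequence is first compressed to its *occurrence vector* (consecutive
repeats removed); lag-1 pairs of that vector are counted into an NC × NC
matrix `T_i` with a structurally zero diagonal. The total count equals
(number of runs − 1), a conservation law the tests assert exactly. "Possible
transitions" can be counted with the diagonal (NC^2 cells, e.g. 625 for
NC = 25) or without it (NC·(NC−1) ordered pairs, e.g. 4,830 for NC = 70);
statistical families use the diagonal-exclusive convention restricted to
*observed* transitions (nonzero total count).

### The flow permutation test (BFA)

For control recordings C (n = N_C) and test recordings T (n = N_T) with
per-recording counts `x[j,k,r]`,

    D = Σ_j Σ_k | mean_C x[j,k,C] − mean_T x[j,k,T] |

is the Manhattan distance between the group-mean matrices. The group
assignment vector is shuffled `nPerm` times (group sizes preserved) to give a
null sample D_1..D_B, from which three summaries are reported:

* percentile = 100 · Σ_b (D_b < D) / (B + 1), with *strict* inequality, so
  the ceiling with B = 1,000 permutations is 100·1000/1001 = 99.9;
* z = (D − mean(D_b)) / sd(D_b);
* right-tailed p = (1 − erf(z/√2)) / 2, evaluated through the standard
  normal upper tail (`pnorm(z, lower.tail = FALSE)`), which is the same
  quantity but keeps relative precision for z > 5 where the erf difference
  underflows.

### Likeness scores (BFL), effect size and power

For each sample i, the elementwise median matrices M_A and M_B of the two
groups are computed over all *other* samples (i is excluded from its own
group), and

    BFL_i = log( d(T_i, M_A) / d(T_i, M_B) )

with Manhattan distances d. The score is scale-invariant (a global positive
rescaling of all matrices cancels in the ratio) and, with the formula written
this way, *negative* when the sample sits closer to group A — the sign
convention is documented here because the opposite reading is also in
circulation; stratification and effect sizes are unaffected since they only
use ranges and differences of scores. Cohen's d between the groups' scores
(classic (n−1)-weighted pooled SD) feeds exact noncentral-t power curves
(`power.t.test`, strict two-sided). At d = 0 power equals α identically; the
implementation returns α exactly in that case rather than the last floating
rounding of the noncentral-t evaluation.

Treated animals whose BFL score lies in the *closed* full range of control
scores are nonresponders; all others are responders.

### Per-unit tests

Cluster occurrences, time in cluster and individual transitions are compared
with two-sample t-tests (Welch by default — the unequal-variance form is the
safer default for count data; a pooled-variance option exists) and corrected
with Benjamini–Yekutieli over the family actually tested: observed
transitions, or the clusters.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `likelihoodThreshold` | 0.95 | minimum tracking confidence per point/frame |
| `existenceScale` | 1.3 | arena scaling of the existence polygon |
| `centerScale` | 0.5 | linear size of the default center zone |
| temporal `halfwidth` | 15 | ±frames of expansion (t = 31, mt = 1,271) |
| smoothing `halfwidth` | 5 | ±frames of the modal label filter |
| `k` (NC) | 25 | cluster count; k = 100 only for the coverage rule |
| `coverage` | 0.95 | frame coverage for `selectClusterCount` |
| `nPerm` | 1000 | BFA permutations |
| classifier | 1,024 ReLU units, dropout 0.4, 30 epochs, batch 512, RMSprop | `"mlp"` backend |
| `alpha` | 0.05 | significance level for power curves |
| sensitivity `sizes` | 25, 20, 15, 10, 5 | group sizes, 50 subsamples each |

## Numerical and design choices

* **Coordinates** follow the image convention (origin top-left, y downward),
  matching pose-estimation exports; all geometry (zones, existence polygon,
  border distances) respects it.
* **Interpolation** of filtered frames is linear in time per coordinate;
  leading/trailing gaps take the nearest valid value. Frames that pass both
  filters are never modified.
* **Calibration**: px/cm = √(arena pixel area / arena cm² area); the
  existence polygon scales about the polygon centroid.
* **Kinematics**: speed and acceleration by first/second finite differences
  of the cleaned positions, with the leading frame(s) padded by replication.
* **Feature registry**: the exact identity of the 41 features is
  configuration-defined; the shipped default covers the five kinds over the
  13 standard points (13 accelerations, 12 distances, 6 signed angles,
  6 border proximities, 4 polygon areas) and is canonically ordered so a
  shuffled configuration reproduces the identical registry. Angles are
  signed and wrapped to (−π, π].
* **Temporal expansion** drops frames lacking a full window rather than
  padding (no fabricated kinematics at the boundaries); the recorded frame
  offset re-aligns labels to original frames. Columns are offset-major.
* **Standardization**: the column z-scorer fitted on the clustering subset
  is persisted and reused verbatim for every later assignment and classifier
  application, guaranteeing train/apply consistency. Zero-variance columns
  standardize to 0 and are kept, preserving the input width.
* **k-means** uses seeded k-means++-style center spreading with restarts
  (best inertia kept) on top of Lloyd iterations; determinism given the seed
  is part of the contract. Nearest-center ties break to the lowest cluster
  id, as do modal-smoothing and classifier argmax ties.
* **Classifier backends**: the default `"mlp"` implements the
  single-hidden-layer architecture above in base R with inverted dropout and
  RMSprop; `"multinom"` (multinomial logistic regression) is the lightweight
  alternative used where training cost matters more than capacity. The
  contract is "any probabilistic multi-class model meeting the CV
  thresholds". Cross-validation folds are formed at the *recording* level so
  no validation frames leak into training.
* **Stabilization** subtracts the control-group mean matrix; the stabilized
  control mean is zero up to float summation order (bit-exact when the
  control count is a power of two).
* **Permutation ties** count strictly (a permuted distance equal to the
  observed one is not "less"), which bounds the percentile at
  100·B/(B+1).
* **BFL** uses raw transition matrices by default; stabilized matrices can
  be passed instead since the functions only see matrices.
* **Embedding**: no UMAP implementation is available to this package's R
  dependency set, and figure geometry is not a validated quantity here, so
  `bffEmbed` uses Kruskal non-metric MDS on Manhattan distances of the
  flattened matrices — a nonlinear, rank-preserving neighborhood embedding —
  initialized from the deterministic classical-MDS solution (seeded jitter
  only for degenerate ties). It is a pure function of inputs, seed and
  hyperparameters. For cross-experiment fingerprints, stabilize each
  experiment against its own internal control group first.
* **Degenerate inputs**: identical matrices embed to finite (zero)
  coordinates; single-class training sets yield a constant classifier;
  zero distances in BFL give flagged infinite scores; zero doses/counts are
  excluded before the log-linear fit.

## The synthetic generator

`simulateLabels` draws a Markov state sequence with geometric (memoryless)
dwell times — mean run length 20 frames by default, long enough that ±5-frame
modal smoothing rarely destroys a true run — and an inter-state transition
kernel with zero diagonal. `simulateExperiment` derives per-animal kernels by
Dirichlet perturbation of the group kernel (the simplest exchangeable model
of animal-to-animal variability; concentration exposed) and applies
multiplicative group effects on selected transitions with row
renormalization. `simulatePose` renders a label sequence as 13 body points on
a rigid template with state-dependent speed and body length, a drifting
heading, Gaussian tracking jitter, seeded likelihood dips and four static
corner points — deliberately coarse: its purpose is to exercise the pipeline
(calibration, filtering, features, clustering), not to imitate mouse
biomechanics.

What the generator does *not* emulate: grooming-like postural detail,
wall-following and thigmotaxis, heavy-tailed dwell times, inter-frame
autocorrelated tracking noise, or occlusions. Passing tests therefore
demonstrate correctness of the computations and recoverability of Markovian
flow structure, not performance on real videos.

### Problem sizes used by the test-suite demonstrations

The package's own validation runs at desk scale: end-to-end recovery uses
two groups of 6 recordings, 2,500 frames each, 3 generative states, ±5-frame
expansion and 500 permutations; calibration uses 200 null experiments of
2 × 5 recordings with 600 frames and 300 permutations; classifier transfer
uses 60 recordings of 125 frames over 25 well-separated clusters with the
lightweight backend. These sizes were chosen once as the smallest at which
the respective effects are unambiguous.

## Worked example

```{r example}
kernel <- uniformKernel(4, meanRun = 15)
effect <- groupEffect(c(1, 2, 2, 1), c(6, 1 / 6))
ex <- simulateExperiment(10, kernel, effect, jitterConcentration = 200,
                         nFrames = 3000, seed = 7)
groups <- experimentTransitions(ex, smooth = 5)

bfa <- bfaPermutation(groups, nPerm = 1000, seed = 7)
bfa

scores <- bflScores(groups)
cohensDFromBfl(scores)
powerCurve(cohensDFromBfl(scores), nGrid = c(3, 5, 10, 20))
```

## Limitations

* The BFA p-value is parametric (normal upper tail of the standardized
  distance); its calibration is verified empirically on the generator's null
  experiments, but heavy-tailed permutation nulls at very small group sizes
  can distort it — the percentile is the safer nonparametric summary there.
* The default 41-feature registry is a documented fixed choice, not a
  learned or optimal one; registries are configuration, and models do not
  transfer across registries without retraining.
* Lag-1 transitions only; no dwell-time distributions or higher-order flow
  statistics.
* The embedding is for visual exploration; no quantitative claims are
  attached to its geometry.
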