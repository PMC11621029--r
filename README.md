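# bflow — behavioral flow analysis of pose-estimation tracking data

`bflow` quantifies rodent behavior from markerless pose-estimation tables
and compares experimental groups through their **behavioral flow**: the
matrix of transitions between unsupervised behavioral clusters within each
recording. It is written for behavioral neuroscientists who already run
pose estimation (e.g. open-field recordings with ~13 tracked body points)
and want group statistics that use an animal's *entire* behavioral
repertoire instead of one hand-picked readout — without the power loss
that multiple-testing correction inflicts on per-cluster or per-transition
tests.

## What it computes

For each recording, per-frame cluster labels are compressed to runs and
lag-1 transitions are counted into a matrix `T_i ∈ W^(NC×NC)` (diagonal
structurally zero). Two groups (controls C, tests T) are then compared by
the Manhattan distance between their mean matrices,

    D = Σ_jk | mean_C x[j,k,C] − mean_T x[j,k,T] | ,

against a permutation null from 1,000 shuffles of the group-assignment
vector, reporting the percentile `100·Σ(D_b < D)/(B+1)`, the standardized
distance `z = (D − mean D_b)/sd D_b`, and the right-tailed parametric
`p = (1 − erf(z/√2))/2` (**BFA**). Per-animal **BFL** likeness scores
`log(d_A/d_B)` — distances to the leave-one-out elementwise-median
matrices of the two groups — provide effect sizes (Cohen's d), exact
noncentral-t power curves, and responder/nonresponder stratification.
**BFF** embeds each animal's control-referenced (stabilized) matrix
`T_i − mean(T_controls)` into 2D for individual-level comparison.

Upstream, the package implements the full preparation pipeline: arena
calibration from tracked corners, likelihood/existence filtering with
interpolation, a 41-feature per-frame registry with ±15-frame temporal
expansion (1,271 columns), seeded k-means clustering with the 95%-coverage
rule for choosing the cluster count, and a classifier-in-the-middle that
stabilizes cluster labels across experiments (validated by recording-level
10-fold cross-validation). A synthetic-data module generates Markovian
label sequences and coarse 13-point pose recordings so every stage is
testable without any video data.

## Worked example

Simulate a two-group experiment (10 animals per group, 3,000 frames each)
in which the treatment multiplies the 1→2 transition probability by 6 and
divides 2→1 by 6, with Dirichlet animal-to-animal kernel variability; then
run the flow statistics:

```r
library(bflow)

kernel <- uniformKernel(4, meanRun = 15)
effect <- groupEffect(c(1, 2, 2, 1), c(6, 1/6))
ex     <- simulateExperiment(10, kernel, effect, jitterConcentration = 200,
                             nFrames = 3000, seed = 7)
groups <- experimentTransitions(ex, smooth = 5)

bfaPermutation(groups, nPerm = 1000, seed = 7)
#> Behavioral flow analysis (1000 permutations)
#>   Manhattan distance : 44.5
#>   percentile         : 99.9
#>   z                  : 5.15
#>   right-tailed P     : 1.31e-07

d <- cohensDFromBfl(bflScores(groups))
d
#> [1] 4.831272
powerCurve(d, nGrid = c(3, 5, 10, 20))
#> Power curve: d = 4.83, alpha = 0.05
#>   n     power
#>   3 0.9895237
#>   5 0.9999979
#>  10 1.0000000
#>  20 1.0000000
```

The observed inter-group distance (44.5) exceeds all 1,000 permuted
distances, so the percentile sits at its ceiling 100·1000/1001 = 99.9; the
standardized distance z = 5.15 gives a right-tailed p of 1.3×10⁻⁷, and the
BFL-based effect size (d ≈ 4.8) implies near-certain detection already at
n = 3 per group. Individual transitions can be tested too — here the
implanted 2→3/1→3 imbalance surfaces with Benjamini–Yekutieli-adjusted
p-values:

```r
tab <- perUnitTests(groups)
head(tab[order(tab$pAdjusted), ], 3)
#>   unit         t            p    pAdjusted meanControl meanTest
#> 5 2->3 -7.262895 9.735331e-07 3.625294e-05        11.3     20.3
#> 2 1->3  6.620127 4.462085e-06 8.308075e-05        10.6      5.0
#> 3 1->4  4.539671 4.504624e-04 4.887610e-03        11.2      5.1
```

A thin command-line front end over the same functions ships in
`inst/scripts/bflow` (`sim-labels`, `smooth`, `transitions`, `readouts`,
`bfa`, `embed`).

## Package layout

- `R/` — S4 classes (`TrackingRecording`, `LabelSequence`,
  `TransitionMatrix`, `BFAResult`, …) and the pipeline functions.
- `tests/testthat/` — unit, property and acceptance suites; all fixtures
  are generated in code.
- `vignettes/behavioral-flow.Rmd` — the model, its parameters, numerical
  choices and limitations.
- `inst/scripts/bflow` — command-line entry point.
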