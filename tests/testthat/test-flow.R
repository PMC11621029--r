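test_that("modal smoothing removes spikes and matches the window oracle", {
  const <- LabelSequence(rep(2L, 30), alphabet = 1:3)
  expect_identical(labelValues(smoothLabels(const, 5)), rep(2L, 30))

  spike <- LabelSequence(c(rep(1L, 5), 3L, rep(1L, 5)), alphabet = 1:3)
  expect_identical(labelValues(smoothLabels(spike, 5)), rep(1L, 11))

  set.seed(1)
  for (r in 1:300) {
    n <- sample(10:60, 1); nc <- sample(2:6, 1); h <- sample(0:6, 1)
    seq <- randomLabelSeq(n, nc)
    expect_identical(labelValues(smoothLabels(seq, h)),
                     bruteSmooth(labelValues(seq), h))
  }
})

test_that("smoothing is idempotent when all runs exceed twice the window", {
  set.seed(2)
  for (r in 1:20) {
    h <- sample(1:4, 1)
    runs <- sample(1:4, 10, replace = TRUE)
    runs <- runs[c(TRUE, diff(runs) != 0)]  # no adjacent repeats
    lab <- rep(runs, each = 2 * h + 1 + sample(1:3, 1))
    s1 <- smoothLabels(LabelSequence(lab, alphabet = 1:4), h)
    s2 <- smoothLabels(s1, h)
    expect_identical(labelValues(s1), labelValues(s2))
  }
})

test_that("transition matrices equal brute-force run-pair counting", {
  seq <- LabelSequence(c(1L, 1L, 2L, 2L, 1L), alphabet = 1:2)
  tm <- transitionMatrix(seq)
  expect_equal(transitionCounts(tm)["1", "2"], 1L, ignore_attr = TRUE)
  expect_equal(transitionCounts(tm)["2", "1"], 1L, ignore_attr = TRUE)
  expect_equal(sum(transitionCounts(tm)), 2L)

  expect_true(all(transitionCounts(
    transitionMatrix(LabelSequence(rep(3L, 40), alphabet = 1:5))) == 0))

  set.seed(3)
  for (r in 1:1000) {
    n <- sample(2:80, 1); nc <- sample(2:6, 1)
    seq <- randomLabelSeq(n, nc)
    got <- transitionCounts(transitionMatrix(seq))
    expect_equal(got, bruteTransitions(labelValues(seq), 1:nc),
                 ignore_attr = TRUE)
  }
  bad <- LabelSequence(1:3, alphabet = 1:3)
  bad@alphabet <- 1:2  # bypass constructor validity on purpose
  expect_error(transitionMatrix(bad), "alphabet")
})

test_that("transition totals and out-degrees obey run conservation", {
  set.seed(4)
  for (r in 1:200) {
    seq <- randomLabelSeq(sample(2:100, 1), sample(2:6, 1))
    lab <- labelValues(seq)
    runs <- rle(lab)$values
    counts <- transitionCounts(transitionMatrix(seq))
    expect_equal(sum(counts), length(runs) - 1L)
    occ <- table(factor(runs, levels = seq@alphabet))
    out <- rowSums(counts)
    for (cl in seq@alphabet) {
      expected <- occ[[as.character(cl)]] -
        (if (runs[length(runs)] == cl) 1L else 0L)
      expect_equal(unname(out[cl]), expected)
    }
  }
})

test_that("per-cluster metrics equal a run-length-encoding oracle", {
  seq <- LabelSequence(c(1L, 1L, 2L, 2L, 1L), alphabet = 1:2)
  m <- computeMetrics(seq)
  expect_equal(m$occurrences, c(2L, 1L))
  expect_equal(m$frames, c(3L, 2L))
  expect_equal(m$onsets[[1]], c(1L, 5L))
  expect_equal(m$offsets[[2]], 4L)

  const <- computeMetrics(LabelSequence(rep(2L, 50), alphabet = 1:2,
                                        fps = 25))
  expect_equal(const$occurrences, c(0L, 1L))
  expect_equal(const$seconds, c(0, 2))

  set.seed(5)
  for (r in 1:100) {
    seq <- randomLabelSeq(sample(5:60, 1), 4)
    m <- computeMetrics(seq)
    rl <- rle(labelValues(seq))
    expect_equal(sum(m$frames), length(labelValues(seq)))
    for (cl in 1:4) {
      expect_equal(m$occurrences[cl], sum(rl$values == cl))
      expect_equal(m$frames[cl], sum(rl$lengths[rl$values == cl]))
      ## onsets and offsets alternate and pair
      expect_length(m$onsets[[cl]], m$occurrences[cl])
      expect_true(all(m$offsets[[cl]] >= m$onsets[[cl]]))
    }
  }
})

test_that("stabilization subtracts the control mean exactly", {
  set.seed(6)
  mkT <- function(id) transitionMatrix(
    LabelSequence(sample.int(4, 60, replace = TRUE), alphabet = 1:4,
                  recordingId = id))
  controls <- lapply(paste0("c", 1:5), mkT)
  target <- mkT("t")

  ## elementwise loop oracle
  st <- stabilize(target, controls)
  ctlMean <- matrix(0, 4, 4)
  for (m in controls) ctlMean <- ctlMean + transitionCounts(m)
  ctlMean <- ctlMean / 5
  expect_equal(st@values, transitionCounts(target) - ctlMean,
               ignore_attr = TRUE)

  ## single control: plain difference
  s1 <- stabilize(target, controls[1])
  expect_equal(s1@values,
               transitionCounts(target) - transitionCounts(controls[[1]]),
               ignore_attr = TRUE)

  ## stabilized controls average to zero (up to float summation order)
  stabCtl <- lapply(controls, stabilize, controls = controls)
  total <- Reduce(`+`, lapply(stabCtl, function(s) s@values))
  expect_lt(max(abs(total / 5)), 1e-12)

  other <- transitionMatrix(LabelSequence(c(1L, 2L), alphabet = 1:2))
  expect_error(stabilize(target, list(other)), "alphabet")
  expect_error(stabilize(target, list()), "nonempty")
})

test_that("cross-tabulation counts frame pairs with correct margins", {
  a <- LabelSequence(c(1L, 1L, 2L, 3L), alphabet = 1:3)
  expect_equal(diag(crossTabulate(a, a)), c(2L, 1L, 1L),
               ignore_attr = TRUE)

  set.seed(7)
  b <- randomLabelSeq(40, 3); c2 <- randomLabelSeq(40, 5)
  tab <- crossTabulate(b, c2)
  expect_equal(rowSums(tab), as.integer(table(factor(labelValues(b),
                                                     levels = 1:3))),
               ignore_attr = TRUE)
  expect_equal(colSums(tab), as.integer(table(factor(labelValues(c2),
                                                     levels = 1:5))),
               ignore_attr = TRUE)

  d1 <- LabelSequence(rep(1L, 10), alphabet = 1:2)
  d2 <- LabelSequence(rep(2L, 10), alphabet = 1:2)
  tab2 <- crossTabulate(d1, d2)
  expect_equal(sum(tab2 > 0), 1L)
  expect_equal(tab2[1, 2], 10L, ignore_attr = TRUE)

  short <- LabelSequence(rep(1L, 9), alphabet = 1:2)
  expect_error(crossTabulate(d1, short), "aligned")
})

test_that("offset-aware cross-tabulation aligns expanded labelings", {
  full <- LabelSequence(c(1L, 1L, 2L, 2L, 2L, 1L, 1L, 1L), alphabet = 1:2)
  trimmed <- LabelSequence(labelValues(full)[3:8], alphabet = 1:2,
                           frameOffset = 2L)
  tab <- crossTabulate(full, trimmed)
  expect_equal(sum(tab), 6L)        # only the common frames
  expect_equal(sum(diag(tab)), 6L)  # and they agree exactly
})

test_that("time binning splits metrics and transition counts cleanly", {
  seq <- LabelSequence(rep(1:2, 900), alphabet = 1:2,
                       fps = 1)  # 30 "minutes" at 1 fps, in seconds
  bins <- binLabels(seq, 360)  # 6-minute bins
  expect_length(bins, 5)
  expect_equal(sum(lengths(lapply(bins, labelValues))), 1800)

  one <- binLabels(seq, 1800)
  expect_length(one, 1)
  expect_identical(labelValues(one[[1]]), labelValues(seq))
  expect_warning(binLabels(seq, 5000), "single bin")

  ## per-bin totals lose exactly the boundary-spanning transitions
  set.seed(8)
  for (r in 1:50) {
    seq <- randomLabelSeq(sample(50:200, 1), 4, fps = 5)
    binSec <- sample(2:6, 1)
    bins <- suppressWarnings(binLabels(seq, binSec))
    whole <- sum(transitionCounts(transitionMatrix(seq)))
    parts <- sum(vapply(bins, function(b)
      sum(transitionCounts(transitionMatrix(b))), numeric(1)))
    ## boundary oracle: count label changes across bin edges
    fpb <- round(binSec * seq@fps)
    lab <- labelValues(seq)
    edges <- seq(fpb, length(lab) - 1, by = fpb)
    crossing <- sum(lab[edges] != lab[edges + 1])
    expect_equal(whole - parts, crossing)
    expect_lte(parts, whole)
  }
})

test_that("label sequences round-trip through CSV", {
  seq <- LabelSequence(c(3L, 1L, 2L, 2L), alphabet = 1:3, fps = 10,
                       recordingId = "rt", frameOffset = 4L)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLabelSequence(seq, path)
  back <- readLabelSequence(path, alphabet = 1:3, fps = 10)
  expect_identical(labelValues(back), labelValues(seq))
})
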