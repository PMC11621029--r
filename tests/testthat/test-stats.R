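mkTM <- function(counts, id = "m", alphabet = NULL) {
  counts <- as.matrix(counts)
  if (is.null(alphabet)) alphabet <- seq_len(nrow(counts))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(alphabet, alphabet)
  new("TransitionMatrix", counts = counts, recordingId = id,
      alphabet = as.integer(alphabet))
}

randomGroups <- function(nC, nT, nc = 3, lam = 4, seed = 1) {
  set.seed(seed)
  mk <- function(id) {
    m <- matrix(rpois(nc * nc, lam), nc); diag(m) <- 0L
    mkTM(m, id)
  }
  groupedTransitionSet(lapply(paste0("c", seq_len(nC)), mk),
                       lapply(paste0("t", seq_len(nT)), mk))
}

test_that("Manhattan group distance matches a double-loop oracle", {
  g <- groupedTransitionSet(list(mkTM(rbind(c(0, 2), c(3, 0)))),
                            list(mkTM(rbind(c(0, 4), c(1, 0)))))
  expect_equal(manhattanGroupDistance(g), 4)  # |2-4| + |3-1|

  gid <- groupedTransitionSet(list(mkTM(rbind(c(0, 2), c(3, 0)))),
                              list(mkTM(rbind(c(0, 2), c(3, 0)))))
  expect_equal(manhattanGroupDistance(gid), 0)

  set.seed(2)
  for (r in 1:200) {
    g <- randomGroups(sample(2:5, 1), sample(2:5, 1), nc = sample(2:4, 1),
                      seed = r + 100)
    meanOf <- function(lst) Reduce(`+`, lapply(lst, transitionCounts)) /
      length(lst)
    oracle <- 0
    mc <- meanOf(g@control); mt <- meanOf(g@test)
    for (i in seq_len(nrow(mc))) for (j in seq_len(ncol(mc)))
      oracle <- oracle + abs(mc[i, j] - mt[i, j])
    expect_equal(manhattanGroupDistance(g), oracle)
    ## symmetry
    flipped <- groupedTransitionSet(g@test, g@control)
    expect_equal(manhattanGroupDistance(flipped),
                 manhattanGroupDistance(g))
  }
})

test_that("the erf-based p-value agrees with a quadrature oracle", {
  expect_equal(erfPvalue(0), 0.5)
  ## printed two-decimal z values bracket the printed P
  pRange <- function(z) c(erfPvalue(z + 0.005), erfPvalue(z - 0.005))
  expect_true(1.01e-3 >= pRange(3.09)[1] && 1.01e-3 <= pRange(3.09)[2])
  expect_true(5.28e-9 >= pRange(5.72)[1] && 5.28e-9 <= pRange(5.72)[2])
  for (z in seq(-8, 8, by = 0.5)) {
    oracle <- integrate(dnorm, z, Inf, rel.tol = 1e-13,
                        abs.tol = 0)$value
    expect_equal(erfPvalue(z), oracle, tolerance = 1e-12)
  }
})

test_that("BFA: ceiling percentile, degenerate guards, null center", {
  g <- disjointPatternGroups(nPer = 8, nc = 10)
  res <- bfaPermutation(g, nPerm = 200, seed = 3)
  expect_equal(res@percentile, 100 * 200 / 201)  # strict ceiling
  expect_gt(res@z, 3)
  expect_lt(res@p, 1e-3)
  expect_length(res@null, 200)
  expect_true(all(res@null >= 0))

  ## determinism and percentile bound over random nulls
  res2 <- bfaPermutation(g, nPerm = 200, seed = 3)
  expect_identical(res@null, res2@null)
  for (s in 1:5) {
    gg <- randomGroups(4, 4, seed = s + 50)
    rr <- bfaPermutation(gg, nPerm = 99, seed = s)
    expect_lte(rr@percentile, 100 * 99 / 100)
  }
  ident <- groupedTransitionSet(rep(list(mkTM(rbind(c(0, 1), c(1, 0)))), 3),
                                rep(list(mkTM(rbind(c(0, 1), c(1, 0)))), 3))
  expect_error(bfaPermutation(ident, nPerm = 50, seed = 1), "degenerate")
})

test_that("an implanted transition effect is detected at small scale", {
  base <- uniformKernel(4, meanRun = 10)
  eff <- groupEffect(c(1, 2, 2, 1), c(10, 0.1))
  ex <- simulateExperiment(6, base, effect = eff,
                           jitterConcentration = Inf, nFrames = 900,
                           seed = 42)
  res <- bfaPermutation(experimentTransitions(ex), nPerm = 500, seed = 42)
  expect_lt(res@p, 0.01)
})

test_that("per-unit t-tests with BY correction behave and match oracles", {
  ## identical groups: all raw p = 1 (constant units skipped)
  m1 <- mkTM(rbind(c(0, 3, 1), c(2, 0, 4), c(1, 2, 0)))
  m2 <- mkTM(rbind(c(0, 5, 2), c(1, 0, 3), c(2, 1, 0)))
  g <- groupedTransitionSet(list(m1, m2), list(m1, m2))
  tab <- suppressMessages(perUnitTests(g))
  expect_true(all(abs(tab$p - 1) < 1e-12))

  ## a single strongly shifted unit gets the smallest adjusted p
  set.seed(4)
  mk <- function(shift, id) {
    m <- matrix(rpois(9, 5), 3); diag(m) <- 0L
    m[1, 2] <- m[1, 2] + shift
    mkTM(m, id)
  }
  g2 <- groupedTransitionSet(lapply(paste0("c", 1:8), function(i) mk(0, i)),
                             lapply(paste0("t", 1:8), function(i) mk(40, i)))
  tab2 <- suppressMessages(perUnitTests(g2))
  expect_equal(tab2$unit[which.min(tab2$pAdjusted)], "1->2")
  expect_true(all(tab2$pAdjusted >= tab2$p - 1e-15))
  expect_true(all(tab2$pAdjusted <= 1))

  ## BY adjustment equals the textbook step-up formula
  set.seed(5)
  for (r in 1:200) {
    m <- sample(2:25, 1)
    p <- runif(m)
    cm <- sum(1 / seq_len(m))
    o <- order(p)
    adjOracle <- numeric(m)
    sorted <- p[o] * m * cm / seq_len(m)
    adjOracle <- rev(cummin(rev(sorted)))
    adjOracle <- pmin(adjOracle, 1)[order(o)]
    expect_equal(p.adjust(p, method = "BY"), adjOracle, tolerance = 1e-12)
  }
  ## monotone in the raw p values
  ord <- order(tab2$p)
  expect_true(all(diff(tab2$pAdjusted[ord]) >= -1e-15))
})

test_that("BFL scores match a hand-worked toy example", {
  ## two clusters; group A members (off-diagonal cells written a->b, b->a)
  A <- list(mkTM(rbind(c(0, 2), c(4, 0)), "a1"),
            mkTM(rbind(c(0, 4), c(6, 0)), "a2"),
            mkTM(rbind(c(0, 6), c(8, 0)), "a3"))
  B <- list(mkTM(rbind(c(0, 20), c(30, 0)), "b1"),
            mkTM(rbind(c(0, 24), c(34, 0)), "b2"))
  g <- groupedTransitionSet(A, B)
  sc <- bflTable(bflScores(g))
  ## by hand, sample a1 = (2, 4): M_A = medians over {a2, a3} = (5, 7);
  ## M_B = medians over {b1, b2} = (22, 32); dA = 3+3 = 6, dB = 20+28 = 48
  expect_equal(sc$dA[sc$sampleId == "a1"], 6)
  expect_equal(sc$dB[sc$sampleId == "a1"], 48)
  expect_equal(sc$score[sc$sampleId == "a1"], log(6 / 48))
  ## sample b1 = (20, 30): M_B(-b1) = (24, 34) -> dB = 4 + 4 = 8;
  ## M_A = medians over all of A = (4, 6) -> dA = 16 + 24 = 40
  expect_equal(sc$dA[sc$sampleId == "b1"], 40)
  expect_equal(sc$dB[sc$sampleId == "b1"], 8)

  ## equidistant sample scores zero
  gEq <- groupedTransitionSet(
    list(mkTM(rbind(c(0, 1), c(5, 0)), "e1"),
         mkTM(rbind(c(0, 1), c(5, 0)), "e2"),
         mkTM(rbind(c(0, 3), c(5, 0)), "probe")),
    list(mkTM(rbind(c(0, 5), c(5, 0)), "f1"),
         mkTM(rbind(c(0, 5), c(5, 0)), "f2")))
  scEq <- bflTable(bflScores(gEq))
  expect_equal(scEq$score[scEq$sampleId == "probe"], 0)

  ## invariance to global positive rescaling
  g10 <- groupedTransitionSet(
    lapply(A, function(m) mkTM(transitionCounts(m) * 10, m@recordingId)),
    lapply(B, function(m) mkTM(transitionCounts(m) * 10, m@recordingId)))
  expect_equal(bflTable(bflScores(g10))$score, sc$score)
})

test_that("Cohen's d follows the pooled-sd definition", {
  ## by hand: |0.5 - 2.5| / sqrt(((1) * 0.5 + (1) * 0.5) / 2) = 2 / sqrt(0.5)
  expect_equal(cohensDFromBfl(c(0, 1, 2, 3), c("A", "A", "B", "B")),
               2 / sqrt(0.5))
  expect_equal(cohensDFromBfl(c(1, 2, 1, 2), c("A", "A", "B", "B")), 0)
  ## large-sample check against the generating effect size
  set.seed(6)
  v <- c(rnorm(10000), rnorm(10000, mean = 1))
  gl <- rep(c("A", "B"), each = 10000)
  expect_equal(cohensDFromBfl(v, gl), 1, tolerance = 0.05)
  ## infinite scores are excluded, with a message
  expect_message(
    d <- cohensDFromBfl(c(0, 1, Inf, 2, 3), c("A", "A", "A", "B", "B")),
    "infinite")
  expect_equal(d, cohensDFromBfl(c(0, 1, 2, 3), c("A", "A", "B", "B")))
})

test_that("power curves: exact alpha at zero effect, monotone, MC-checked", {
  pc0 <- powerCurve(0)
  expect_true(all(pc0@table$power == pc0@alpha))
  pc <- powerCurve(0.8)
  expect_true(all(diff(pc@table$power) >= 0))
  expect_gte(powerCurve(1.2)@table$power[1], pc@table$power[1])

  ## Monte-Carlo rejection rates within 0.02
  set.seed(7)
  for (case in list(c(d = 0.8, n = 20), c(d = 0.5, n = 30))) {
    nSim <- 10000; n <- case[["n"]]; d <- case[["d"]]
    a <- matrix(rnorm(nSim * n), n)
    b <- matrix(rnorm(nSim * n, mean = d), n)
    ma <- colMeans(a); mb <- colMeans(b)
    va <- apply(a, 2, var); vb <- apply(b, 2, var)
    tstat <- (mb - ma) / sqrt((va + vb) / n)
    crit <- qt(0.975, 2 * n - 2)
    mcPower <- mean(abs(tstat) > crit)
    exact <- powerCurve(d, nGrid = n)@table$power
    expect_equal(exact, mcPower, tolerance = 0.02)
  }
})

test_that("responder stratification uses the closed control range", {
  ctl <- c(-1, 0, 0.5, 2)
  expect_equal(stratifyResponders(2, ctl), "nonresponder")     # boundary
  expect_equal(stratifyResponders(c(-1.5, 3), ctl),
               c("responder", "responder"))
  set.seed(8)
  tr <- runif(100, -3, 4)
  got <- stratifyResponders(tr, ctl)
  brute <- ifelse(tr >= min(ctl) & tr <= max(ctl), "nonresponder",
                  "responder")
  expect_identical(got, brute)
  expect_error(stratifyResponders(1, numeric(0)), "empty")
})

test_that("the sensitivity assay summarizes -log10 p by size", {
  g <- randomGroups(8, 8, lam = 6, seed = 9)
  out <- sensitivityAssay(g, sizes = c(8, 5), reps = 6, nPerm = 99,
                          seed = 10)
  expect_equal(out$size, c(8, 5))
  expect_true(all(out$meanNegLog10P > 0))
  ## size = full group: all replicates identical, so sd is exactly 0
  expect_equal(out$sdNegLog10P[out$size == 8], 0)
  expect_gt(out$sdNegLog10P[out$size == 5], 0)
  expect_warning(sensitivityAssay(g, sizes = 10, reps = 2, nPerm = 50,
                                  seed = 1), "skipped")
})

test_that("the log-linear dose model matches closed-form least squares", {
  doses <- c(1, 2, 4, 8, 16)
  counts <- 3 * doses^1.7
  fit <- suppressWarnings(logLinearDoseModel(doses, counts))
  expect_equal(fit$r.squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 1.7, tolerance = 1e-12)

  set.seed(11)
  for (r in 1:50) {
    n <- sample(4:12, 1)
    doses <- exp(runif(n, -1, 2)); counts <- exp(rnorm(n, 2))
    fit <- logLinearDoseModel(doses, counts)
    x <- log(doses); y <- log(counts)
    bHat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    aHat <- mean(y) - bHat * mean(x)
    ssRes <- sum((y - aHat - bHat * x)^2)
    ssTot <- sum((y - mean(y))^2)
    expect_equal(fit$slope, bHat, tolerance = 1e-10)
    expect_equal(fit$r.squared, 1 - ssRes / ssTot, tolerance = 1e-10)
    ## algebraic identity R^2 = F / (F + df2)
    expect_equal(fit$r.squared, fit$f / (fit$f + fit$df2),
                 tolerance = 1e-12)
  }
  expect_message(suppressWarnings(
    logLinearDoseModel(c(0, 1, 2, 3), c(2, 3, 5, 9))), "excluded")
  expect_error(logLinearDoseModel(c(0, 1), c(1, 1)), "at least 3")
})

test_that("dose models across transitions carry a BY-adjusted family", {
  set.seed(12)
  doses <- rep(c(1, 2, 4, 8), each = 3)
  mats <- lapply(seq_along(doses), function(i) {
    m <- matrix(rpois(9, 4) + 1L, 3); diag(m) <- 0L
    m[1, 2] <- round(2 * doses[i]^1.5) # an implanted dose effect
    mkTM(m, paste0("r", i))
  })
  tab <- doseModelTable(doses, mats)
  expect_true(all(tab$pAdjusted >= tab$p - 1e-15))
  expect_equal(tab$transition[which.min(tab$pAdjusted)], "1->2")
})
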