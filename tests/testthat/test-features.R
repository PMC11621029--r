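test_that("the default registry has 41 features over the five kinds", {
  reg <- defaultFeatureRegistry()
  expect_equal(nFeatures(reg), 41)
  expect_setequal(unique(reg@specs$kind),
                  c("point_acceleration", "pair_distance", "pairpair_angle",
                    "border_proximity", "polygon_area"))
  ## normalization rules follow the kinds
  sp <- reg@specs
  expect_true(all(sp$normalization[sp$kind %in%
    c("pair_distance", "polygon_area")] == "zscore"))
  expect_true(all(sp$normalization[sp$kind == "pairpair_angle"] == "raw"))
  expect_equal(unique(sp$factor[sp$kind == "border_proximity"]), 0.1)
  expect_equal(unique(sp$factor[sp$kind == "point_acceleration"]), 4)
})

test_that("registry construction is canonical and validates operands", {
  one <- featureRegistry(data.frame(
    name = "d", kind = "pair_distance", operands = "nose,tailbase"))
  expect_equal(nFeatures(one), 1)

  spec <- defaultFeatureRegistry()@specs
  set.seed(3)
  shuffled <- featureRegistry(spec[sample.int(nrow(spec)), ])
  expect_identical(shuffled@specs, defaultFeatureRegistry()@specs)

  expect_error(featureRegistry(data.frame(
    name = "bad", kind = "pair_distance", operands = "nose,unicorn")),
    "unicorn")
  expect_error(featureRegistry(data.frame(
    name = c("a", "a"), kind = "pair_distance",
    operands = c("nose,neck", "nose,tailbase"))), "duplicate")
})

test_that("feature evaluation matches per-kind geometric oracles", {
  lab <- simulateLabels(uniformKernel(3), nFrames = 120, seed = 2)
  rec <- simulatePose(lab, seed = 3)
  rec <- withArena(rec)
  rec <- preprocessRecording(rec)
  reg <- defaultFeatureRegistry()
  fm <- extractFeatures(rec, reg)
  ppc <- rec@arena@pxPerCm
  sp <- reg@specs
  frames <- c(1, 17, 60, 120)
  for (i in seq_len(nrow(sp))) {
    ops <- trimws(strsplit(sp$operands[i], ",")[[1]])
    for (f in frames) {
      expected <- switch(sp$kind[i],
        point_acceleration = rec@acceleration[f, ops],
        pair_distance = sqrt(sum((c(rec@x[f, ops[1]], rec@y[f, ops[1]]) -
          c(rec@x[f, ops[2]], rec@y[f, ops[2]]))^2)) / ppc,
        pairpair_angle = {
          v1 <- c(rec@x[f, ops[2]] - rec@x[f, ops[1]],
                  rec@y[f, ops[2]] - rec@y[f, ops[1]])
          v2 <- c(rec@x[f, ops[4]] - rec@x[f, ops[3]],
                  rec@y[f, ops[4]] - rec@y[f, ops[3]])
          atan2(v1[1] * v2[2] - v1[2] * v2[1], sum(v1 * v2))
        },
        border_proximity = {
          ## distance to the nearest arena edge, edge by edge
          poly <- rec@arena@corners
          p <- c(rec@x[f, ops], rec@y[f, ops])
          dmin <- Inf
          for (e in seq_len(nrow(poly))) {
            a <- poly[e, ]; b <- poly[if (e == nrow(poly)) 1 else e + 1, ]
            t <- max(0, min(1, sum((p - a) * (b - a)) / sum((b - a)^2)))
            dmin <- min(dmin, sqrt(sum((p - (a + t * (b - a)))^2)))
          }
          dmin / ppc
        },
        polygon_area = {
          px <- rec@x[f, ops]; py <- rec@y[f, ops]
          abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)) / 2 / ppc^2
        })
      expect_equal(unname(fm@values[f, i]), unname(expected),
                   tolerance = 1e-10,
                   label = paste(sp$name[i], "frame", f))
    }
  }
})

test_that("angles are signed, wrapped to (-pi, pi], with known cases", {
  ## synthetic 1-frame recording with hand-placed points
  pts <- c("nose", "neck", "bodycentre", "tailbase")
  x <- matrix(c(2, 1, 1, 0), 2, 4, byrow = TRUE,
              dimnames = list(NULL, pts))
  x <- rbind(x, x)  # a few frames
  y <- matrix(0, 4, 4, dimnames = list(NULL, pts))
  x <- cbind(x, corner1 = 0, corner2 = 10, corner3 = 10, corner4 = 0)
  y <- cbind(y, corner1 = 0, corner2 = 0, corner3 = 10, corner4 = 10)
  x[, pts] <- matrix(c(2, 1, 1, 0), 4, 4, byrow = TRUE)
  rec <- TrackingRecording(x, y, fps = 25)
  rec@arena <- inferArena(rec, paste0("corner", 1:4), 100)
  rec <- preprocessRecording(rec)
  reg <- featureRegistry(data.frame(
    name = c("parallel", "antiparallel"),
    kind = "pairpair_angle",
    operands = c("neck,nose,tailbase,bodycentre",     # both point +x
                 "neck,nose,bodycentre,tailbase")))   # opposed
  fm <- extractFeatures(rec, reg)
  expect_equal(unname(fm@values[1, "parallel"]), 0)
  expect_equal(unname(fm@values[1, "antiparallel"]), pi)
})

test_that("normalization applies the per-kind rules", {
  lab <- simulateLabels(uniformKernel(3), nFrames = 80, seed = 9)
  rec <- preprocessRecording(withArena(simulatePose(lab, seed = 10)))
  reg <- defaultFeatureRegistry()
  fm <- extractFeatures(rec, reg)
  nf <- normalizeFeatures(fm, reg)
  sp <- reg@specs
  for (i in seq_len(nrow(sp))) {
    v <- nf@values[, i]
    switch(sp$kind[i],
      pair_distance = , polygon_area = {
        expect_equal(mean(v), 0, tolerance = 1e-9)
        expect_equal(sd(v), 1, tolerance = 1e-9)
      },
      pairpair_angle = expect_equal(v, fm@values[, i]),
      border_proximity = expect_equal(v, fm@values[, i] * 0.1),
      point_acceleration = expect_equal(v, fm@values[, i] * 4))
  }
  ## re-normalizing is a no-op for angle and already-z-scored columns
  nf2 <- suppressWarnings(normalizeFeatures(nf, reg))
  zcols <- sp$kind %in% c("pair_distance", "polygon_area", "pairpair_angle")
  expect_equal(nf2@values[, zcols], nf@values[, zcols], tolerance = 1e-9)
})

test_that("zero-variance z-score columns become 0 with a warning", {
  reg <- featureRegistry(data.frame(
    name = "d", kind = "pair_distance", operands = "nose,neck"))
  fm <- new("FeatureMatrix", recordingId = "r",
            values = matrix(3, 10, 1, dimnames = list(NULL, "d")))
  expect_warning(nf <- normalizeFeatures(fm, reg), "zero-variance")
  expect_equal(nf@values[, 1], rep(0, 10), ignore_attr = TRUE)
})

test_that("temporal expansion geometry: width, offsets, edge policy", {
  set.seed(21)
  mkfm <- function(n, m) new("FeatureMatrix", recordingId = "r",
    values = matrix(rnorm(n * m), n, m,
                    dimnames = list(NULL, paste0("f", seq_len(m)))))
  fm <- mkfm(100, 41)
  tf <- temporalExpand(fm, 15)
  expect_equal(ncol(tf@values), 1271)
  expect_equal(nrow(tf@values), 100 - 30)
  expect_equal(tf@frameOffset, 15L)

  ## offset-0 block equals the input rows, exactly
  zeroBlock <- tf@values[, 15 * 41 + seq_len(41)]
  expect_identical(unname(zeroBlock), unname(fm@values[16:85, ]))

  ## h = 0 is the identity
  tf0 <- temporalExpand(fm, 0)
  expect_equal(unname(tf0@values), unname(fm@values))
  expect_equal(tf0@frameOffset, 0L)

  ## constant-in-time features tile the m-vector t times
  cfm <- new("FeatureMatrix", recordingId = "r",
             values = matrix(rep(c(1, 2, 3), each = 50), 50, 3,
                             dimnames = list(NULL, c("a", "b", "c"))))
  tfc <- temporalExpand(cfm, 4)
  expect_equal(unname(tfc@values[1, ]), rep(c(1, 2, 3), 9))

  ## column count = m * (2h + 1) over random small m, h
  for (rep in 1:20) {
    m <- sample(1:6, 1); h <- sample(0:5, 1); n <- 2 * h + sample(1:10, 1)
    tfr <- temporalExpand(mkfm(n, m), h)
    expect_equal(ncol(tfr@values), m * (2 * h + 1))
    expect_equal(nrow(tfr@values), n - 2 * h)
  }
  expect_error(temporalExpand(mkfm(10, 2), 5), "too short")
})
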