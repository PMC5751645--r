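sigOf <- function(m) {
  colnames(m) <- cellNames()
  m
}

test_that("detection features are windowed per-cell min/max pairs", {
  # constant signals give [v, v] for every cell
  sig <- sigOf(matrix(2.5, 30, 10))
  f <- extractDetectionFeature(sig, 10, tau = 8)
  expect_length(f, 20)
  expect_true(all(f == 2.5))

  # a ramp on cell 0 with the window covering the whole signal
  sig2 <- sigOf(cbind(0:4, matrix(0, 5, 9)))
  f2 <- extractDetectionFeature(sig2, 2, tau = 4)
  expect_equal(unname(f2[1:2]), c(0, 4))

  # full left clamp at t = 0 uses [0, floor(tau/2)] only
  sig3 <- sigOf(cbind(c(5, 1, 9, 100, 100), matrix(0, 5, 9)))
  f3 <- extractDetectionFeature(sig3, 0, tau = 4)
  expect_equal(unname(f3[1:2]), c(1, 9))

  # the all-frames matrix agrees with the per-frame extractor
  set.seed(3)
  sig4 <- sigOf(matrix(runif(300), 30, 10))
  F <- detectionFeatures(sig4, tau = 8)
  expect_identical(nrow(F), 30L)
  for (t in c(0, 7, 29))
    expect_identical(F[t + 1, ], extractDetectionFeature(sig4, t, tau = 8))
})

test_that("frame labeling opens a strict half-width window per apex", {
  lab <- labelFrames(300, 100, tau = 65, delta = 0.25)
  expect_identical(which(lab) - 1L, 84:116)   # |t - 100| < 16.25
  expect_true(all(!labelFrames(50, integer(0), 65)))
  # overlapping windows union without double counting
  lab2 <- labelFrames(300, c(100, 110), tau = 65, delta = 0.25)
  expect_identical(which(lab2) - 1L, 84:126)
})

test_that("training-set balancing subsamples non-ME frames by seed", {
  set.seed(1)
  X <- matrix(rnorm(550 * 20), 550, 20)
  y <- c(rep(TRUE, 50), rep(FALSE, 500))
  b1 <- balanceTrainingSet(X, y, seed = 9)
  expect_length(b1$labels, 100)
  expect_identical(sum(b1$labels), 50L)
  b2 <- balanceTrainingSet(X, y, seed = 9)
  expect_identical(b1$features, b2$features)
  expect_false(identical(b1$features,
                         balanceTrainingSet(X, y, seed = 10)$features))
  # degenerate branch: fewer non-ME than ME keeps everything, with warning
  y3 <- c(rep(TRUE, 50), rep(FALSE, 30))
  expect_warning(b3 <- balanceTrainingSet(X[1:80, ], y3, seed = 1),
                 "fewer non-ME")
  expect_length(b3$labels, 80)
})

test_that("the boosted spotter separates, is deterministic, and rejects
           single-class input", {
  set.seed(21)
  X <- rbind(matrix(rnorm(200 * 20, 0), 200, 20),
             matrix(rnorm(200 * 20, 4), 200, 20))
  y <- rep(c(FALSE, TRUE), each = 200)
  m <- trainSpotter(X, y, seed = 1)
  expect_s4_class(m, "MEDetector")
  expect_lte(length(m@trees), 35L)
  pred <- mexpress:::ensembleScore(m, X) > 0
  expect_identical(mean(pred == y), 1)      # linearly separable toy data

  # retraining gives identical predictions on a probe set
  probe <- matrix(rnorm(50 * 20, 2), 50, 20)
  m2 <- trainSpotter(X, y, seed = 1)
  expect_identical(mexpress:::ensembleScore(m, probe),
                   mexpress:::ensembleScore(m2, probe))

  expect_error(trainSpotter(X, rep(TRUE, 400)), "both classes")
})

test_that("shuffled labels give chance-level held-out accuracy", {
  set.seed(77)
  X <- matrix(rnorm(800 * 20), 800, 20)
  y <- sample(rep(c(TRUE, FALSE), 400))
  m <- trainSpotter(X[1:400, ], y[1:400])
  acc <- mean((mexpress:::ensembleScore(m, X[401:800, ]) > 0) == y[401:800])
  expect_gte(acc, 0.35); expect_lte(acc, 0.65)
})

test_that("per-frame prediction forces the zero-filled prefix to non-ME", {
  set.seed(4)
  X <- rbind(matrix(rnorm(100 * 20, 0), 100, 20),
             matrix(rnorm(100 * 20, 3), 100, 20))
  y <- rep(c(FALSE, TRUE), each = 100)
  m <- trainSpotter(X, y)
  sig <- new("CellSignal", signals = sigOf(matrix(0, 50, 10)), tau = 20L)
  lab <- predictFrames(m, sig)
  expect_length(lab, 50)
  expect_true(all(!lab[1:10]))                # prefix ceiling(tau/2)
  expect_identical(length(unique(lab[11:50])), 1L)  # constant input
})

test_that("interval post-processing merges, filters and takes midpoints", {
  expect_identical(nrow(postprocessIntervals(rep(FALSE, 50), 4, 10)), 0L)

  # hand-traced merge: runs (10,20) and (25,40), gap 5 < 130 -> (10,40),
  # length 30 >= 16, apex floor((10+40)/2) = 25
  lab <- rep(FALSE, 60)
  lab[(10:20) + 1] <- TRUE; lab[(25:40) + 1] <- TRUE
  out <- postprocessIntervals(lab, minMicroSz = 16, maxDist = 130)
  expect_identical(out, data.frame(start = 10L, end = 40L, apex = 25L))

  # a short lone run is dropped
  lab2 <- rep(FALSE, 30); lab2[(5:10) + 1] <- TRUE
  expect_identical(nrow(postprocessIntervals(lab2, 16, 10)), 0L)

  # printed (length-difference) merge rule stays available
  out2 <- postprocessIntervals(lab, minMicroSz = 5, maxDist = 2,
                               mergeRule = "printed")
  expect_s3_class(out2, "data.frame")
})

test_that("post-processing equals the exhaustive merge oracle on random
           label series", {
  set.seed(2024)
  for (k in 1:300) {
    n <- sample(20:200, 1)
    lab <- runif(n) < runif(1, 0.05, 0.6)
    minSz <- sample(0:20, 1)
    maxD <- sample(1:50, 1)
    got <- postprocessIntervals(lab, minSz, maxD)
    want <- brutePostprocess(lab, minSz, maxD)
    expect_identical(got, want)
    # structural invariants of the output
    if (nrow(got) > 1) {
      expect_true(all(diff(got$start) > 0))
      expect_true(all(got$start[-1] > got$end[-nrow(got)]))
    }
    expect_true(all(got$end - got$start >= minSz))
    expect_true(all(got$start <= got$apex & got$apex <= got$end))
  }
})

test_that("increasing the merge distance never adds merged intervals", {
  # monotonicity holds for the merge stage itself (checked with the size
  # filter disabled); the filter can turn 0 survivors into 1 when longer
  # merged intervals start to clear the minimum size
  set.seed(8)
  for (k in 1:40) {
    lab <- runif(150) < 0.3
    counts <- vapply(c(1, 3, 8, 20, 60), function(md)
      nrow(postprocessIntervals(lab, 0, md)), integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("apex scoring applies the quarter-duration threshold with
           one-to-one matching", {
  # exact hit
  s <- scoreSpotting(100, 100, tau = 65)
  expect_identical(s$TP, 1L); expect_identical(s$FP, 0L)

  # tau = 65, delta = 0.25: 16 <= 16.25 is TP, 17 is FP
  expect_identical(scoreSpotting(116, 100, 65)$TP, 1L)
  expect_identical(scoreSpotting(117, 100, 65)$TP, 0L)
  expect_identical(scoreSpotting(117, 100, 65)$FP, 1L)

  # two detections near one truth apex: one TP, one FP
  s2 <- scoreSpotting(c(98, 103), 100, 65)
  expect_identical(s2$TP, 1L); expect_identical(s2$FP, 1L)
  expect_identical(s2$detMatched[1], 1L)    # nearest-first
  expect_true(is.na(s2$detMatched[2]))

  # rates normalize by the number of ground-truth micro-expressions
  s3 <- scoreSpotting(c(10, 300), c(12, 100, 200), tau = 65)
  expect_equal(s3$detectionRate, 1 / 3)
  expect_equal(s3$falsePositiveRate, 1 / 3)
})

test_that("scoring ground truth against itself is perfect", {
  set.seed(5)
  for (k in 1:10) {
    # apexes far enough apart that their label runs stay unmerged
    apexes <- sort(sample(seq(50, 550, by = 170), sample(1:3, 1)))
    lab <- labelFrames(600, apexes, tau = 37)
    ints <- postprocessIntervals(lab, 9, 74)
    s <- scoreSpotting(ints, apexes, tau = 37)
    expect_identical(s$FP, 0L)
    expect_equal(s$detectionRate, 1)
  }
})
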