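test_that("motion magnitude evaluates the normalized frame ratio exactly", {
  p <- descriptorParams(tau = 4, eps = 1)

  # constant sequence: both differences vanish, MM is exactly 1
  seq <- FrameSequence(array(37, c(5, 5, 6)), fps = 100)
  expect_true(all(motionMagnitude(seq, 4, p) == 1))

  # single-pixel hand computations: (|10-4|+1)/(|10-10|+1) = 7
  s1 <- FrameSequence(lapply(c(4, 10, 10), function(v) matrix(v, 1, 1)))
  expect_equal(motionMagnitude(s1, 2, p)[1, 1], 7)
  # (|4-4|+1)/(|4-9|+1) = 1/6
  s2 <- FrameSequence(lapply(c(4, 9, 4), function(v) matrix(v, 1, 1)))
  expect_equal(motionMagnitude(s2, 2, p)[1, 1], 1 / 6)

  # reference indices clamp to frame 0
  expect_true(all(motionMagnitude(s1, 0, p) == 1))
})

test_that("motion magnitude is positive and shift-invariant", {
  p <- descriptorParams(tau = 6, eps = 2)
  set.seed(11)
  fr <- array(sample(0:255, 8 * 8 * 8, replace = TRUE), c(8, 8, 8))
  seq <- FrameSequence(fr, fps = 100)
  seqShift <- FrameSequence(fr + 17L, fps = 100)
  for (t in c(0, 3, 7)) {
    mm <- motionMagnitude(seq, t, p)
    expect_true(all(mm > 0))
    # adding a constant to every frame leaves all differences unchanged
    expect_identical(mm, motionMagnitude(seqShift, t, p))
  }
})

test_that("cell mean matches direct averages and the brute-force oracle", {
  # 2x2 block with values 1,3,5,7 averages to 4
  mm <- matrix(0, 8, 8)
  mm[2:3, 2:3] <- matrix(c(1, 5, 3, 7), 2, 2)
  g <- testGrid(center = c(1.5, 1.5), side = 2)
  expect_equal(cellMean(mm, g, 1), 4)

  # constant image: mean is the constant for any cell, clipped or not
  mmc <- matrix(2.5, 10, 10)
  gEdge <- testGrid(center = c(0, 5), side = 6)
  expect_equal(cellMean(mmc, gEdge, 1), 2.5)

  # random instances against the explicit double loop: exact on the
  # integer intensity domain, 1e-12 on continuous values (R's mean()
  # accumulates in extended precision)
  set.seed(7)
  for (k in 1:25) {
    mmI <- matrix(sample(0:255, 256, replace = TRUE) + 0, 16, 16)
    g <- testGrid(center = runif(2, 2, 13), side = runif(1, 2, 8))
    px <- cellPixels(g, 1, c(16, 16))
    expect_identical(cellMean(mmI, g, 1),
                     bruteCellMean(mmI, px$rows, px$cols))
    mmC <- matrix(runif(256, 0.1, 9), 16, 16)
    expect_equal(cellMean(mmC, g, 1), bruteCellMean(mmC, px$rows, px$cols),
                 tolerance = 1e-12)
  }
})

test_that("weighted centroid is a mass-weighted mean inside the cell", {
  # uniform mass: geometric center of the pixel block
  mm <- matrix(1, 21, 21)
  g <- testGrid(center = c(10, 10), side = 7)
  expect_equal(weightedCentroid(mm, g, 1), c(cx = 10, cy = 10))

  # nearly all mass at one pixel
  mm2 <- matrix(1e-6, 21, 21)
  mm2[9, 13] <- 1e6   # pixel (x = 12, y = 8)
  expect_equal(weightedCentroid(mm2, g, 1), c(cx = 12, cy = 8),
               tolerance = 1e-3)

  # two equal masses average their positions
  g9 <- testGrid(center = c(10, 10), side = 9)
  mm3 <- matrix(1e-9, 21, 21)
  mm3[11, 11] <- 5; mm3[11, 15] <- 5     # (10,10) and (14,10)
  expect_equal(weightedCentroid(mm3, g9, 1), c(cx = 12, cy = 10),
               tolerance = 1e-5)

  # random instances: equality with the loop oracle, centroid in the bbox
  set.seed(13)
  for (k in 1:25) {
    mm <- matrix(runif(256, 0.05, 4), 16, 16)
    g <- testGrid(center = runif(2, 1, 14), side = runif(1, 2, 9))
    px <- cellPixels(g, 1, c(16, 16))
    got <- weightedCentroid(mm, g, 1)
    expect_equal(unname(got), bruteCentroid(mm, px$rows, px$cols),
                 tolerance = 1e-12)
    expect_gte(got[["cx"]], min(px$x)); expect_lte(got[["cx"]], max(px$x))
    expect_gte(got[["cy"]], min(px$y)); expect_lte(got[["cy"]], max(px$y))
  }
})

test_that("window resampling rounds to frames and keeps the endpoints", {
  expect_identical(resampleWindow(0, 10, 11), 0:10)
  expect_identical(resampleWindow(0, 36, 11),
                   c(0L, 4L, 7L, 11L, 14L, 18L, 22L, 25L, 29L, 32L, 36L))
  expect_identical(resampleWindow(5, 5, 3), c(5L, 5L, 5L))
  # n = window length: a permutation-free enumeration of every index
  for (k in 1:10) {
    s <- sample(0:50, 1); e <- s + sample(1:40, 1)
    expect_identical(resampleWindow(s, e, e - s + 1), s:e)
  }
  expect_error(resampleWindow(4, 3, 5), "start")
})

test_that("per-cell signals zero the undefined prefix and track events", {
  p <- descriptorParams(tau = 20, eps = 3)
  g <- testGrid(center = c(10, 10), side = 7)

  # constant sequence: 0 for t < ceiling(tau/2), 1 afterwards
  seq <- FrameSequence(array(100, c(24, 24, 40)), fps = 100)
  sig <- signalMatrix(computeCellSignals(seq, g, p))
  expect_identical(nrow(sig), 40L)
  expect_true(all(sig[1:10, ] == 0))
  expect_true(all(sig[11:40, ] == 1))

  # blink-like brightening of the first cell over [a, a + tau/2] (cosine
  # ramp to a plateau) peaks the signal at a + tau/2
  p1 <- descriptorParams(tau = 20, eps = 1)
  a <- 14L; h <- 10L
  fr <- array(100, c(24, 24, 60))
  px <- cellPixels(g, 1, c(24, 24))
  for (t in 0:59) {
    amp <- 30 * 0.5 * (1 - cos(pi * min(1, max(0, (t - a) / h))))
    fr[px$rows, px$cols, t + 1] <- 100 + amp
  }
  sig2 <- signalMatrix(computeCellSignals(FrameSequence(fr, 100), g, p1))
  peak <- which.max(sig2[, 1]) - 1L
  expect_lte(abs(peak - (a + h)), 2)
  # all other cells stay flat: under 10% of the peak excess
  excess <- max(sig2[, 1]) - 1
  expect_lt(max(abs(sig2[11:60, 2:10] - 1)), 0.1 * excess)
})

test_that("displacement features measure localized motion only", {
  p <- descriptorParams(tau = 20, eps = 3, nResample = 11)

  # constant sequence: identical centroids everywhere
  g <- testGrid(center = c(20, 20), side = 11, parkAt = c(45, 15))
  seq <- FrameSequence(array(60, c(60, 60, 60)), fps = 100)
  d0 <- displacementFeatures(seq, g, 30, p)
  expect_identical(dim(d0), c(10L, 10L, 2L))
  expect_true(all(d0 == 0))

  # bright blob inside the cell translated by (+4, 0) px between the
  # window start F_0 and the apex, static elsewhere; measured against the
  # window-start baseline so late window frames keep referencing F_0
  g2 <- testGrid(center = c(20, 20), side = 9, parkAt = c(45, 15))
  apex <- 30L; w0 <- apex - 10L
  xs <- 0:59
  blob <- function(cx) 200 * exp(-outer((xs - 20)^2, (xs - cx)^2, "+") /
                                   (2 * 1.5^2))
  fr <- array(60, c(60, 60, 60))
  for (t in 0:59) {
    shift <- 4 * min(1, max(0, (t - w0) / (apex - w0)))
    fr[, , t + 1] <- 60 + blob(23 + shift)
  }
  d <- displacementFeatures(FrameSequence(fr, 100), g2, apex, p,
                            baseline = "windowStart")
  final <- d[1, 10, ]
  expect_gte(final[["dx"]], 2); expect_lte(final[["dx"]], 6)
  expect_lt(abs(final[["dy"]]), 1)
  other <- sqrt(d[2:10, , 1]^2 + d[2:10, , 2]^2)
  expect_lt(max(other), 0.5)
})

test_that("the window-start baseline variant is exposed", {
  p <- descriptorParams(tau = 20, eps = 3, nResample = 5)
  set.seed(5)
  fr <- array(runif(40 * 40 * 50, 0, 255), c(40, 40, 50))
  seq <- FrameSequence(fr, 100)
  g <- testGrid(center = c(20, 20), side = 9)
  d1 <- displacementFeatures(seq, g, 25, p, baseline = "eq1")
  d2 <- displacementFeatures(seq, g, 25, p, baseline = "windowStart")
  expect_false(isTRUE(all.equal(d1, d2)))
  expect_identical(dim(d2), c(10L, 4L, 2L))
})
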