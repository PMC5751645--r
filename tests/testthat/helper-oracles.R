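# Independent oracles and small fixture builders shared by the tests.
# Oracles are written naively (explicit loops, separate numerics) so they
# stay independent of the implementation paths they check.

# brute-force mean of a matrix over an explicit pixel list
bruteCellMean <- function(mm, rows, cols) {
  tot <- 0; n <- 0
  for (cc in cols) for (r in rows) {   # column-major, like R's mean()
    tot <- tot + mm[r, cc]
    n <- n + 1
  }
  tot / n
}

# brute-force intensity-weighted centroid over an explicit pixel list,
# 0-based pixel-center coordinates
bruteCentroid <- function(mm, rows, cols) {
  sx <- 0; sy <- 0; sw <- 0
  for (r in rows) for (cc in cols) {
    w <- mm[r, cc]
    sx <- sx + (cc - 1) * w
    sy <- sy + (r - 1) * w
    sw <- sw + w
  }
  c(sx / sw, sy / sw)
}

# exhaustive merge-until-fixpoint interval post-processing oracle:
# scan sorted runs, merge the first adjacent pair meeting the gap rule,
# restart, until stable; then drop short intervals and set apexes.
brutePostprocess <- function(labels, minMicroSz, maxDist) {
  runs <- list()
  inRun <- FALSE
  for (t in seq_along(labels)) {
    if (labels[t] && !inRun) { s <- t; inRun <- TRUE }
    if (!labels[t] && inRun) {
      runs[[length(runs) + 1]] <- c(s - 1L, t - 2L); inRun <- FALSE
    }
  }
  if (inRun) runs[[length(runs) + 1]] <- c(s - 1L, length(labels) - 1L)
  changed <- TRUE
  while (changed && length(runs) > 1) {
    changed <- FALSE
    for (i in 2:length(runs)) {
      if (runs[[i]][1] - runs[[i - 1]][2] < maxDist) {
        runs[[i - 1]] <- c(runs[[i - 1]][1], runs[[i]][2])
        runs[[i]] <- NULL
        changed <- TRUE
        break
      }
    }
  }
  keep <- Filter(function(r) (r[2] - r[1]) >= minMicroSz, runs)
  data.frame(
    start = vapply(keep, `[`, integer(1), 1),
    end = vapply(keep, `[`, integer(1), 2),
    apex = vapply(keep, function(r) (r[1] + r[2]) %/% 2L, integer(1)))
}

# bivariate normal log-density via eigendecomposition (independent of the
# Cholesky path used by the package)
eigenLogpdf <- function(x, mu, sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  z <- t(e$vectors) %*% (x - mu)
  -log(2 * pi) - 0.5 * sum(log(e$values)) - 0.5 * sum(z^2 / e$values)
}

# argmax-class oracle: enumerate classes, summing eigen-based log-densities
bruteClassify <- function(feature, model) {
  best <- NULL; bestScore <- -Inf
  for (e in model@classes) {
    s <- 0
    for (ci in 1:10) {
      P <- matrix(feature[ci, , , drop = FALSE], ncol = 2)
      for (r in seq_len(nrow(P)))
        s <- s + eigenLogpdf(P[r, ], model@means[[e]][ci, ],
                             model@covs[[e]][[ci]])
    }
    if (s > bestScore) { bestScore <- s; best <- e }
  }
  best
}

# random SPD 2x2 matrix
randomSPD <- function() {
  A <- matrix(rnorm(4), 2, 2)
  A %*% t(A) + 0.2 * diag(2)
}

# a grid whose first cell covers an exact pixel block: odd integer side and
# integer center make the block symmetric about the center (no half-pixel
# offset), the rest of the cells are parked far away inside a large frame
testGrid <- function(center, side, parkAt = c(3, 3)) {
  centers <- matrix(rep(parkAt, each = 10), 10, 2)
  centers[1, ] <- center
  FacialCellGrid(centers, side)
}

# random expression model over all three classes
randomModel <- function() {
  classes <- expressionClasses()
  means <- list(); covs <- list()
  for (e in classes) {
    means[[e]] <- matrix(rnorm(20, sd = 2), 10, 2,
                         dimnames = list(cellNames(), c("dx", "dy")))
    covs[[e]] <- lapply(seq_len(10), function(i) randomSPD())
    names(covs[[e]]) <- cellNames()
  }
  new("ExpressionModel", classes = classes, means = means, covs = covs,
      counts = stats::setNames(rep(5L, 3), classes),
      pairCounts = stats::setNames(rep(50L, 3), classes),
      cellOrder = cellNames(), nResample = 11L, covFloor = 1e-6,
      version = "1")
}

# random displacement feature array
randomFeature <- function(n = 11) {
  array(rnorm(10 * (n - 1) * 2, sd = 2), c(10, n - 1, 2),
        dimnames = list(cellNames(), NULL, c("dx", "dy")))
}

# train a spotter on every sequence of a dataset (no held-out subject)
trainTinySpotter <- function(ds, cfg = pipelineConfig()) {
  X <- NULL; y <- NULL
  for (s in ds$sequences) {
    grid <- defineCells(s$landmarks)
    sig <- computeCellSignals(s$frames, grid,
                              descriptorParams(cfg$tau, cfg$eps,
                                               cfg$nResample, cfg$delta))
    ann <- ds$annotations[ds$annotations$sequence_id == s$sequenceId, ]
    X <- rbind(X, detectionFeatures(sig, cfg$tau))
    y <- c(y, labelFrames(nFrames(s$frames), ann$apex, cfg$tau, cfg$delta))
  }
  bal <- balanceTrainingSet(X, y, seed = 1)
  trainSpotter(bal$features, bal$labels, cfg$nEstimators, cfg$treeDepth)
}

# fit a recognizer on every annotated event of a dataset
trainTinyRecognizer <- function(ds, cfg = pipelineConfig()) {
  dp <- descriptorParams(cfg$tau, cfg$eps, cfg$nResample, cfg$delta)
  byClass <- list()
  for (s in ds$sequences) {
    grid <- defineCells(s$landmarks)
    ann <- ds$annotations[ds$annotations$sequence_id == s$sequenceId, ]
    for (k in seq_len(nrow(ann))) {
      f <- displacementFeatures(s$frames, grid, ann$apex[k], dp)
      byClass[[ann$label[k]]] <- c(byClass[[ann$label[k]]], list(f))
    }
  }
  have <- intersect(expressionClasses(), names(byClass))
  fitExpressionModels(byClass[have], classes = have)
}

# small synthetic dataset for pipeline tests
tinyDataset <- function(seed = 1, nSubjects = 4, sequencesPerSubject = 3,
                        noiseSigma = 2) {
  generateDataset(
    nSubjects = nSubjects, sequencesPerSubject = sequencesPerSubject,
    params = sceneParams(imageSize = 80, seqLen = 240,
                         noiseSigma = noiseSigma),
    seed = seed, magnitudeRange = c(2.5, 4),
    eventCountProbs = c(0.1, 0.9, 0))
}
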