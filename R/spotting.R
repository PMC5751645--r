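## Micro-expression spotting: windowed min/max features over the per-cell
## motion signals, a discrete AdaBoost frame classifier, interval
## post-processing with apex extraction, and apex-based scoring.

#' Windowed min/max detection feature for one frame
#'
#' For frame \code{t}, a window of size \code{tau} is centered on the frame
#' (clamped to the sequence) and, for each of the 10 cells in canonical
#' order, the minimum and maximum of the per-cell motion signal over the
#' window are extracted, giving a 20-dimensional vector
#' \code{[min(w_c0), max(w_c0), ..., min(w_c9), max(w_c9)]}.
#'
#' @param signals a \linkS4class{CellSignal} or its T x 10 matrix.
#' @param t 0-based frame index.
#' @param tau window size in frames (defaults to the tau stored in
#'   \code{signals}).
#' @return Named numeric vector of length 20.
#' @export
extractDetectionFeature <- function(signals, t, tau = NULL) {
  sig <- if (is(signals, "CellSignal")) signals@signals else signals
  if (is.null(tau)) {
    if (!is(signals, "CellSignal")) stop("tau is required for a raw matrix")
    tau <- signals@tau
  }
  T <- nrow(sig)
  t <- as.integer(t)
  if (t < 0L || t >= T) stop("frame index out of range")
  h <- as.integer(tau) %/% 2L
  w <- (max(0L, t - h):min(T - 1L, t + h)) + 1L
  f <- as.vector(rbind(apply(sig[w, , drop = FALSE], 2, min),
                       apply(sig[w, , drop = FALSE], 2, max)))
  names(f) <- as.vector(rbind(paste0(colnames(sig), "_min"),
                              paste0(colnames(sig), "_max")))
  f
}

#' Detection features for every frame of a sequence
#'
#' @inheritParams extractDetectionFeature
#' @return T x 20 numeric matrix, one row per frame.
#' @export
detectionFeatures <- function(signals, tau = NULL) {
  sig <- if (is(signals, "CellSignal")) signals@signals else signals
  if (is.null(tau)) {
    if (!is(signals, "CellSignal")) stop("tau is required for a raw matrix")
    tau <- signals@tau
  }
  T <- nrow(sig)
  h <- as.integer(tau) %/% 2L
  out <- matrix(NA_real_, T, 20L)
  for (ci in 1:10) {
    s <- sig[, ci]
    mins <- maxs <- numeric(T)
    for (t in 0:(T - 1L)) {
      w <- (max(0L, t - h):min(T - 1L, t + h)) + 1L
      mins[t + 1L] <- min(s[w])
      maxs[t + 1L] <- max(s[w])
    }
    out[, 2L * ci - 1L] <- mins
    out[, 2L * ci] <- maxs
  }
  colnames(out) <- as.vector(rbind(paste0(colnames(sig), "_min"),
                                   paste0(colnames(sig), "_max")))
  out
}

#' Label frames as micro-expression / non-micro-expression from apexes
#'
#' A frame \code{t} is a micro-expression frame iff
#' \code{|t - apex| < delta * tau} for some ground-truth apex (strict
#' inequality on the real-valued threshold); all other frames, neutral or
#' macro-expression, are non-ME.
#'
#' @param seqLen sequence length in frames.
#' @param apexes 0-based ground-truth apex indices (possibly empty).
#' @param tau average micro-expression duration in frames.
#' @param delta labeling half-width factor.
#' @return Logical vector of length \code{seqLen}; TRUE = ME frame.
#' @export
#' @examples
#' which(labelFrames(300, 100, tau = 65, delta = 0.25)) - 1  # 84..116
labelFrames <- function(seqLen, apexes, tau, delta = 0.25) {
  seqLen <- as.integer(seqLen)
  lab <- rep(FALSE, seqLen)
  if (length(apexes)) {
    stopifnot(all(apexes >= 0 & apexes < seqLen))
    t <- 0:(seqLen - 1L)
    for (a in apexes) lab <- lab | (abs(t - a) < delta * tau)
  }
  lab
}

#' Balance a frame-level training set
#'
#' Keeps every micro-expression frame and subsamples the (far more numerous)
#' non-ME frames without replacement down to the ME count; the combined set
#' is then shuffled. Fully deterministic given \code{seed}. If fewer non-ME
#' than ME frames exist, all are kept with a warning.
#'
#' @param features feature matrix, one row per frame.
#' @param labels logical vector (TRUE = ME), same length as rows.
#' @param seed RNG seed.
#' @return \code{list(features =, labels =)}.
#' @export
balanceTrainingSet <- function(features, labels, seed = 1) {
  stopifnot(nrow(features) == length(labels))
  me <- which(labels)
  non <- which(!labels)
  if (length(me) == 0L) stop("no micro-expression frames to train on")
  withSeed(seed, {
    keep <- if (length(non) < length(me)) {
      warning("fewer non-ME than ME frames; keeping all ",
              length(non), " non-ME frames")
      non
    } else {
      sample(non, length(me))
    }
    idx <- sample(c(me, keep))
  })
  list(features = features[idx, , drop = FALSE], labels = labels[idx])
}

.featureFrame <- function(features) {
  df <- as.data.frame(features)
  names(df) <- sprintf("f%02d", seq_len(ncol(features)))
  df
}

#' Train the boosted decision-tree frame spotter
#'
#' Discrete AdaBoost: depth-limited decision trees (stumps by default) are
#' fit to reweighted training sets; after each round the misclassified
#' frames are upweighted, and the trees vote with stage weights
#' \code{0.5 * log((1 - err) / err)}. Training is deterministic given the
#' input (the trees use no randomness); \code{seed} is recorded for
#' provenance of the balancing step.
#'
#' @param features numeric matrix with 20 columns (one row per frame).
#' @param labels logical vector, TRUE = micro-expression frame.
#' @param nEstimators maximum number of weak learners.
#' @param depth weak-learner tree depth (1 = decision stumps).
#' @param seed seed recorded in the model.
#' @return An \linkS4class{MEDetector}.
#' @export
trainSpotter <- function(features, labels, nEstimators = 35, depth = 1,
                         seed = 1) {
  stopifnot(ncol(features) == 20L, nrow(features) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("training set must contain both classes")
  df <- .featureFrame(features)
  y <- factor(ifelse(labels, "ME", "nonME"), levels = c("nonME", "ME"))
  n <- nrow(df)
  w <- rep(1 / n, n)
  ctrl <- rpart::rpart.control(maxdepth = depth, minsplit = 2, minbucket = 1,
                               cp = 0, xval = 0, maxcompete = 0,
                               maxsurrogate = 0, usesurrogate = 0)
  trees <- list()
  alphas <- numeric(0)
  dat <- cbind(df, .y = y)
  for (m in seq_len(nEstimators)) {
    fit <- rpart::rpart(.y ~ ., data = dat, weights = w, method = "class",
                        control = ctrl)
    pred <- predict(fit, df, type = "class")
    mis <- pred != y
    err <- sum(w[mis])
    if (err >= 0.5 && length(trees) > 0L) break
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    trees[[length(trees) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    if (!any(mis)) break     # perfect weak learner: ensemble is done
    w <- w * exp(ifelse(mis, alpha, -alpha))
    w <- w / sum(w)
  }
  new("MEDetector", trees = trees, alphas = alphas,
      cellOrder = .CELL_NAMES, depth = as.integer(depth),
      seed = as.integer(seed), version = "1")
}

# Signed ensemble vote (positive = ME) for a feature matrix.
ensembleScore <- function(model, features) {
  df <- .featureFrame(features)
  score <- numeric(nrow(df))
  for (m in seq_along(model@trees)) {
    pred <- predict(model@trees[[m]], df, type = "class")
    score <- score + model@alphas[m] * ifelse(pred == "ME", 1, -1)
  }
  score
}

#' Predict a per-frame micro-expression label series
#'
#' Applies the boosted spotter to the windowed min/max feature of every
#' frame. The sign of the weighted ensemble vote decides the label. Prefix
#' frames \code{t < ceiling(tau/2)}, where the signals are zero-filled, are
#' forced to non-ME.
#'
#' @param model an \linkS4class{MEDetector}.
#' @param signals a \linkS4class{CellSignal}.
#' @param tau window size (defaults to the tau stored in \code{signals}).
#' @return Logical vector, one entry per frame (TRUE = ME).
#' @export
predictFrames <- function(model, signals, tau = NULL) {
  stopifnot(is(model, "MEDetector"), is(signals, "CellSignal"))
  if (!identical(model@cellOrder, colnames(signals@signals)))
    stop("cell order of the model does not match the signals")
  tau <- tau %||% signals@tau
  feats <- detectionFeatures(signals, tau)
  lab <- ensembleScore(model, feats) > 0
  pre <- as.integer(ceiling(tau / 2))
  lab[seq_len(min(pre, length(lab)))] <- FALSE
  lab
}

#' Post-process raw frame labels into micro-expression intervals
#'
#' (1) maximal runs of ME-labelled frames become intervals; (2) adjacent
#' intervals are merged repeatedly until no merge applies; (3) intervals
#' shorter than \code{minMicroSz} (measured as \code{end - start}) are
#' dropped; (4) the apex of each survivor is the middle frame
#' \code{floor((start + end) / 2)}.
#'
#' The default merge condition is the gap between consecutive intervals,
#' \code{start_i - end_(i-1) < maxDist}. \code{mergeRule = "printed"} keeps
#' the alternative length-difference condition
#' \code{(len_i - len_(i-1)) < maxDist} available for fidelity experiments.
#'
#' @param labels logical per-frame label series (TRUE = ME).
#' @param minMicroSz minimum interval size in frames (typically
#'   \code{tau/4}).
#' @param maxDist maximum distance between two clusters to be merged
#'   (typically \code{2 * tau}).
#' @param mergeRule \code{"gap"} (default) or \code{"printed"}.
#' @return data.frame with 0-based columns \code{start}, \code{end},
#'   \code{apex}; zero rows if nothing survives.
#' @export
postprocessIntervals <- function(labels, minMicroSz, maxDist,
                                 mergeRule = c("gap", "printed")) {
  mergeRule <- match.arg(mergeRule)
  empty <- data.frame(start = integer(0), end = integer(0),
                      apex = integer(0))
  if (!length(labels) || !any(labels)) return(empty)
  r <- rle(as.logical(labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  I <- cbind(start = starts[r$values] - 1L, end = ends[r$values] - 1L)
  repeat {
    merged <- FALSE
    if (nrow(I) >= 2L) {
      for (i in 2:nrow(I)) {
        cond <- if (mergeRule == "gap") {
          (I[i, "start"] - I[i - 1L, "end"]) < maxDist
        } else {
          ((I[i, "end"] - I[i, "start"]) -
             (I[i - 1L, "end"] - I[i - 1L, "start"])) < maxDist
        }
        if (cond) {
          I[i - 1L, "end"] <- I[i, "end"]
          I <- I[-i, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  keep <- (I[, "end"] - I[, "start"]) >= minMicroSz
  I <- I[keep, , drop = FALSE]
  if (!nrow(I)) return(empty)
  data.frame(start = as.integer(I[, "start"]),
             end = as.integer(I[, "end"]),
             apex = as.integer((I[, "start"] + I[, "end"]) %/% 2L))
}

#' Score detected apexes against ground truth
#'
#' A detected apex is a true positive when it can be matched to an unmatched
#' ground-truth apex with \code{|apex_gt - apex_d| <= delta * tau}; matching
#' is greedy nearest-first and one-to-one, so extra detections near a truth
#' apex count as false positives. The detection rate is matched truth over
#' total truth; the false-positive rate follows the per-emotion convention:
#' false positives divided by the total number of ground-truth
#' micro-expressions.
#'
#' @param detected data.frame with an \code{apex} column (as returned by
#'   \code{\link{postprocessIntervals}}) or a numeric vector of apexes.
#' @param truth numeric vector of ground-truth apex indices.
#' @param tau average micro-expression duration in frames.
#' @param delta matching half-width factor.
#' @return list with \code{TP}, \code{FP}, \code{nTruth}, \code{nDetected},
#'   \code{detectionRate}, \code{falsePositiveRate}, \code{truthMatched}
#'   (logical per truth apex) and \code{detMatched} (index of the matched
#'   truth apex per detection, NA if unmatched).
#' @export
scoreSpotting <- function(detected, truth, tau, delta = 0.25) {
  da <- if (is.data.frame(detected)) detected$apex else as.numeric(detected)
  truth <- as.numeric(truth)
  thr <- delta * tau
  nT <- length(truth); nD <- length(da)
  truthMatched <- rep(FALSE, nT)
  detMatched <- rep(NA_integer_, nD)
  if (nT && nD) {
    pairs <- expand.grid(ti = seq_len(nT), di = seq_len(nD))
    pairs$dist <- abs(truth[pairs$ti] - da[pairs$di])
    pairs <- pairs[pairs$dist <= thr, , drop = FALSE]
    pairs <- pairs[order(pairs$dist, pairs$ti, pairs$di), , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      ti <- pairs$ti[k]; di <- pairs$di[k]
      if (!truthMatched[ti] && is.na(detMatched[di])) {
        truthMatched[ti] <- TRUE
        detMatched[di] <- ti
      }
    }
  }
  TP <- sum(!is.na(detMatched))
  FP <- nD - TP
  list(TP = TP, FP = FP, nTruth = nT, nDetected = nD,
       detectionRate = if (nT) sum(truthMatched) / nT else NA_real_,
       falsePositiveRate = if (nT) FP / nT else NA_real_,
       truthMatched = truthMatched, detMatched = detMatched)
}
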