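## Normalized frame-difference motion descriptors.
##
## The motion-magnitude image at frame t is
##   MM_t = (|f_t - f_{t - floor(tau/2)}| + 1) / (|f_t - f_{t - eps}| + 1)
## computed in real arithmetic on the 0-255 intensity scale. The numerator
## compares the potential apex frame with a potential onset frame half a
## micro-expression earlier; the denominator normalizes by a near frame so
## that sensor noise and flicker cancel out. Reference indices are clamped
## to frame 0.

#' Descriptor parameter set
#'
#' @param tau average micro-expression duration in frames (65 at 200 fps,
#'   37 at ~100 fps are typical high-speed values).
#' @param eps normalization offset in frames; over \code{eps} frames of
#'   high-speed video no facial movement is expected.
#' @param nResample number of frames a recognition window is resampled to.
#' @param delta labeling half-width factor: frames within
#'   \code{delta * tau} of an apex count as micro-expression frames.
#' @return A validated named list of class \code{descriptorParams}.
#' @export
#' @examples
#' descriptorParams(tau = 37)
descriptorParams <- function(tau = 37, eps = 3, nResample = 11,
                             delta = 0.25) {
  p <- list(tau = as.integer(tau), eps = as.integer(eps),
            nResample = as.integer(nResample), delta = as.numeric(delta))
  if (p$tau < 2L) stop("tau must be >= 2")
  if (p$eps < 1L) stop("eps must be >= 1")
  if (p$eps >= p$tau / 2) stop("eps must be < tau/2")
  if (p$nResample < 2L) stop("nResample must be >= 2")
  if (p$delta <= 0 || p$delta >= 0.5) stop("delta must be in (0, 0.5)")
  class(p) <- "descriptorParams"
  p
}

#' Motion-magnitude image at a frame
#'
#' @param seq a \linkS4class{FrameSequence} (grayscale).
#' @param t 0-based frame index.
#' @param params a \code{\link{descriptorParams}} list.
#' @return Numeric matrix of positive motion-magnitude values, same shape as
#'   a frame; exactly 1 wherever both frame differences vanish.
#' @export
motionMagnitude <- function(seq, t, params = descriptorParams()) {
  stopifnot(is(seq, "FrameSequence"))
  ft <- frameAt(seq, t)
  h <- params$tau %/% 2L
  f1 <- frameAt(seq, max(0L, t - h))
  f2 <- frameAt(seq, max(0L, t - params$eps))
  (abs(ft - f1) + 1) / (abs(ft - f2) + 1)
}

#' Mean motion magnitude within one cell
#'
#' Arithmetic mean of a motion-magnitude image over the integer pixel block
#' covered by the (clipped) cell square.
#'
#' @param mm motion-magnitude matrix.
#' @param grid a \linkS4class{FacialCellGrid}.
#' @param cell cell name or index.
#' @return Scalar mean.
#' @export
cellMean <- function(mm, grid, cell) {
  px <- cellPixels(grid, cell, dim(mm))
  mean(mm[px$rows, px$cols])
}

#' Per-cell motion-magnitude signals for a whole sequence
#'
#' Computes \code{cellMean(motionMagnitude(seq, t), cell)} for every frame
#' and cell. Frames \code{t < ceiling(tau/2)}, where the motion-magnitude
#' image is undefined, are stored as 0.
#'
#' @param seq a \linkS4class{FrameSequence}.
#' @param grid a \linkS4class{FacialCellGrid}.
#' @param params a \code{\link{descriptorParams}} list.
#' @return A \linkS4class{CellSignal}.
#' @export
computeCellSignals <- function(seq, grid, params = descriptorParams()) {
  stopifnot(is(seq, "FrameSequence"), is(grid, "FacialCellGrid"))
  T <- nFrames(seq)
  h <- params$tau %/% 2L
  pre <- as.integer(ceiling(params$tau / 2))
  sig <- matrix(0, T, 10L, dimnames = list(NULL, .CELL_NAMES))
  if (T > pre) {
    tt <- pre:(T - 1L)             # frames with a defined MM image
    d <- frameDim(seq)
    for (ci in 1:10) {
      px <- cellPixels(grid, ci, d)
      block <- seq@frames[px$rows, px$cols, , drop = FALSE]
      B <- matrix(as.double(block), nrow = length(px$rows) * length(px$cols))
      num <- abs(B[, tt + 1L, drop = FALSE] - B[, tt - h + 1L, drop = FALSE])
      den <- abs(B[, tt + 1L, drop = FALSE] -
                 B[, tt - params$eps + 1L, drop = FALSE])
      sig[tt + 1L, ci] <- colMeans((num + 1) / (den + 1))
    }
  }
  new("CellSignal", signals = sig, tau = params$tau)
}

#' Intensity-weighted centroid of a cell
#'
#' Weighted mean pixel position of the motion-magnitude image within the
#' clipped cell block; pixel coordinates are 0-based integer centers. The
#' centroid always lies inside the clipped cell bounding box because the
#' motion magnitude is strictly positive.
#'
#' @param mm motion-magnitude matrix.
#' @param grid a \linkS4class{FacialCellGrid}.
#' @param cell cell name or index.
#' @return Named numeric \code{c(cx =, cy =)}.
#' @export
weightedCentroid <- function(mm, grid, cell) {
  px <- cellPixels(grid, cell, dim(mm))
  block <- mm[px$rows, px$cols, drop = FALSE]
  tot <- sum(block)
  if (tot <= 0) stop("non-positive total mass in cell")
  c(cx = sum(colSums(block) * px$x) / tot,
    cy = sum(rowSums(block) * px$y) / tot)
}

#' Resample a frame window to a fixed number of indices
#'
#' Evenly spaced indices over \code{[start, end]} rounded half-up to the
#' nearest frame; the first index is \code{start}, the last is \code{end},
#' and duplicates appear when \code{n} exceeds the window length. Makes the
#' recognition features invariant to the capture frame rate.
#'
#' @param start,end 0-based inclusive window bounds, \code{end >= start}.
#' @param n number of indices, \code{n >= 2}.
#' @return Integer vector of length \code{n}, non-decreasing.
#' @export
#' @examples
#' resampleWindow(0, 36, 11)
resampleWindow <- function(start, end, n) {
  start <- as.integer(start); end <- as.integer(end); n <- as.integer(n)
  if (end < start) stop("end must be >= start")
  if (n < 2L) stop("n must be >= 2")
  as.integer(start + roundHalfUp((0:(n - 1L)) * (end - start) / (n - 1L)))
}

#' Weighted-centroid displacement features around an apex
#'
#' A window of \code{tau} frames is centered on the apex (clamped to the
#' sequence) and resampled to \code{nResample} indices F_0..F_{n-1}. For
#' each cell, the weighted centroid of the motion-magnitude image is
#' computed at every resampled frame; the features are the displacements
#' centroid(F_i) - centroid(F_0) for i = 1..n-1.
#'
#' @param seq a \linkS4class{FrameSequence}.
#' @param grid a \linkS4class{FacialCellGrid}.
#' @param apex 0-based apex frame index.
#' @param params a \code{\link{descriptorParams}} list.
#' @param baseline reference-frame convention for the motion-magnitude
#'   numerator: \code{"eq1"} (the frame \code{floor(tau/2)} earlier; default)
#'   or \code{"windowStart"} (the window's own first frame F_0).
#' @return Array of dim \code{c(10, nResample - 1, 2)}; dimnames are the
#'   cell names, NULL, and \code{c("dx", "dy")}.
#' @export
displacementFeatures <- function(seq, grid, apex,
                                 params = descriptorParams(),
                                 baseline = c("eq1", "windowStart")) {
  stopifnot(is(seq, "FrameSequence"), is(grid, "FacialCellGrid"))
  baseline <- match.arg(baseline)
  T <- nFrames(seq)
  apex <- as.integer(apex)
  if (apex < 0L || apex >= T) stop("apex index out of range")
  h <- params$tau %/% 2L
  w0 <- max(0L, apex - h)
  w1 <- min(T - 1L, apex + h)
  idx <- resampleWindow(w0, w1, params$nResample)
  n <- length(idx)
  d <- frameDim(seq)
  cents <- array(NA_real_, c(10L, n, 2L))
  for (ci in 1:10) {
    px <- cellPixels(grid, ci, d)
    xs <- px$x; ys <- px$y
    block <- seq@frames[px$rows, px$cols, , drop = FALSE]
    B <- array(as.double(block), dim(block))
    for (j in seq_len(n)) {
      t <- idx[j]
      ref <- if (baseline == "eq1") max(0L, t - h) else w0
      ft <- B[, , t + 1L]
      num <- abs(ft - B[, , ref + 1L])
      den <- abs(ft - B[, , max(0L, t - params$eps) + 1L])
      mm <- (num + 1) / (den + 1)
      tot <- sum(mm)
      cents[ci, j, 1] <- sum(colSums(mm) * xs) / tot
      cents[ci, j, 2] <- sum(rowSums(mm) * ys) / tot
    }
  }
  disp <- cents[, -1L, , drop = FALSE] -
    cents[, rep(1L, n - 1L), , drop = FALSE]
  dimnames(disp) <- list(.CELL_NAMES, NULL, c("dx", "dy"))
  disp
}
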