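#' FrameSequence: an ordered stack of grayscale video frames
#'
#' Holds a high-frame-rate face video as a 3-dimensional array
#' (rows x cols x frames) of intensities on the 0--255 scale, together with
#' the nominal capture frame rate. Frames may be stored as integer (8-bit
#' sensor output) or double (e.g. after roll normalization).
#'
#' @slot frames numeric or integer array, dim \code{c(height, width, n)}.
#' @slot fps frames per second (nominal).
#' @exportClass FrameSequence
setClass("FrameSequence",
  representation(frames = "array", fps = "numeric"),
  validity = function(object) {
    d <- dim(object@frames)
    if (length(d) != 3L) return("frames must be a 3D array (H x W x T)")
    if (d[3] < 1L) return("at least one frame is required")
    if (!is.numeric(object@frames)) return("frames must be numeric")
    if (anyNA(object@frames)) return("frames contain missing values")
    if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
      return("fps must be a single positive number")
    TRUE
  }
)

#' Construct a FrameSequence
#'
#' @param frames a 3D array (H x W x frames), a single matrix, or a list of
#'   equally-sized matrices.
#' @param fps nominal frames per second.
#' @return A \linkS4class{FrameSequence}.
#' @export
#' @examples
#' fs <- FrameSequence(array(0, c(4, 4, 3)), fps = 100)
#' nFrames(fs)
FrameSequence <- function(frames, fps = 100) {
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
      stop("all frames must have the same shape")
    frames <- array(unlist(frames, use.names = FALSE),
                    c(d, length(frames)))
  }
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  new("FrameSequence", frames = frames, fps = as.numeric(fps))
}

#' FacialCellGrid: ten muscle-aligned square cells
#'
#' Square, axis-aligned regions anchored to facial landmarks, one per
#' facial-expression muscle group analyzed. All cells share a common side
#' length (half the mouth width).
#'
#' @slot centers 10 x 2 matrix of cell centers (x, y pixel coordinates),
#'   rows named by \code{\link{cellNames}}.
#' @slot side common side length in pixels.
#' @exportClass FacialCellGrid
setClass("FacialCellGrid",
  representation(centers = "matrix", side = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@centers), c(10L, 2L)))
      return("centers must be a 10 x 2 matrix")
    if (!identical(rownames(object@centers), .CELL_NAMES))
      return("centers rows must be named by the 10 canonical cells, in order")
    if (anyNA(object@centers) || any(!is.finite(object@centers)))
      return("cell centers must be finite")
    if (length(object@side) != 1L || !is.finite(object@side) ||
        object@side <= 0)
      return("side must be a single positive number")
    TRUE
  }
)

#' Construct a FacialCellGrid directly
#'
#' Mostly useful for tests and custom layouts; regular use goes through
#' \code{\link{defineCells}}.
#'
#' @param centers 10 x 2 matrix of (x, y) cell centers in canonical order
#'   (rows are renamed to \code{\link{cellNames}}).
#' @param side common cell side length in pixels.
#' @return A \linkS4class{FacialCellGrid}.
#' @export
FacialCellGrid <- function(centers, side) {
  centers <- as.matrix(centers)
  rownames(centers) <- .CELL_NAMES
  colnames(centers) <- c("x", "y")
  new("FacialCellGrid", centers = centers, side = as.numeric(side))
}

#' CellSignal: per-cell motion-magnitude time series
#'
#' For each facial cell, the mean of the motion-magnitude image within the
#' cell at every frame. The first \code{ceiling(tau/2)} frames, where the
#' motion-magnitude image cannot be computed, are stored as 0.
#'
#' @slot signals T x 10 matrix, columns in \code{\link{cellNames}} order.
#' @slot tau the micro-expression duration (frames) used to compute it.
#' @exportClass CellSignal
setClass("CellSignal",
  representation(signals = "matrix", tau = "integer"),
  validity = function(object) {
    if (!identical(colnames(object@signals), .CELL_NAMES))
      return("signal columns must be the 10 canonical cells, in order")
    if (any(object@signals < 0)) return("signals must be non-negative")
    if (length(object@tau) != 1L || object@tau < 2L)
      return("tau must be a single integer >= 2")
    TRUE
  }
)

#' MEDetector: boosted decision-tree frame spotter
#'
#' A discrete AdaBoost ensemble of depth-limited decision trees over the
#' 20-dimensional windowed min/max cell-signal feature, labelling each frame
#' micro-expression / non-micro-expression.
#'
#' @slot trees list of fitted \code{rpart} weak learners.
#' @slot alphas numeric stage weights, one per weak learner.
#' @slot cellOrder the cell order the features were built in.
#' @slot depth weak-learner tree depth.
#' @slot seed training seed (for provenance).
#' @slot version serialization format version.
#' @exportClass MEDetector
setClass("MEDetector",
  representation(trees = "list", alphas = "numeric", cellOrder = "character",
                 depth = "integer", seed = "integer", version = "character"),
  validity = function(object) {
    if (length(object@trees) != length(object@alphas))
      return("one stage weight per weak learner is required")
    if (length(object@trees) < 1L) return("ensemble is empty")
    if (!identical(object@cellOrder, .CELL_NAMES))
      return("cell order metadata does not match the canonical cell order")
    TRUE
  }
)

#' ExpressionModel: per-class bivariate Gaussian displacement models
#'
#' For every expression class and every facial cell, the mean vector and
#' (regularized) covariance of the weighted-centroid displacement pairs
#' observed in training.
#'
#' @slot classes character, the classes modelled (subset of
#'   \code{\link{expressionClasses}}, in tie-break order).
#' @slot means named list: per class a 10 x 2 matrix of per-cell means.
#' @slot covs named list: per class a list of 10 2x2 covariance matrices.
#' @slot counts named integer: training sequences per class.
#' @slot pairCounts named integer: pooled displacement pairs per class.
#' @slot cellOrder cell order metadata.
#' @slot nResample number of resampled frames the features used.
#' @slot covFloor covariance regularization floor (px^2).
#' @slot version serialization format version.
#' @exportClass ExpressionModel
setClass("ExpressionModel",
  representation(classes = "character", means = "list", covs = "list",
                 counts = "integer", pairCounts = "integer",
                 cellOrder = "character", nResample = "integer",
                 covFloor = "numeric", version = "character"),
  validity = function(object) {
    if (length(object@classes) < 1L) return("no classes modelled")
    if (!all(object@classes %in% .ME_CLASSES))
      return("unknown expression class")
    if (!identical(names(object@means), object@classes) ||
        !identical(names(object@covs), object@classes))
      return("means/covs must be named by the modelled classes")
    if (!identical(object@cellOrder, .CELL_NAMES))
      return("cell order metadata does not match the canonical cell order")
    for (e in object@classes) {
      if (!identical(dim(object@means[[e]]), c(10L, 2L)))
        return("each class needs a 10 x 2 mean matrix")
      for (S in object@covs[[e]]) {
        if (!identical(dim(S), c(2L, 2L))) return("covariances must be 2 x 2")
        if (max(abs(S - t(S))) > 1e-8) return("covariances must be symmetric")
      }
    }
    TRUE
  }
)

## ---- generics and accessors -------------------------------------------

#' Number of frames in a sequence
#' @param x a \linkS4class{FrameSequence}.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "FrameSequence", function(x) dim(x@frames)[3])

#' Frame dimensions (height, width)
#' @param x a \linkS4class{FrameSequence}.
#' @return integer vector \code{c(height, width)}.
#' @export
setGeneric("frameDim", function(x) standardGeneric("frameDim"))

#' @rdname frameDim
#' @export
setMethod("frameDim", "FrameSequence", function(x) dim(x@frames)[1:2])

#' Nominal frame rate
#' @param x a \linkS4class{FrameSequence}.
#' @return frames per second.
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))

#' @rdname fps
#' @export
setMethod("fps", "FrameSequence", function(x) x@fps)

#' Extract a single frame
#' @param x a \linkS4class{FrameSequence}.
#' @param t 0-based frame index.
#' @return numeric matrix (H x W).
#' @export
setGeneric("frameAt", function(x, t) standardGeneric("frameAt"))

#' @rdname frameAt
#' @export
setMethod("frameAt", "FrameSequence", function(x, t) {
  t <- as.integer(t)
  if (t < 0L || t >= nFrames(x)) stop("frame index out of range: ", t)
  d <- dim(x@frames)
  matrix(as.double(x@frames[, , t + 1L]), d[1], d[2])
})

#' Cell centers of a grid
#' @param x a \linkS4class{FacialCellGrid}.
#' @return 10 x 2 matrix of (x, y) centers named by \code{\link{cellNames}}.
#' @export
setGeneric("cellCenters", function(x) standardGeneric("cellCenters"))

#' @rdname cellCenters
#' @export
setMethod("cellCenters", "FacialCellGrid", function(x) x@centers)

#' Cell side length of a grid
#' @param x a \linkS4class{FacialCellGrid}.
#' @return side length in pixels.
#' @export
setGeneric("cellSide", function(x) standardGeneric("cellSide"))

#' @rdname cellSide
#' @export
setMethod("cellSide", "FacialCellGrid", function(x) x@side)

#' Per-cell signal matrix
#' @param x a \linkS4class{CellSignal}.
#' @return T x 10 numeric matrix, columns in canonical cell order.
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @rdname signalMatrix
#' @export
setMethod("signalMatrix", "CellSignal", function(x) x@signals)

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameSequence: %d frames of %d x %d px @ %g fps (%s)\n",
              d[3], d[1], d[2], object@fps,
              storage.mode(object@frames)))
})

setMethod("show", "FacialCellGrid", function(object) {
  cat(sprintf("FacialCellGrid: 10 cells, side %.2f px\n", object@side))
  print(round(object@centers, 2))
})

setMethod("show", "CellSignal", function(object) {
  cat(sprintf("CellSignal: %d frames x 10 cells (tau = %d)\n",
              nrow(object@signals), object@tau))
})

setMethod("show", "MEDetector", function(object) {
  cat(sprintf(
    "MEDetector: %d boosted trees (depth %d), 20-d min/max feature\n",
    length(object@trees), object@depth))
})

setMethod("show", "ExpressionModel", function(object) {
  cat(sprintf(
    "ExpressionModel: classes {%s}, %d cells, n_resample = %d\n",
    paste(object@classes, collapse = ", "),
    length(object@cellOrder), object@nResample))
  cat("training sequences:",
      paste(sprintf("%s=%d", names(object@counts), object@counts),
            collapse = ", "), "\n")
})
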