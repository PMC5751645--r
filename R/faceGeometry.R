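## Facial geometry: landmarks -> roll normalization -> muscle-aligned cells.
##
## Landmarks are a 68 x 2 matrix in iBUG order (x right, y down, pixel
## units). Landmark numbers in comments/docs are the usual 1-based names.

validateLandmarks <- function(landmarks) {
  lm <- as.matrix(landmarks)
  if (!is.numeric(lm) || !identical(dim(lm), c(68L, 2L)))
    stop("landmarks must be a numeric 68 x 2 matrix (iBUG ordering)")
  if (anyNA(lm) || any(!is.finite(lm)))
    stop("landmarks must be finite")
  colnames(lm) <- c("x", "y")
  lm
}

euclid <- function(a, b) sqrt(sum((a - b)^2))

#' Estimate the in-plane (roll) rotation of a face
#'
#' The roll angle is the angle of the line joining the two outer eye corners
#' (iBUG landmarks 37 and 46) with the image x-axis, measured with y pointing
#' down. A frontal, level face yields 0.
#'
#' @param landmarks 68 x 2 landmark matrix.
#' @return Roll angle in radians.
#' @export
#' @examples
#' lm <- landmarkTemplate(96)
#' estimateRoll(lm)  # 0 for the symmetric template
estimateRoll <- function(landmarks) {
  lm <- validateLandmarks(landmarks)
  d <- lm[46, ] - lm[37, ]
  if (sqrt(sum(d^2)) < 1e-8)
    stop("degenerate geometry: outer eye corners coincide")
  theta <- atan2(d[["y"]], d[["x"]])
  if (abs(theta) >= pi / 2)
    stop("roll angle of ", round(theta, 3),
         " rad exceeds 90 degrees; face rejected")
  theta
}

# Rotate 2D points about a center: p' = c + R(angle) (p - c),
# R = [[cos, -sin], [sin, cos]] in (x right, y down) coordinates.
rotatePoints <- function(points, center, angle) {
  dx <- points[, 1] - center[1]
  dy <- points[, 2] - center[2]
  cbind(center[1] + cos(angle) * dx - sin(angle) * dy,
        center[2] + sin(angle) * dx + cos(angle) * dy)
}

# Precompute a bilinear backward warp that rotates an image by -theta about
# `center` (i.e. samples the source at +theta). Returns gather indices and
# weights; out-of-frame samples get weight 0 (zero fill).
makeRotationWarp <- function(dimhw, center, theta) {
  H <- dimhw[1]; W <- dimhw[2]
  x <- rep(0:(W - 1L), each = H)
  y <- rep.int(0:(H - 1L), W)
  dx <- x - center[1]; dy <- y - center[2]
  sx <- center[1] + cos(theta) * dx - sin(theta) * dy
  sy <- center[2] + sin(theta) * dx + cos(theta) * dy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  nb <- function(xi, yi, w) {
    inside <- xi >= 0 & xi <= W - 1 & yi >= 0 & yi <= H - 1
    list(idx = ifelse(inside, yi + 1 + xi * H, 1L), w = w * inside)
  }
  list(H = H, W = W,
       n00 = nb(x0,      y0,      (1 - fx) * (1 - fy)),
       n10 = nb(x0 + 1L, y0,      fx       * (1 - fy)),
       n01 = nb(x0,      y0 + 1L, (1 - fx) * fy),
       n11 = nb(x0 + 1L, y0 + 1L, fx       * fy))
}

# Apply a precomputed warp to one frame (matrix) or to a H*W x T matrix of
# flattened frames.
applyWarp <- function(warp, img) {
  v <- as.matrix(img)
  flat <- if (ncol(v) == warp$W) matrix(v, nrow = warp$H * warp$W) else v
  out <- warp$n00$w * flat[warp$n00$idx, , drop = FALSE] +
         warp$n10$w * flat[warp$n10$idx, , drop = FALSE] +
         warp$n01$w * flat[warp$n01$idx, , drop = FALSE] +
         warp$n11$w * flat[warp$n11$idx, , drop = FALSE]
  if (is.matrix(img) && ncol(img) == warp$W)
    matrix(out, warp$H, warp$W) else out
}

# Bilinear sample of an image at arbitrary 0-based (x, y) positions,
# zero-filled outside the frame. Used by the synthetic renderer.
bilinearSample <- function(img, x, y) {
  H <- nrow(img); W <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  val <- function(xi, yi) {
    inside <- xi >= 0 & xi <= W - 1 & yi >= 0 & yi <= H - 1
    v <- numeric(length(xi))
    v[inside] <- img[cbind(yi[inside] + 1L, xi[inside] + 1L)]
    v
  }
  (1 - fx) * (1 - fy) * val(x0, y0) +
    fx * (1 - fy) * val(x0 + 1L, y0) +
    (1 - fx) * fy * val(x0, y0 + 1L) +
    fx * fy * val(x0 + 1L, y0 + 1L)
}

#' Rotate a frame and its landmarks so the roll angle becomes zero
#'
#' Rotates both the image and the landmark set about the landmark centroid by
#' minus the estimated roll, so that \code{\link{estimateRoll}} of the result
#' is 0 (up to interpolation tolerance). The image is resampled with bilinear
#' interpolation and pixels mapped from outside the frame are filled with 0.
#' A zero input roll returns the inputs unchanged.
#'
#' @param frame numeric matrix (one grayscale frame), or \code{NULL} to
#'   transform landmarks only.
#' @param landmarks 68 x 2 landmark matrix.
#' @return \code{list(frame =, landmarks =, theta =)}.
#' @export
normalizeRoll <- function(frame, landmarks) {
  lm <- validateLandmarks(landmarks)
  theta <- estimateRoll(lm)
  if (theta == 0)
    return(list(frame = frame, landmarks = lm, theta = 0))
  ctr <- colMeans(lm)
  lm2 <- rotatePoints(lm, ctr, -theta)
  colnames(lm2) <- c("x", "y")
  out <- NULL
  if (!is.null(frame)) {
    warp <- makeRotationWarp(dim(frame), ctr, theta)
    out <- applyWarp(warp, frame)
  }
  list(frame = out, landmarks = lm2, theta = theta)
}

#' Roll-normalize a whole sequence with one shared warp
#'
#' @param seq a \linkS4class{FrameSequence}.
#' @param landmarks 68 x 2 landmark matrix (shared by all frames).
#' @return \code{list(seq =, landmarks =, theta =)}.
#' @export
normalizeSequence <- function(seq, landmarks) {
  stopifnot(is(seq, "FrameSequence"))
  lm <- validateLandmarks(landmarks)
  theta <- estimateRoll(lm)
  if (theta == 0) return(list(seq = seq, landmarks = lm, theta = 0))
  ctr <- colMeans(lm)
  lm2 <- rotatePoints(lm, ctr, -theta)
  colnames(lm2) <- c("x", "y")
  d <- dim(seq@frames)
  warp <- makeRotationWarp(d[1:2], ctr, theta)
  flat <- matrix(as.double(seq@frames), nrow = d[1] * d[2])
  out <- applyWarp(warp, flat)
  list(seq = FrameSequence(array(out, d), fps = fps(seq)),
       landmarks = lm2, theta = theta)
}

#' Place the ten muscle-aligned square cells from landmarks
#'
#' The common cell side is half the Euclidean mouth width (distance between
#' iBUG landmarks 49 and 55). Centers are placed from named landmark anchors:
#' frontalis cells above the mid-brow points and the procerus above the inner
#' brow ends (all raised by \code{frontalisOffset} sides), orbicularis oculi
#' at the eye centroids, nostril/zygomatic cells lateral to the nose wings by
#' \code{nostrilOffset} sides, mouth-corner cells on the mouth corners, and
#' the mentalis below the lower-lip midpoint by \code{mentalisOffset} sides.
#' The construction is equivariant under translation and uniform scaling of
#' the landmarks. Landmarks are expected to be roll-normalized.
#'
#' @param landmarks 68 x 2 roll-normalized landmark matrix.
#' @param frontalisOffset upward offset of brow cells, in cell sides.
#' @param nostrilOffset lateral offset of the nose-wing cells, in cell sides.
#' @param mentalisOffset downward offset of the chin cell, in cell sides.
#' @return A \linkS4class{FacialCellGrid}.
#' @export
#' @examples
#' grid <- defineCells(landmarkTemplate(96))
#' cellSide(grid)
defineCells <- function(landmarks, frontalisOffset = 0.6,
                        nostrilOffset = 0.75, mentalisOffset = 0.75) {
  lm <- validateLandmarks(landmarks)
  side <- 0.5 * euclid(lm[49, ], lm[55, ])
  if (side <= 1e-8)
    stop("degenerate geometry: zero mouth width")
  mid <- function(idx) colMeans(lm[idx, , drop = FALSE])
  up <- c(0, -frontalisOffset * side)
  centers <- rbind(
    left_frontalis          = mid(c(20, 21)) + up,
    procerus                = mid(c(22, 23)) + up,
    right_frontalis         = mid(c(24, 25)) + up,
    left_orbicularis_oculi  = mid(37:42),
    right_orbicularis_oculi = mid(43:48),
    left_nostril_zygomatic  = lm[32, ] + c(-nostrilOffset * side, 0),
    right_nostril_zygomatic = lm[36, ] + c(nostrilOffset * side, 0),
    left_mouth_corner       = lm[49, ],
    right_mouth_corner      = lm[55, ],
    mentalis                = lm[58, ] + c(0, mentalisOffset * side)
  )
  colnames(centers) <- c("x", "y")
  new("FacialCellGrid", centers = centers, side = side)
}

#' Integer pixel set covered by a cell, clipped to the frame
#'
#' Resolves a cell of the grid to the integer pixel block it covers inside a
#' frame of the given dimensions. Pixel coordinates are 0-based integer
#' centers; a cell entirely outside the frame is an error, partial overlap is
#' clipped.
#'
#' @param grid a \linkS4class{FacialCellGrid}.
#' @param cell cell name or index (1..10).
#' @param dimhw frame dimensions \code{c(height, width)}.
#' @return \code{list(rows =, cols =, x =, y =)}: 1-based matrix indices and
#'   the matching 0-based pixel coordinates.
#' @export
cellPixels <- function(grid, cell, dimhw) {
  stopifnot(is(grid, "FacialCellGrid"))
  if (is.character(cell)) {
    cell <- match(cell, .CELL_NAMES)
    if (is.na(cell)) stop("unknown cell name")
  }
  ctr <- grid@centers[cell, ]
  side <- grid@side
  n <- max(1L, as.integer(roundHalfUp(side)))
  x0 <- as.integer(roundHalfUp(ctr[["x"]] - side / 2))
  y0 <- as.integer(roundHalfUp(ctr[["y"]] - side / 2))
  xs <- x0:(x0 + n - 1L)
  ys <- y0:(y0 + n - 1L)
  xs <- xs[xs >= 0L & xs <= dimhw[2] - 1L]
  ys <- ys[ys >= 0L & ys <= dimhw[1] - 1L]
  if (length(xs) == 0L || length(ys) == 0L)
    stop("cell '", .CELL_NAMES[cell], "' lies entirely outside the frame")
  list(rows = ys + 1L, cols = xs + 1L, x = xs, y = ys)
}
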