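## Synthetic face-video simulator: a near-frontal textured face with stable
## 68-point landmarks; micro-expression events move a localized intensity
## blob inside each affected facial cell along a class-specific direction
## with an onset -> apex -> offset piecewise-cosine envelope; additive
## Gaussian sensor noise and optional global flicker complete the scene.
## Every output is a pure function of (parameters, seed).

#' Synthetic 68-point frontal landmark layout
#'
#' A symmetric, near-frontal iBUG-style landmark template scaled to a square
#' frame. The outer eye corners are level, so the template's roll angle is
#' exactly zero.
#'
#' @param imageSize side of the square frame in pixels.
#' @return 68 x 2 landmark matrix (x, y), pixel units.
#' @export
landmarkTemplate <- function(imageSize = 96) {
  S <- imageSize
  pts <- matrix(NA_real_, 68L, 2L)
  # jaw / face outline 1-17: lower half-ellipse, left ear -> chin -> right ear
  a <- pi * (0:16) / 16
  pts[1:17, ] <- cbind(0.5 - 0.38 * cos(a), 0.48 + 0.46 * sin(a))
  # brows 18-22 (left, 22 innermost) and 23-27 (right, 23 innermost)
  pts[18:22, ] <- cbind(seq(0.22, 0.40, length.out = 5),
                        0.30 - c(0, 0.015, 0.02, 0.015, 0.005))
  pts[23:27, ] <- cbind(seq(0.60, 0.78, length.out = 5),
                        0.30 - c(0.005, 0.015, 0.02, 0.015, 0))
  # nose bridge 28-31 and base 32-36 (32/36 are the nose wings)
  pts[28:31, ] <- cbind(rep(0.5, 4), seq(0.34, 0.475, length.out = 4))
  pts[32:36, ] <- cbind(c(0.42, 0.46, 0.50, 0.54, 0.58),
                        c(0.52, 0.53, 0.535, 0.53, 0.52))
  # eyes 37-42 (left, 37 outer corner) and 43-48 (right, 46 outer corner)
  pts[37:42, ] <- cbind(c(0.27, 0.31, 0.35, 0.39, 0.35, 0.31),
                        c(0.36, 0.345, 0.345, 0.36, 0.375, 0.375))
  pts[43:48, ] <- cbind(c(0.61, 0.65, 0.69, 0.73, 0.69, 0.65),
                        c(0.36, 0.345, 0.345, 0.36, 0.375, 0.375))
  # mouth: outer lip 49-60 (49/55 corners), inner lip 61-68
  pts[49:60, ] <- cbind(
    c(0.36, 0.40, 0.45, 0.50, 0.55, 0.60, 0.64,
      0.60, 0.55, 0.50, 0.45, 0.40),
    c(0.66, 0.64, 0.635, 0.63, 0.635, 0.64, 0.66,
      0.69, 0.70, 0.705, 0.70, 0.69))
  pts[61:68, ] <- cbind(
    c(0.38, 0.44, 0.50, 0.56, 0.62, 0.56, 0.50, 0.44),
    c(0.66, 0.655, 0.65, 0.655, 0.66, 0.67, 0.675, 0.67))
  colnames(pts) <- c("x", "y")
  pts * S
}

#' Per-cell motion direction template of an expression class
#'
#' Unit direction vectors (image coordinates, y down) of the localized
#' motion each class produces, guided by the facial action units: surprise
#' raises the brows and lifts the eyelids (upward motion in the frontalis,
#' procerus and eye cells); a positive expression pulls the mouth corners
#' outward and upward; a negative expression knits the brows downward and
#' inward and drags the mouth corners down. Unaffected cells carry zero
#' vectors.
#'
#' @param cls one of \code{\link{expressionClasses}}.
#' @return 10 x 2 matrix of directions, rows named by \code{\link{cellNames}};
#'   non-zero rows have unit norm.
#' @export
classDirectionTemplate <- function(cls) {
  cls <- match.arg(cls, .ME_CLASSES)
  unit <- function(x, y) c(x, y) / sqrt(x^2 + y^2)
  D <- matrix(0, 10L, 2L, dimnames = list(.CELL_NAMES, c("dx", "dy")))
  if (cls == "surprise") {
    up <- c("left_frontalis", "procerus", "right_frontalis",
            "left_orbicularis_oculi", "right_orbicularis_oculi")
    D[up, ] <- matrix(c(0, -1), length(up), 2, byrow = TRUE)
  } else if (cls == "positive") {
    D["left_mouth_corner", ] <- unit(-1, -1)
    D["right_mouth_corner", ] <- unit(1, -1)
  } else { # negative
    D["left_frontalis", ] <- unit(1, 1)
    D["procerus", ] <- c(0, 1)
    D["right_frontalis", ] <- unit(-1, 1)
    D["left_mouth_corner", ] <- c(0, 1)
    D["right_mouth_corner", ] <- c(0, 1)
  }
  D
}

#' Scene parameters for the synthetic generator
#'
#' @param imageSize square frame side in pixels.
#' @param fps nominal frame rate (frames/second).
#' @param seqLen sequence length in frames.
#' @param noiseSigma additive Gaussian sensor noise sd, intensity units on
#'   the 0--255 scale.
#' @param flickerAmp amplitude of a global multiplicative sinusoidal flicker
#'   (0 to 0.2), emulating the light flicker of high-speed footage.
#' @param flickerHz flicker frequency in Hz.
#' @param events list of expression events, each created with
#'   \code{\link{expressionEvent}}.
#' @param landmarks optional 68 x 2 landmark matrix; defaults to
#'   \code{\link{landmarkTemplate}(imageSize)}.
#' @return Validated named list of class \code{sceneParams}.
#' @export
sceneParams <- function(imageSize = 96, fps = 100, seqLen = 360,
                        noiseSigma = 2, flickerAmp = 0, flickerHz = 7,
                        events = list(), landmarks = NULL) {
  p <- list(imageSize = as.integer(imageSize), fps = as.numeric(fps),
            seqLen = as.integer(seqLen), noiseSigma = as.numeric(noiseSigma),
            flickerAmp = as.numeric(flickerAmp),
            flickerHz = as.numeric(flickerHz),
            events = events, landmarks = landmarks)
  if (p$imageSize < 32L) stop("imageSize must be >= 32")
  if (p$noiseSigma < 0) stop("noiseSigma must be >= 0")
  if (p$flickerAmp < 0 || p$flickerAmp > 0.2)
    stop("flickerAmp must be in [0, 0.2]")
  if (p$seqLen < 2L) stop("seqLen must be >= 2")
  for (ev in p$events) {
    if (!inherits(ev, "expressionEvent")) stop("events must be expressionEvent objects")
    if (ev$onset < 0L || ev$offset >= p$seqLen)
      stop("event [", ev$onset, ", ", ev$offset,
           "] lies outside the sequence")
  }
  class(p) <- "sceneParams"
  p
}

#' A programmed micro-expression event
#'
#' The annotated interval \code{[onset, offset]} is the period of visible
#' motion: the displacement envelope rises 0 to 1 over \code{[onset, apex]}
#' and falls back over \code{[apex, offset]} (piecewise cosine). As in real
#' footage, the face does not snap back to the exact neutral texture the
#' moment the visible motion ends: a residual fraction of the displacement
#' remains at the offset and relaxes to zero slowly (sub-threshold) over
#' \code{relax} further frames.
#'
#' @param cls expression class (positive / negative / surprise).
#' @param onset,apex,offset 0-based frame indices, onset < apex < offset.
#' @param magnitude peak texture displacement in pixels (> 0).
#' @param residual displacement fraction still present at the annotated
#'   offset (0 = instant return to neutral).
#' @param relax frames over which the residual relaxes to zero.
#' @return Named list of class \code{expressionEvent}.
#' @export
expressionEvent <- function(cls, onset, apex, offset, magnitude = 3,
                            residual = 0.5, relax = 80) {
  cls <- match.arg(cls, .ME_CLASSES)
  onset <- as.integer(onset); apex <- as.integer(apex)
  offset <- as.integer(offset)
  if (!(onset < apex && apex < offset))
    stop("need onset < apex < offset")
  if (magnitude <= 0) stop("magnitude must be > 0")
  if (residual < 0 || residual >= 1) stop("residual must be in [0, 1)")
  if (relax < 1) stop("relax must be >= 1")
  structure(list(cls = cls, onset = onset, apex = apex, offset = offset,
                 magnitude = as.numeric(magnitude),
                 residual = as.numeric(residual),
                 relax = as.integer(relax)),
            class = "expressionEvent")
}

# displacement envelope: cosine rise 0 -> 1 on [onset, apex], cosine fall
# 1 -> residual on [apex, offset], slow cosine relaxation residual -> 0
# over the `relax` frames after the annotated offset.
eventEnvelope <- function(t, ev) {
  r <- ev$residual %||% 0
  rel <- ev$relax %||% 1L
  if (t < ev$onset || t > ev$offset + rel) return(0)
  if (t <= ev$apex)
    return(0.5 * (1 - cos(pi * (t - ev$onset) / (ev$apex - ev$onset))))
  if (t <= ev$offset)
    return(r + (1 - r) * 0.5 *
             (1 + cos(pi * (t - ev$apex) / (ev$offset - ev$apex))))
  r * 0.5 * (1 + cos(pi * (t - ev$offset) / rel))
}

# Gaussian intensity blob evaluated on 0-based pixel coordinates.
.blobField <- function(xs, ys, cx, cy, amp, sd) {
  gx <- exp(-((xs - cx)^2) / (2 * sd^2))
  gy <- exp(-((ys - cy)^2) / (2 * sd^2))
  amp * outer(gy, gx)
}

# Static base face: mid-gray background, elliptical face shading, weak
# texture blobs near random landmarks, plus one anchor blob per facial cell
# (the element an expression event moves). Returns the texture and the
# anchor parameters.
.baseFace <- function(S, landmarks, grid) {
  xs <- 0:(S - 1L); ys <- 0:(S - 1L)
  ctr <- colMeans(landmarks)
  gx <- exp(-((xs - ctr[1])^2) / (2 * (0.40 * S)^2))
  gy <- exp(-((ys - ctr[2])^2) / (2 * (0.45 * S)^2))
  tex <- matrix(110, S, S) + 35 * outer(gy, gx)
  for (b in seq_len(18)) {
    p <- landmarks[sample.int(68L, 1L), ] + stats::rnorm(2, 0, 0.03 * S)
    tex <- tex + .blobField(xs, ys, p[["x"]], p[["y"]],
                            stats::runif(1, -18, 18),
                            stats::runif(1, 2, 5))
  }
  side <- cellSide(grid)
  anchors <- lapply(seq_len(10L), function(ci) {
    c0 <- cellCenters(grid)[ci, ]
    list(cx = c0[["x"]], cy = c0[["y"]],
         amp = stats::runif(1, 35, 60) * sample(c(-1, 1), 1),
         sd = stats::runif(1, 0.14, 0.20) * side)
  })
  for (a in anchors)
    tex <- tex + .blobField(xs, ys, a$cx, a$cy, a$amp, a$sd)
  list(tex = pmin(pmax(tex, 20), 235), anchors = anchors)
}

#' Render a synthetic annotated face sequence
#'
#' Renders a static textured base face anchored to the landmark set. For
#' every event and every affected cell, the cell's anchor blob is re-drawn
#' displaced by \code{direction * magnitude * envelope(t)} (evaluated
#' analytically, restricted to the cell square), so the motion is strictly
#' localized: with noise and flicker disabled, all pixels outside affected
#' cells are constant over time. Per-pixel Gaussian noise and global
#' multiplicative flicker are then applied and frames are quantized to
#' 8-bit. Fully deterministic given \code{seed}.
#'
#' @param params a \code{\link{sceneParams}} list.
#' @param seed RNG seed.
#' @return list with \code{frames} (a \linkS4class{FrameSequence}, integer
#'   0--255), \code{landmarks}, \code{grid} (the
#'   \linkS4class{FacialCellGrid} used for rendering), and
#'   \code{annotations} (data.frame with \code{onset}, \code{apex},
#'   \code{offset}, \code{label}; zero rows when there are no events).
#' @export
generateSequence <- function(params = sceneParams(), seed = 1) {
  stopifnot(inherits(params, "sceneParams"))
  withSeed(seed, {
    S <- params$imageSize
    lm <- params$landmarks %||% landmarkTemplate(S)
    grid <- defineCells(lm)
    bf <- .baseFace(S, lm, grid)
    phase <- stats::runif(1, 0, 2 * pi)
    cellPx <- lapply(seq_len(10L), function(ci)
      cellPixels(grid, ci, c(S, S)))
    evDirs <- lapply(params$events, function(ev)
      classDirectionTemplate(ev$cls))
    frames <- array(0L, c(S, S, params$seqLen))
    noise <- if (params$noiseSigma > 0)
      array(stats::rnorm(S * S * params$seqLen, 0, params$noiseSigma),
            c(S, S, params$seqLen))
    for (t in 0:(params$seqLen - 1L)) {
      f <- bf$tex
      for (k in seq_along(params$events)) {
        ev <- params$events[[k]]
        env <- eventEnvelope(t, ev)
        if (env <= 0) next
        D <- evDirs[[k]]
        for (ci in which(rowSums(abs(D)) > 0)) {
          px <- cellPx[[ci]]
          a <- bf$anchors[[ci]]
          shift <- env * ev$magnitude * D[ci, ]
          rest <- .blobField(px$x, px$y, a$cx, a$cy, a$amp, a$sd)
          moved <- .blobField(px$x, px$y, a$cx + shift[1], a$cy + shift[2],
                              a$amp, a$sd)
          f[px$rows, px$cols] <- f[px$rows, px$cols] - rest + moved
        }
      }
      if (params$flickerAmp > 0)
        f <- f * (1 + params$flickerAmp *
                    sin(2 * pi * params$flickerHz * t / params$fps + phase))
      if (!is.null(noise)) f <- f + noise[, , t + 1L]
      frames[, , t + 1L] <- as.integer(pmin(255, pmax(0, roundHalfUp(f))))
    }
    ann <- if (length(params$events)) {
      data.frame(
        onset = vapply(params$events, `[[`, integer(1), "onset"),
        apex = vapply(params$events, `[[`, integer(1), "apex"),
        offset = vapply(params$events, `[[`, integer(1), "offset"),
        label = vapply(params$events, `[[`, character(1), "cls"),
        stringsAsFactors = FALSE)
    } else {
      data.frame(onset = integer(0), apex = integer(0), offset = integer(0),
                 label = character(0), stringsAsFactors = FALSE)
    }
    list(frames = FrameSequence(frames, fps = params$fps),
         landmarks = lm, grid = grid, annotations = ann)
  })
}

#' Generate an annotated multi-subject dataset
#'
#' Each subject gets a distinct base-face seed and a small random
#' perturbation of the landmark template; each sequence carries 0, 1 or 2
#' micro-expression events with classes drawn from \code{classMix},
#' magnitudes from \code{magnitudeRange} and total durations from
#' \code{durationRange} (rise time about half the duration). Apexes are
#' placed at least \code{margin} frames from the sequence borders and, for
#' two-event sequences, at least \code{4 * margin} frames apart so separate
#' events stay separable after interval merging.
#'
#' @param nSubjects number of subjects (>= 2).
#' @param sequencesPerSubject sequences rendered per subject.
#' @param classMix named class probabilities (positive/negative/surprise).
#' @param params a \code{\link{sceneParams}} list (its \code{events} and
#'   \code{landmarks} entries are overridden per sequence).
#' @param seed RNG seed; the whole dataset is a pure function of it.
#' @param eventCountProbs probabilities of 0, 1 and 2 events per sequence.
#' @param magnitudeRange peak displacement range in pixels.
#' @param durationRange event duration range in frames.
#' @param margin minimum apex distance to the sequence borders in frames.
#' @param dir optional directory: when given, the dataset is also written to
#'   disk via \code{\link{writeDataset}}.
#' @return list of class \code{meDataset} with \code{sequences} (each a
#'   list \code{subjectId}, \code{sequenceId}, \code{frames},
#'   \code{landmarks}) and \code{annotations} (data.frame with
#'   \code{subject_id}, \code{sequence_id}, \code{onset}, \code{apex},
#'   \code{offset}, \code{label}).
#' @export
generateDataset <- function(nSubjects = 8, sequencesPerSubject = 5,
                            classMix = c(positive = 1/3, negative = 1/3,
                                         surprise = 1/3),
                            params = sceneParams(), seed = 1,
                            eventCountProbs = c(0.2, 0.6, 0.2),
                            magnitudeRange = c(1, 4),
                            durationRange = c(20, 40),
                            margin = 40, dir = NULL) {
  if (nSubjects < 2L) stop("need at least 2 subjects")
  stopifnot(inherits(params, "sceneParams"))
  if (is.null(names(classMix)) || !all(names(classMix) %in% .ME_CLASSES))
    stop("classMix must be named by expression classes")
  lo <- margin
  hi <- params$seqLen - 1L - margin
  if (hi <= lo) stop("seqLen too short for the apex placement margin")
  if (length(eventCountProbs) != 3L || any(eventCountProbs < 0))
    stop("eventCountProbs must be 3 non-negative probabilities")
  if (eventCountProbs[3] > 0 && (hi - lo) < 4L * margin)
    stop("seqLen too short to place two separated events; ",
         "set eventCountProbs[3] to 0 or lengthen the sequences")
  dataset <- withSeed(seed, {
    seqs <- list()
    annAll <- list()
    for (s in seq_len(nSubjects)) {
      subj <- sprintf("S%02d", s)
      lm <- landmarkTemplate(params$imageSize) +
        matrix(stats::rnorm(136, 0, 0.01 * params$imageSize), 68L, 2L)
      for (q in seq_len(sequencesPerSubject)) {
        sid <- sprintf("%s_%02d", subj, q)
        nEv <- sample(0:2, 1L, prob = eventCountProbs)
        apexes <- integer(0)
        if (nEv == 1L) {
          apexes <- sample(lo:hi, 1L)
        } else if (nEv == 2L) {
          repeat {
            apexes <- sort(sample(lo:hi, 2L))
            if (diff(apexes) >= 4L * margin) break
          }
        }
        events <- lapply(apexes, function(a) {
          dur <- sample(durationRange[1]:durationRange[2], 1L)
          rise <- dur %/% 2L
          expressionEvent(
            cls = sample(names(classMix), 1L, prob = classMix),
            onset = max(0L, a - rise), apex = a,
            offset = min(params$seqLen - 1L, a + (dur - rise)),
            magnitude = stats::runif(1, magnitudeRange[1], magnitudeRange[2]))
        })
        p <- params
        p$events <- events
        p$landmarks <- lm
        sseed <- sample.int(.Machine$integer.max - 1L, 1L)
        out <- generateSequence(p, seed = sseed)
        seqs[[sid]] <- list(subjectId = subj, sequenceId = sid,
                            frames = out$frames, landmarks = out$landmarks)
        if (nrow(out$annotations)) {
          ann <- cbind(subject_id = subj, sequence_id = sid,
                       out$annotations, stringsAsFactors = FALSE)
          annAll[[length(annAll) + 1L]] <- ann
        }
      }
    }
    annotations <- if (length(annAll)) {
      do.call(rbind, annAll)
    } else {
      data.frame(subject_id = character(0), sequence_id = character(0),
                 onset = integer(0), apex = integer(0), offset = integer(0),
                 label = character(0), stringsAsFactors = FALSE)
    }
    rownames(annotations) <- NULL
    structure(list(sequences = seqs, annotations = annotations),
              class = "meDataset")
  })
  if (!is.null(dir)) writeDataset(dataset, dir)
  dataset
}

#' @export
print.meDataset <- function(x, ...) {
  subs <- unique(vapply(x$sequences, `[[`, character(1), "subjectId"))
  cat(sprintf(
    "meDataset: %d sequences, %d subjects, %d annotated micro-expressions\n",
    length(x$sequences), length(subs), nrow(x$annotations)))
  invisible(x)
}
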