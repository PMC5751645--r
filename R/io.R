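## File formats: frame directories (PNG via the png package, plus a minimal
## uncompressed BMP codec since no installed R package reads BMP), landmark
## files (pts dialect and CSV), annotation tables, model files and dataset
## directories. All frame indices on disk are 0-based.

# ITU-R BT.601 luma on the 0-255 scale for color input.
.toGray <- function(a) {
  if (length(dim(a)) == 2L) return(a)
  if (dim(a)[3] >= 3L)
    return(0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3])
  a[, , 1]
}

#' Read a grayscale frame image (PNG or BMP)
#'
#' Color input is converted to grayscale with BT.601 luma weights; values
#' are returned on the 0--255 scale.
#'
#' @param path image file path.
#' @return Numeric matrix (H x W).
#' @export
readFrameImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    .toGray(png::readPNG(path) * 255)
  } else if (ext == "bmp") {
    readBMP(path)
  } else {
    stop("unsupported frame format: ", ext)
  }
}

#' Minimal BMP reader (uncompressed 8-bit palette or 24-bit)
#'
#' @param path BMP file path.
#' @return Numeric grayscale matrix on the 0--255 scale.
#' @export
readBMP <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
  s32 <- function(off) { v <- u32(off); if (v >= 2^31) v - 2^32 else v }
  if (rawToChar(raw[1:2]) != "BM") stop("not a BMP file")
  dataOff <- u32(10)
  hdrSize <- u32(14)
  W <- s32(18); Hs <- s32(22)
  bpp <- u16(28)
  if (u32(30) != 0) stop("compressed BMP is not supported")
  H <- abs(Hs)
  topDown <- Hs < 0
  pal <- NULL
  if (bpp == 8L) {
    nPal <- u32(46); if (nPal == 0) nPal <- 256
    off <- 14 + hdrSize
    pal <- matrix(as.integer(raw[off + seq_len(4 * nPal)]), ncol = 4,
                  byrow = TRUE)   # B, G, R, reserved
  } else if (bpp != 24L) {
    stop("only 8-bit and 24-bit BMP are supported")
  }
  stride <- ((W * bpp / 8 + 3) %/% 4) * 4
  img <- matrix(0, H, W)
  for (r in seq_len(H)) {
    rowOff <- dataOff + (r - 1L) * stride
    if (bpp == 8L) {
      idx <- as.integer(raw[rowOff + seq_len(W)]) + 1L
      v <- 0.299 * pal[idx, 3] + 0.587 * pal[idx, 2] + 0.114 * pal[idx, 1]
    } else {
      b <- as.integer(raw[rowOff + seq_len(3 * W)])
      B <- b[seq(1, 3 * W, 3)]; G <- b[seq(2, 3 * W, 3)]
      R <- b[seq(3, 3 * W, 3)]
      v <- 0.299 * R + 0.587 * G + 0.114 * B
    }
    row <- if (topDown) r else H - r + 1L
    img[row, ] <- v
  }
  img
}

#' Minimal BMP writer (8-bit grayscale palette, uncompressed)
#'
#' @param img numeric matrix on the 0--255 scale.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeBMP <- function(img, path) {
  H <- nrow(img); W <- ncol(img)
  v <- as.integer(pmin(255, pmax(0, roundHalfUp(img))))
  stride <- ((W + 3) %/% 4) * 4
  palette <- as.raw(rbind(0:255, 0:255, 0:255, 0L))
  dataOff <- 14L + 40L + 1024L
  dataSize <- stride * H
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  u32(dataOff + dataSize); u16(0); u16(0); u32(dataOff)
  u32(40); u32(W); u32(H); u16(1); u16(8); u32(0); u32(dataSize)
  u32(2835); u32(2835); u32(256); u32(0)
  writeBin(palette, con)
  m <- matrix(v, H, W)
  pad <- raw(stride - W)
  for (r in H:1) {   # bottom-up
    writeBin(as.raw(m[r, ]), con)
    if (length(pad)) writeBin(pad, con)
  }
  invisible(path)
}

#' Read a frame directory into a FrameSequence
#'
#' Image files (PNG/BMP) are taken in lexicographic filename order. When all
#' basenames are integers they are interpreted as capture timestamps in
#' microseconds (high-speed recorders commonly name frames by timestamp) and
#' the frame rate is estimated from their median spacing; otherwise
#' \code{fps} must be supplied (or defaults to 100).
#'
#' @param path directory containing the frames.
#' @param fps frame rate override.
#' @return A \linkS4class{FrameSequence}.
#' @export
readFrameDirectory <- function(path, fps = NULL) {
  files <- sort(list.files(path, pattern = "\\.(png|bmp)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) stop("no PNG/BMP frames found in ", path)
  base <- tools::file_path_sans_ext(basename(files))
  if (is.null(fps)) {
    if (all(grepl("^[0-9]+$", base)) && length(files) > 1L) {
      ts <- as.numeric(base)
      dt <- stats::median(diff(sort(ts)))
      fps <- if (dt > 0) 1e6 / dt else 100
    } else {
      fps <- 100
    }
  }
  frames <- lapply(files, readFrameImage)
  FrameSequence(frames, fps = fps)
}

#' Write a FrameSequence as a frame directory
#'
#' Filenames are synthesized timestamps in microseconds derived from the
#' frame rate, zero-padded so lexicographic order equals temporal order.
#'
#' @param seq a \linkS4class{FrameSequence}.
#' @param path output directory (created if missing).
#' @param format \code{"png"} or \code{"bmp"}.
#' @return Invisibly, the file paths written.
#' @export
writeFrameDirectory <- function(seq, path, format = c("png", "bmp")) {
  format <- match.arg(format)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  T <- nFrames(seq)
  ts <- roundHalfUp((0:(T - 1L)) * 1e6 / fps(seq))
  files <- file.path(path, sprintf("%012.0f.%s", ts, format))
  for (t in seq_len(T)) {
    m <- frameAt(seq, t - 1L)
    if (format == "png") {
      png::writePNG(pmin(pmax(m / 255, 0), 1), files[t])
    } else {
      writeBMP(m, files[t])
    }
  }
  invisible(files)
}

#' Read landmarks from a pts file
#'
#' Plain-text pts dialect: a \code{version:} line, an \code{n_points:} line,
#' then one \code{x y} pair per line (optionally wrapped in braces).
#'
#' @param path pts file path.
#' @return 68 x 2 landmark matrix.
#' @export
readLandmarksPts <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & lines != "{" & lines != "}"]
  hdr <- grepl(":", lines, fixed = TRUE)
  n <- as.integer(sub(".*n_points:\\s*", "",
                      lines[grepl("^n_points:", lines)][1]))
  pts <- do.call(rbind, lapply(strsplit(lines[!hdr], "\\s+"),
                               function(x) as.numeric(x[1:2])))
  if (!is.na(n) && nrow(pts) != n)
    stop("pts header announces ", n, " points but ", nrow(pts), " found")
  validateLandmarks(pts)
}

#' Write landmarks to a pts file
#'
#' @param landmarks 68 x 2 landmark matrix.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeLandmarksPts <- function(landmarks, path) {
  lm <- validateLandmarks(landmarks)
  writeLines(c("version: 1", sprintf("n_points: %d", nrow(lm)), "{",
               sprintf("%.6f %.6f", lm[, 1], lm[, 2]), "}"), path)
  invisible(path)
}

#' Read landmarks from CSV
#'
#' Columns \code{frame_index, point_index, x, y} (0-based indices). Returns
#' a single landmark matrix when only one frame index is present, otherwise
#' a list of matrices named by frame index.
#'
#' @param path CSV file path.
#' @return 68 x 2 matrix or named list of such matrices.
#' @export
readLandmarksCsv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("frame_index", "point_index", "x", "y")
  if (!all(need %in% names(d)))
    stop("landmark CSV must have columns ", paste(need, collapse = ", "))
  build <- function(dd) {
    m <- matrix(NA_real_, 68L, 2L)
    m[dd$point_index + 1L, ] <- cbind(dd$x, dd$y)
    validateLandmarks(m)
  }
  fr <- sort(unique(d$frame_index))
  if (length(fr) == 1L) return(build(d))
  out <- lapply(fr, function(f) build(d[d$frame_index == f, , drop = FALSE]))
  names(out) <- fr
  out
}

#' Write landmarks to CSV
#'
#' @param landmarks one 68 x 2 matrix or a list of them (per frame).
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeLandmarksCsv <- function(landmarks, path) {
  if (!is.list(landmarks)) landmarks <- list(`0` = landmarks)
  fi <- names(landmarks) %||% as.character(seq_along(landmarks) - 1L)
  rows <- do.call(rbind, lapply(seq_along(landmarks), function(k) {
    lm <- validateLandmarks(landmarks[[k]])
    data.frame(frame_index = as.integer(fi[k]), point_index = 0:67,
               x = lm[, 1], y = lm[, 2])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

.ANN_COLS <- c("subject_id", "sequence_id", "onset", "apex", "offset",
               "label")

#' Read an annotation table
#'
#' CSV with header \code{subject_id, sequence_id, onset, apex, offset,
#' label}; frame indices 0-based inclusive, labels in
#' \{positive, negative, surprise, other\}.
#'
#' @param path CSV file path.
#' @return data.frame of annotations.
#' @export
readAnnotations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(.ANN_COLS %in% names(d)))
    stop("annotation CSV must have columns ",
         paste(.ANN_COLS, collapse = ", "))
  bad <- setdiff(unique(d$label), c(.ME_CLASSES, "other"))
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  d[, .ANN_COLS]
}

#' Write an annotation table
#' @param annotations data.frame with the annotation columns.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeAnnotations <- function(annotations, path) {
  stopifnot(all(.ANN_COLS %in% names(annotations)))
  utils::write.csv(annotations[, .ANN_COLS], path, row.names = FALSE)
  invisible(path)
}

#' Save / load a boosted frame spotter
#'
#' The model file is a versioned serialization carrying the feature (cell)
#' order; loading a file whose cell order does not match the package's
#' canonical order is an error.
#'
#' @param model an \linkS4class{MEDetector}.
#' @param path file path.
#' @return \code{saveDetector} invisibly returns \code{path};
#'   \code{readDetector} returns the \linkS4class{MEDetector}.
#' @export
saveDetector <- function(model, path) {
  stopifnot(is(model, "MEDetector"))
  saveRDS(list(format = "mexpress-detector", version = model@version,
               cellOrder = model@cellOrder, trees = model@trees,
               alphas = model@alphas, depth = model@depth,
               seed = model@seed),
          path)
  invisible(path)
}

#' @rdname saveDetector
#' @export
readDetector <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "mexpress-detector"))
    stop("not a detector model file")
  if (!identical(x$cellOrder, .CELL_NAMES))
    stop("model file cell order does not match this package")
  new("MEDetector", trees = x$trees, alphas = x$alphas,
      cellOrder = x$cellOrder, depth = x$depth, seed = x$seed,
      version = x$version)
}

#' Save / load an expression model (JSON, lossless)
#'
#' Per-class, per-cell means and covariances are written as full-precision
#' JSON; the round trip is lossless.
#'
#' @param model an \linkS4class{ExpressionModel}.
#' @param path file path.
#' @return \code{saveExpressionModel} invisibly returns \code{path};
#'   \code{readExpressionModel} returns the \linkS4class{ExpressionModel}.
#' @export
saveExpressionModel <- function(model, path) {
  stopifnot(is(model, "ExpressionModel"))
  x <- list(format = "mexpress-expression-model", version = model@version,
            cellOrder = model@cellOrder, classes = model@classes,
            nResample = model@nResample, covFloor = model@covFloor,
            counts = as.list(model@counts),
            pairCounts = as.list(model@pairCounts),
            means = lapply(model@means, function(m)
              apply(m, 1, identity, simplify = FALSE)),
            covs = lapply(model@covs, function(l)
              lapply(l, function(S) list(S[1, 1], S[1, 2], S[2, 2]))))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname saveExpressionModel
#' @export
readExpressionModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$format, "mexpress-expression-model"))
    stop("not an expression model file")
  cellOrder <- unlist(x$cellOrder)
  if (!identical(cellOrder, .CELL_NAMES))
    stop("model file cell order does not match this package")
  classes <- unlist(x$classes)
  means <- lapply(x$means, function(m) {
    mm <- do.call(rbind, lapply(m, unlist))
    dimnames(mm) <- list(.CELL_NAMES, c("dx", "dy"))
    mm
  })
  covs <- lapply(x$covs, function(l) {
    out <- lapply(l, function(s) {
      s <- unlist(s)
      matrix(c(s[1], s[2], s[2], s[3]), 2, 2)
    })
    names(out) <- .CELL_NAMES
    out
  })
  new("ExpressionModel", classes = classes,
      means = means[classes], covs = covs[classes],
      counts = unlist(x$counts)[classes],
      pairCounts = unlist(x$pairCounts)[classes],
      cellOrder = cellOrder, nResample = as.integer(x$nResample),
      covFloor = as.numeric(x$covFloor), version = x$version)
}

#' Write a dataset to a directory
#'
#' Layout: \code{annotations.csv}, \code{sequences.csv} (subject_id,
#' sequence_id, dir, fps) and one sub-directory per sequence holding the
#' frame images and a \code{landmarks.pts} file — the same formats the
#' readers consume.
#'
#' @param dataset an \code{meDataset} (see \code{\link{generateDataset}}).
#' @param dir output directory.
#' @param format frame image format.
#' @return Invisibly, \code{dir}.
#' @export
writeDataset <- function(dataset, dir, format = c("png", "bmp")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeAnnotations(dataset$annotations, file.path(dir, "annotations.csv"))
  idx <- data.frame(
    subject_id = vapply(dataset$sequences, `[[`, character(1), "subjectId"),
    sequence_id = vapply(dataset$sequences, `[[`, character(1),
                         "sequenceId"),
    dir = vapply(dataset$sequences, `[[`, character(1), "sequenceId"),
    fps = vapply(dataset$sequences, function(s) fps(s$frames), numeric(1)))
  utils::write.csv(idx, file.path(dir, "sequences.csv"), row.names = FALSE)
  for (s in dataset$sequences) {
    sdir <- file.path(dir, s$sequenceId)
    writeFrameDirectory(s$frames, sdir, format)
    writeLandmarksPts(s$landmarks, file.path(sdir, "landmarks.pts"))
  }
  invisible(dir)
}

#' Read a dataset directory
#'
#' @param dir dataset directory written by \code{\link{writeDataset}}.
#' @return An \code{meDataset} list.
#' @export
readDataset <- function(dir) {
  idx <- utils::read.csv(file.path(dir, "sequences.csv"),
                         stringsAsFactors = FALSE)
  seqs <- list()
  for (k in seq_len(nrow(idx))) {
    sdir <- file.path(dir, idx$dir[k])
    seqs[[idx$sequence_id[k]]] <- list(
      subjectId = idx$subject_id[k],
      sequenceId = idx$sequence_id[k],
      frames = readFrameDirectory(sdir, fps = idx$fps[k]),
      landmarks = readLandmarksPts(file.path(sdir, "landmarks.pts")))
  }
  structure(list(sequences = seqs,
                 annotations = readAnnotations(
                   file.path(dir, "annotations.csv"))),
            class = "meDataset")
}

#' Write pipeline predictions
#'
#' One row per detected micro-expression: \code{sequence_id, start, end,
#' apex, predicted_class, score_positive, score_negative, score_surprise}.
#'
#' @param predictions data.frame of predictions.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writePredictions <- function(predictions, path) {
  utils::write.csv(predictions, path, row.names = FALSE)
  invisible(path)
}
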