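## Orchestration: configuration, leave-one-subject-out protocol,
## detection / recognition runs and the evaluation report.

#' Pipeline configuration
#'
#' Bundles and re-validates every tunable parameter of the descriptor,
#' spotting and recognition stages.
#'
#' @param tau average micro-expression duration in frames.
#' @param eps motion-magnitude normalization offset in frames.
#' @param nResample frames per recognition window.
#' @param delta labeling / matching half-width factor.
#' @param minMicroSz minimum interval size (frames); default
#'   \code{floor(tau/4)}.
#' @param maxDist maximum merge distance (frames); default \code{2 * tau}.
#' @param nEstimators boosted weak learners.
#' @param treeDepth weak-learner depth.
#' @param mergeRule interval merge rule ("gap" or "printed").
#' @param pooling recognition pooling mode ("pool" or "mean").
#' @param covFloor covariance regularization floor (px^2).
#' @param mmBaseline recognition motion-magnitude reference ("eq1" or
#'   "windowStart").
#' @param recogApex apex source for end-to-end recognition ("detected" or
#'   "annotation").
#' @param seed base RNG seed for balancing/training.
#' @return Named list of class \code{mePipelineConfig}.
#' @export
pipelineConfig <- function(tau = 37, eps = 3, nResample = 11, delta = 0.25,
                           minMicroSz = NULL, maxDist = NULL,
                           nEstimators = 35, treeDepth = 1,
                           mergeRule = c("gap", "printed"),
                           pooling = c("pool", "mean"), covFloor = 1e-6,
                           mmBaseline = c("eq1", "windowStart"),
                           recogApex = c("detected", "annotation"),
                           seed = 1) {
  dp <- descriptorParams(tau, eps, nResample, delta)
  cfg <- list(
    tau = dp$tau, eps = dp$eps, nResample = dp$nResample, delta = dp$delta,
    minMicroSz = as.integer(minMicroSz %||% (dp$tau %/% 4L)),
    maxDist = as.integer(maxDist %||% (2L * dp$tau)),
    nEstimators = as.integer(nEstimators),
    treeDepth = as.integer(treeDepth),
    mergeRule = match.arg(mergeRule),
    pooling = match.arg(pooling),
    covFloor = as.numeric(covFloor),
    mmBaseline = match.arg(mmBaseline),
    recogApex = match.arg(recogApex),
    seed = as.integer(seed))
  if (cfg$minMicroSz < 0L) stop("minMicroSz must be >= 0")
  if (cfg$maxDist < 1L) stop("maxDist must be >= 1")
  if (cfg$nEstimators < 1L) stop("nEstimators must be >= 1")
  if (cfg$treeDepth < 1L) stop("treeDepth must be >= 1")
  class(cfg) <- "mePipelineConfig"
  cfg
}

.cfgParams <- function(cfg)
  descriptorParams(cfg$tau, cfg$eps, cfg$nResample, cfg$delta)

#' Read / write a pipeline configuration file (YAML)
#'
#' @param path configuration file path.
#' @return \code{readPipelineConfig} returns a re-validated
#'   \code{mePipelineConfig}; \code{writePipelineConfig} invisibly returns
#'   \code{path}.
#' @export
readPipelineConfig <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipelineConfig, x)
}

#' @rdname readPipelineConfig
#' @param cfg an \code{mePipelineConfig}.
#' @export
writePipelineConfig <- function(cfg, path) {
  stopifnot(inherits(cfg, "mePipelineConfig"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Leave-one-subject-out folds
#'
#' One fold per subject; each subject is the test subject exactly once and
#' never appears in its own training set.
#'
#' @param subjects character vector of subject ids (one entry per sequence
#'   or the unique subjects themselves).
#' @return list of folds, each \code{list(train =, test =)} of subject ids.
#' @export
losoSplit <- function(subjects) {
  subs <- unique(as.character(subjects))
  if (length(subs) < 2L)
    stop("leave-one-subject-out needs at least 2 subjects")
  lapply(subs, function(s) list(train = setdiff(subs, s), test = s))
}

# Per-sequence preprocessing shared by detection and evaluation: roll
# normalization, cell grid, per-cell signals, detection features and ground
# truth. Sequences shorter than tau are skipped (returned as NULL) with a
# message.
.prepSequence <- function(s, cfg, annotations = NULL) {
  params <- .cfgParams(cfg)
  if (nFrames(s$frames) < cfg$tau) {
    message("sequence ", s$sequenceId, " is shorter than tau (",
            nFrames(s$frames), " < ", cfg$tau, "); skipped")
    return(NULL)
  }
  norm <- normalizeSequence(s$frames, s$landmarks)
  grid <- defineCells(norm$landmarks)
  signals <- computeCellSignals(norm$seq, grid, params)
  ann <- NULL
  if (!is.null(annotations))
    ann <- annotations[annotations$sequence_id == s$sequenceId, ,
                       drop = FALSE]
  list(sequenceId = s$sequenceId, subjectId = s$subjectId,
       seq = norm$seq, grid = grid, signals = signals,
       features = detectionFeatures(signals, cfg$tau),
       truth = ann,
       gtLabels = if (!is.null(ann))
         labelFrames(nFrames(s$frames), ann$apex, cfg$tau, cfg$delta))
}

#' Detect micro-expression intervals in sequences
#'
#' Runs the full spotting path per sequence: roll normalization, cell
#' placement, per-cell signals, per-frame boosted classification and
#' interval post-processing. Sequences shorter than \code{tau} are skipped
#' with a message.
#'
#' @param sequences list of sequences (each \code{list(subjectId,
#'   sequenceId, frames, landmarks)}), e.g. \code{dataset$sequences}.
#' @param cfg an \code{\link{pipelineConfig}}.
#' @param model a trained \linkS4class{MEDetector}.
#' @return Named list (by sequence id) of interval data.frames from
#'   \code{\link{postprocessIntervals}}.
#' @export
runDetection <- function(sequences, cfg, model) {
  out <- list()
  for (s in sequences) {
    prep <- .prepSequence(s, cfg)
    if (is.null(prep)) next
    raw <- predictFrames(model, prep$signals, cfg$tau)
    out[[s$sequenceId]] <- postprocessIntervals(
      raw, cfg$minMicroSz, cfg$maxDist, cfg$mergeRule)
  }
  out
}

#' Run detection plus recognition end-to-end
#'
#' Detected apexes are fed to the displacement-feature extractor and the
#' Gaussian classifier; one prediction row is emitted per detected
#' micro-expression.
#'
#' @param sequences list of sequences (as in \code{\link{runDetection}}).
#' @param cfg an \code{\link{pipelineConfig}}.
#' @param spotter a trained \linkS4class{MEDetector}.
#' @param recognizer a fitted \linkS4class{ExpressionModel}.
#' @return data.frame: \code{sequence_id, start, end, apex,
#'   predicted_class, score_positive, score_negative, score_surprise}.
#' @export
runFullPipeline <- function(sequences, cfg, spotter, recognizer) {
  params <- .cfgParams(cfg)
  rows <- list()
  for (s in sequences) {
    prep <- .prepSequence(s, cfg)
    if (is.null(prep)) next
    raw <- predictFrames(spotter, prep$signals, cfg$tau)
    ints <- postprocessIntervals(raw, cfg$minMicroSz, cfg$maxDist,
                                 cfg$mergeRule)
    for (k in seq_len(nrow(ints))) {
      feat <- displacementFeatures(prep$seq, prep$grid, ints$apex[k],
                                   params, cfg$mmBaseline)
      cl <- classifyExpression(feat, recognizer, cfg$pooling)
      sc <- setNames(rep(NA_real_, 3), .ME_CLASSES)
      sc[names(cl$scores)] <- cl$scores
      rows[[length(rows) + 1L]] <- data.frame(
        sequence_id = s$sequenceId, start = ints$start[k],
        end = ints$end[k], apex = ints$apex[k],
        predicted_class = cl$class,
        score_positive = sc[["positive"]],
        score_negative = sc[["negative"]],
        score_surprise = sc[["surprise"]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), apex = integer(0),
                      predicted_class = character(0),
                      score_positive = numeric(0),
                      score_negative = numeric(0),
                      score_surprise = numeric(0)))
  do.call(rbind, rows)
}

# fit the fold recognizer from annotated training sequences; classes with
# no training sequence are dropped with a warning.
.fitFoldRecognizer <- function(preps, cfg) {
  params <- .cfgParams(cfg)
  byClass <- setNames(vector("list", 3L), .ME_CLASSES)
  for (p in preps) {
    tr <- p$truth
    for (k in seq_len(nrow(tr))) {
      if (!tr$label[k] %in% .ME_CLASSES) next
      feat <- displacementFeatures(p$seq, p$grid, tr$apex[k], params,
                                   cfg$mmBaseline)
      byClass[[tr$label[k]]] <- c(byClass[[tr$label[k]]], list(feat))
    }
  }
  have <- .ME_CLASSES[vapply(byClass, function(x) length(x) > 0, logical(1))]
  if (length(have) < length(.ME_CLASSES))
    warning("classes absent from this training fold: ",
            paste(setdiff(.ME_CLASSES, have), collapse = ", "),
            "; recognizer trained on the remaining classes")
  if (length(have) == 0L) return(NULL)
  fitExpressionModels(byClass[have], classes = have,
                      covFloor = cfg$covFloor)
}

.confusion2 <- function() matrix(0, 2, 2, dimnames = list(
  actual = c("ME", "nonME"), predicted = c("ME", "nonME")))

.accumulate2 <- function(M, truth, pred) {
  M["ME", "ME"] <- M["ME", "ME"] + sum(truth & pred)
  M["ME", "nonME"] <- M["ME", "nonME"] + sum(truth & !pred)
  M["nonME", "ME"] <- M["nonME", "ME"] + sum(!truth & pred)
  M["nonME", "nonME"] <- M["nonME", "nonME"] + sum(!truth & !pred)
  M
}

.rowPercent <- function(M) {
  s <- rowSums(M)
  sweep(M, 1, ifelse(s > 0, s, 1), "/") * 100
}

# macro precision / recall / F1 and accuracy from a square confusion matrix
.classMetrics <- function(M) {
  tp <- diag(M)
  prec <- ifelse(colSums(M) > 0, tp / colSums(M), NA_real_)
  rec <- ifelse(rowSums(M) > 0, tp / rowSums(M), NA_real_)
  f1 <- ifelse(!is.na(prec) & !is.na(rec) & (prec + rec) > 0,
               2 * prec * rec / (prec + rec), NA_real_)
  list(accuracy = if (sum(M) > 0) sum(tp) / sum(M) else NA_real_,
       precision = mean(prec, na.rm = TRUE),
       recall = mean(rec, na.rm = TRUE),
       f1 = mean(f1, na.rm = TRUE),
       perClassPrecision = prec, perClassRecall = rec, perClassF1 = f1)
}

#' Leave-one-subject-out evaluation of the full pipeline
#'
#' For every fold a spotter is trained on the balanced frame features of the
#' training subjects and a recognizer on the displacement features at their
#' annotated apexes; both are then applied to the held-out subject. The
#' report aggregates (a) the per-frame confusion matrix, both for raw
#' classifier output and after interval post-processing, (b) apex-based
#' per-emotion detection rates with the false-positive rate (false apexes
#' over total ground-truth micro-expressions), and (c) the 3-class
#' recognition confusion with accuracy and macro precision/recall/F1.
#' Recognition at test time uses detected apexes
#' (\code{cfg$recogApex = "detected"}, matched one-to-one to ground truth)
#' or annotated apexes (\code{"annotation"}).
#'
#' @param dataset an \code{meDataset} (see \code{\link{generateDataset}} /
#'   \code{\link{readDataset}}).
#' @param cfg an \code{\link{pipelineConfig}}.
#' @param seed base seed for the fold-level balancing.
#' @return list of class \code{meEvalReport}.
#' @export
evaluatePipeline <- function(dataset, cfg = pipelineConfig(), seed = 1) {
  preps <- list()
  for (s in dataset$sequences) {
    p <- .prepSequence(s, cfg, dataset$annotations)
    if (!is.null(p)) preps[[p$sequenceId]] <- p
  }
  if (!length(preps)) stop("no usable sequences")
  subjects <- vapply(preps, `[[`, character(1), "subjectId")
  folds <- losoSplit(subjects)
  rawConf <- .confusion2(); postConf <- .confusion2()
  recogConf <- matrix(0, 3, 3, dimnames = list(actual = .ME_CLASSES,
                                               predicted = .ME_CLASSES))
  TP <- 0L; FP <- 0L
  truthTotal <- setNames(integer(3), .ME_CLASSES)
  truthMatchedByClass <- setNames(integer(3), .ME_CLASSES)
  foldSummaries <- list()
  params <- .cfgParams(cfg)
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    trIdx <- names(preps)[subjects %in% fold$train]
    teIdx <- names(preps)[subjects == fold$test]
    Xtr <- do.call(rbind, lapply(preps[trIdx], `[[`, "features"))
    ytr <- unlist(lapply(preps[trIdx], `[[`, "gtLabels"), use.names = FALSE)
    bal <- balanceTrainingSet(Xtr, ytr, seed = seed + f)
    spotter <- trainSpotter(bal$features, bal$labels, cfg$nEstimators,
                            cfg$treeDepth, seed = seed + f)
    recognizer <- .fitFoldRecognizer(preps[trIdx], cfg)
    foldTP <- 0L; foldFP <- 0L; foldTruth <- 0L
    for (sid in teIdx) {
      p <- preps[[sid]]
      raw <- predictFrames(spotter, p$signals, cfg$tau)
      ints <- postprocessIntervals(raw, cfg$minMicroSz, cfg$maxDist,
                                   cfg$mergeRule)
      post <- rep(FALSE, length(raw))
      for (k in seq_len(nrow(ints)))
        post[(ints$start[k]:ints$end[k]) + 1L] <- TRUE
      rawConf <- .accumulate2(rawConf, p$gtLabels, raw)
      postConf <- .accumulate2(postConf, p$gtLabels, post)
      truthApex <- p$truth$apex
      truthClass <- p$truth$label
      sc <- scoreSpotting(ints, truthApex, cfg$tau, cfg$delta)
      TP <- TP + sc$TP; FP <- FP + sc$FP
      foldTP <- foldTP + sc$TP; foldFP <- foldFP + sc$FP
      foldTruth <- foldTruth + sc$nTruth
      for (cl in .ME_CLASSES) {
        truthTotal[cl] <- truthTotal[cl] + sum(truthClass == cl)
        truthMatchedByClass[cl] <- truthMatchedByClass[cl] +
          sum(sc$truthMatched & truthClass == cl)
      }
      if (!is.null(recognizer)) {
        if (cfg$recogApex == "detected") {
          for (di in which(!is.na(sc$detMatched))) {
            ti <- sc$detMatched[di]
            if (!truthClass[ti] %in% .ME_CLASSES) next
            feat <- displacementFeatures(p$seq, p$grid, ints$apex[di],
                                         params, cfg$mmBaseline)
            pred <- classifyExpression(feat, recognizer, cfg$pooling)$class
            recogConf[truthClass[ti], pred] <-
              recogConf[truthClass[ti], pred] + 1
          }
        } else {
          for (k in seq_len(nrow(p$truth))) {
            if (!truthClass[k] %in% .ME_CLASSES) next
            feat <- displacementFeatures(p$seq, p$grid, truthApex[k],
                                         params, cfg$mmBaseline)
            pred <- classifyExpression(feat, recognizer, cfg$pooling)$class
            recogConf[truthClass[k], pred] <-
              recogConf[truthClass[k], pred] + 1
          }
        }
      }
    }
    foldSummaries[[f]] <- data.frame(
      fold = f, testSubject = fold$test, nTruth = foldTruth,
      TP = foldTP, FP = foldFP)
  }
  nTruth <- sum(truthTotal)
  recogMetrics <- .classMetrics(recogConf)
  report <- list(
    perFrame = list(
      rawConfusion = rawConf, postConfusion = postConf,
      rawConfusionPct = .rowPercent(rawConf),
      postConfusionPct = .rowPercent(postConf),
      rawAccuracy = sum(diag(rawConf)) / sum(rawConf),
      postAccuracy = sum(diag(postConf)) / sum(postConf)),
    detection = list(
      TP = TP, FP = FP, nTruth = nTruth,
      rate = if (nTruth) sum(truthMatchedByClass) / nTruth else NA_real_,
      perClassRate = ifelse(truthTotal > 0,
                            truthMatchedByClass / truthTotal, NA_real_),
      falsePositiveRate = if (nTruth) FP / nTruth else NA_real_),
    recognition = c(list(confusion = recogConf,
                         confusionPct = .rowPercent(recogConf)),
                    recogMetrics),
    folds = do.call(rbind, foldSummaries),
    config = cfg)
  class(report) <- "meEvalReport"
  report
}

#' Leave-one-subject-out evaluation of recognition only
#'
#' Skips the spotting stage and evaluates the Gaussian recognizer on
#' annotated apexes alone (training and test), which isolates the
#' recognition question from detection quality.
#'
#' @inheritParams evaluatePipeline
#' @return list with \code{confusion}, \code{accuracy}, macro
#'   \code{precision}/\code{recall}/\code{f1} and \code{n} test events.
#' @export
evaluateRecognition <- function(dataset, cfg = pipelineConfig(), seed = 1) {
  params <- .cfgParams(cfg)
  preps <- list()
  for (s in dataset$sequences) {
    ann <- dataset$annotations
    ann <- ann[ann$sequence_id == s$sequenceId & ann$label %in% .ME_CLASSES,
               , drop = FALSE]
    if (!nrow(ann)) next
    if (nFrames(s$frames) < cfg$tau) next
    norm <- normalizeSequence(s$frames, s$landmarks)
    grid <- defineCells(norm$landmarks)
    feats <- lapply(ann$apex, function(a)
      displacementFeatures(norm$seq, grid, a, params, cfg$mmBaseline))
    preps[[s$sequenceId]] <- list(subjectId = s$subjectId,
                                  labels = ann$label, feats = feats)
  }
  if (!length(preps)) stop("no annotated sequences")
  subjects <- vapply(preps, `[[`, character(1), "subjectId")
  folds <- losoSplit(subjects)
  conf <- matrix(0, 3, 3, dimnames = list(actual = .ME_CLASSES,
                                          predicted = .ME_CLASSES))
  for (fold in folds) {
    byClass <- setNames(vector("list", 3L), .ME_CLASSES)
    for (sid in names(preps)[subjects %in% fold$train]) {
      p <- preps[[sid]]
      for (k in seq_along(p$labels))
        byClass[[p$labels[k]]] <- c(byClass[[p$labels[k]]],
                                    list(p$feats[[k]]))
    }
    have <- .ME_CLASSES[vapply(byClass, function(x) length(x) > 0,
                               logical(1))]
    if (!length(have)) next
    model <- fitExpressionModels(byClass[have], classes = have,
                                 covFloor = cfg$covFloor)
    for (sid in names(preps)[subjects == fold$test]) {
      p <- preps[[sid]]
      for (k in seq_along(p$labels)) {
        pred <- classifyExpression(p$feats[[k]], model, cfg$pooling)$class
        conf[p$labels[k], pred] <- conf[p$labels[k], pred] + 1
      }
    }
  }
  c(list(confusion = conf, n = sum(conf)), .classMetrics(conf))
}

#' Train a spotter on every sequence of a dataset
#'
#' Convenience wrapper: extracts windowed min/max features and apex-derived
#' labels from all (usable) sequences, balances the classes and trains the
#' boosted frame classifier. Used by the command-line interface; the
#' leave-one-subject-out loop in \code{\link{evaluatePipeline}} does the
#' same per fold.
#'
#' @param dataset an \code{meDataset}.
#' @param cfg an \code{\link{pipelineConfig}}.
#' @param seed balancing seed.
#' @return An \linkS4class{MEDetector}.
#' @export
fitDatasetSpotter <- function(dataset, cfg = pipelineConfig(), seed = 1) {
  X <- NULL; y <- NULL
  for (s in dataset$sequences) {
    p <- .prepSequence(s, cfg, dataset$annotations)
    if (is.null(p)) next
    X <- rbind(X, p$features)
    y <- c(y, p$gtLabels)
  }
  if (is.null(X)) stop("no usable sequences")
  bal <- balanceTrainingSet(X, y, seed)
  trainSpotter(bal$features, bal$labels, cfg$nEstimators, cfg$treeDepth,
               seed)
}

#' Fit the Gaussian recognizer on every annotated event of a dataset
#'
#' @param dataset an \code{meDataset}.
#' @param cfg an \code{\link{pipelineConfig}}.
#' @return An \linkS4class{ExpressionModel}.
#' @export
fitDatasetRecognizer <- function(dataset, cfg = pipelineConfig()) {
  params <- .cfgParams(cfg)
  byClass <- setNames(vector("list", 3L), .ME_CLASSES)
  for (s in dataset$sequences) {
    if (nFrames(s$frames) < cfg$tau) next
    ann <- dataset$annotations
    ann <- ann[ann$sequence_id == s$sequenceId & ann$label %in% .ME_CLASSES,
               , drop = FALSE]
    if (!nrow(ann)) next
    norm <- normalizeSequence(s$frames, s$landmarks)
    grid <- defineCells(norm$landmarks)
    for (k in seq_len(nrow(ann))) {
      f <- displacementFeatures(norm$seq, grid, ann$apex[k], params,
                                cfg$mmBaseline)
      byClass[[ann$label[k]]] <- c(byClass[[ann$label[k]]], list(f))
    }
  }
  have <- .ME_CLASSES[vapply(byClass, function(x) length(x) > 0, logical(1))]
  if (!length(have)) stop("no annotated events to train on")
  if (length(have) < 3L)
    warning("classes absent from the training data: ",
            paste(setdiff(.ME_CLASSES, have), collapse = ", "))
  fitExpressionModels(byClass[have], classes = have, covFloor = cfg$covFloor)
}

# half-up percentage formatting used by the report printer
.pct <- function(x) sprintf("%.2f%%", roundHalfUp(x * 10000) / 100)

#' @export
print.meEvalReport <- function(x, ...) {
  cat("Leave-one-subject-out evaluation\n")
  cat("\nPer-frame (after post-processing), row-normalized:\n")
  print(round(x$perFrame$postConfusionPct, 2))
  cat("per-frame accuracy:", .pct(x$perFrame$postAccuracy),
      "(raw classifier:", .pct(x$perFrame$rawAccuracy), ")\n")
  cat("\nPer-emotion detection: rate", .pct(x$detection$rate),
      " FPR", .pct(x$detection$falsePositiveRate),
      sprintf(" (TP %d / FP %d / truth %d)\n",
              x$detection$TP, x$detection$FP, x$detection$nTruth))
  print(round(100 * x$detection$perClassRate, 2))
  cat("\nRecognition confusion, row-normalized:\n")
  print(round(x$recognition$confusionPct, 2))
  cat("accuracy:", .pct(x$recognition$accuracy),
      " macro P/R/F1:", .pct(x$recognition$precision),
      .pct(x$recognition$recall), .pct(x$recognition$f1), "\n")
  invisible(x)
}
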