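## Micro-expression recognition: per-class bivariate Gaussian models over
## the per-cell weighted-centroid displacement pairs; classification sums
## log-densities over cells (and pairs) and takes the argmax class.

#' Log-density of the bivariate normal distribution
#'
#' \code{-log(2*pi) - 0.5*log(det(Sigma)) - 0.5*(x-mu)' Sigma^{-1} (x-mu)}
#' for the 2-dimensional case (the general k-dimensional form is used when
#' \code{length(mu) != 2}).
#'
#' @param x observation vector.
#' @param mu mean vector.
#' @param sigma symmetric positive-definite covariance matrix.
#' @return Scalar log-density.
#' @export
#' @examples
#' mvnLogpdf(c(0, 0), c(0, 0), diag(2))  # -log(2*pi)
mvnLogpdf <- function(x, mu, sigma) {
  k <- length(mu)
  ch <- tryCatch(chol(sigma),
                 error = function(e) stop("covariance is not positive definite"))
  z <- backsolve(ch, x - mu, transpose = TRUE)
  -0.5 * k * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z * z)
}

# Pool the displacement pairs of one cell across a list of feature arrays.
.poolCellPairs <- function(featureList, ci) {
  do.call(rbind, lapply(featureList, function(a) {
    m <- a[ci, , , drop = FALSE]
    matrix(m, ncol = 2L, dimnames = list(NULL, c("dx", "dy")))
  }))
}

#' Fit per-class Gaussian expression models
#'
#' For each class, the displacement pairs of every training sequence are
#' pooled per cell as i.i.d. observations; the per-cell model is the sample
#' mean and the unbiased sample covariance plus a ridge
#' \code{covFloor * I} that keeps degenerate (e.g. identical) training
#' displacements positive definite.
#'
#' @param featuresByClass named list (class -> list of displacement feature
#'   arrays as produced by \code{\link{displacementFeatures}}).
#' @param classes classes to model, in tie-break order. Defaults to
#'   \code{\link{expressionClasses}}; every listed class must have at least
#'   one training sequence (and at least 2 pooled pairs).
#' @param covFloor covariance regularization floor in px^2.
#' @return An \linkS4class{ExpressionModel}.
#' @export
fitExpressionModels <- function(featuresByClass,
                                classes = expressionClasses(),
                                covFloor = 1e-6) {
  means <- list(); covs <- list()
  counts <- integer(0); pairCounts <- integer(0)
  nres <- NA_integer_
  for (e in classes) {
    fl <- featuresByClass[[e]]
    if (is.null(fl) || length(fl) == 0L)
      stop("no training sequences for class '", e, "'")
    nres <- as.integer(dim(fl[[1]])[2] + 1L)
    mu <- matrix(NA_real_, 10L, 2L,
                 dimnames = list(.CELL_NAMES, c("dx", "dy")))
    Sg <- vector("list", 10L)
    names(Sg) <- .CELL_NAMES
    np <- 0L
    for (ci in 1:10) {
      P <- .poolCellPairs(fl, ci)
      if (anyNA(P) || any(!is.finite(P)))
        stop("non-finite displacement pairs for class '", e, "'")
      if (nrow(P) < 2L)
        stop("need at least 2 displacement pairs per class; class '", e,
             "' has ", nrow(P))
      mu[ci, ] <- colMeans(P)
      Sg[[ci]] <- unname(stats::cov(P)) + covFloor * diag(2)
      np <- nrow(P)
    }
    means[[e]] <- mu
    covs[[e]] <- Sg
    counts[e] <- length(fl)
    pairCounts[e] <- np
  }
  new("ExpressionModel", classes = classes, means = means, covs = covs,
      counts = counts, pairCounts = pairCounts, cellOrder = .CELL_NAMES,
      nResample = nres, covFloor = as.numeric(covFloor), version = "1")
}

#' Classify a micro-expression from its displacement features
#'
#' The score of a class is the sum over cells (and, in the default pooling
#' mode, over the cell's displacement pairs) of the bivariate normal
#' log-density under that class's per-cell model; probabilities are
#' logarithmized for numerical stability. The predicted class attains the
#' maximal score, with ties broken deterministically by the model's class
#' order (positive before negative before surprise).
#'
#' @param feature displacement feature array from
#'   \code{\link{displacementFeatures}}.
#' @param model an \linkS4class{ExpressionModel}.
#' @param pooling \code{"pool"} (each displacement pair is one observation;
#'   default) or \code{"mean"} (score the per-cell mean displacement once).
#' @return list with \code{scores} (named per class) and \code{class}.
#' @export
classifyExpression <- function(feature, model, pooling = c("pool", "mean")) {
  stopifnot(is(model, "ExpressionModel"))
  pooling <- match.arg(pooling)
  cells <- dimnames(feature)[[1]]
  if (is.null(cells) || !identical(cells, model@cellOrder))
    stop("feature cell order does not match the model")
  scores <- vapply(model@classes, function(e) {
    s <- 0
    for (ci in 1:10) {
      P <- matrix(feature[ci, , , drop = FALSE], ncol = 2L)
      mu <- model@means[[e]][ci, ]
      Sg <- model@covs[[e]][[ci]]
      if (pooling == "pool") {
        for (r in seq_len(nrow(P))) s <- s + mvnLogpdf(P[r, ], mu, Sg)
      } else {
        s <- s + mvnLogpdf(colMeans(P), mu, Sg)
      }
    }
    s
  }, numeric(1))
  list(scores = scores, class = model@classes[which.max(scores)])
}
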