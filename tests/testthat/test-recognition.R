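test_that("bivariate normal log-density matches closed forms and an
           integration-normalized oracle", {
  expect_equal(mvnLogpdf(c(0, 0), c(0, 0), diag(2)), -log(2 * pi),
               tolerance = 1e-12)
  expect_equal(mvnLogpdf(c(1, 0), c(0, 0), diag(2)), -log(2 * pi) - 0.5,
               tolerance = 1e-12)

  # oracle: unnormalized kernel normalized by adaptive 2D quadrature
  set.seed(31)
  for (k in 1:8) {
    S <- randomSPD()
    mu <- rnorm(2)
    x <- rnorm(2, sd = 2)
    kern <- function(u, v) {
      d <- rbind(u - mu[1], v - mu[2])
      Si <- solve(S)
      exp(-0.5 * (Si[1, 1] * d[1, ]^2 + 2 * Si[1, 2] * d[1, ] * d[2, ] +
                    Si[2, 2] * d[2, ]^2))
    }
    Z <- stats::integrate(function(u) {
      vapply(u, function(ui) stats::integrate(function(v) kern(ui, v),
        -Inf, Inf, rel.tol = 1e-12)$value, numeric(1))
    }, -Inf, Inf, rel.tol = 1e-12)$value
    want <- log(kern(x[1], x[2])) - log(Z)
    expect_equal(mvnLogpdf(x, mu, S), want, tolerance = 1e-9)
  }

  expect_error(mvnLogpdf(c(0, 0), c(0, 0),
                         matrix(c(1, 2, 2, 1), 2, 2)),
               "positive definite")
})

test_that("model fitting recovers known Gaussian displacement statistics", {
  set.seed(42)
  mu <- c(3, -1)
  S <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  ch <- chol(S)
  # 50 sequences x 10 pairs = 500 pooled pairs per cell
  feats <- lapply(1:50, function(i) {
    a <- array(NA_real_, c(10, 10, 2),
               dimnames = list(cellNames(), NULL, c("dx", "dy")))
    for (ci in 1:10)
      a[ci, , ] <- matrix(rnorm(20), 10, 2) %*% ch +
        matrix(mu, 10, 2, byrow = TRUE)
    a
  })
  m <- fitExpressionModels(list(positive = feats, negative = feats,
                                surprise = feats))
  # the known-Gaussian example at n = 500: tolerances follow standard-error
  # bounds for a single recovery, so the covariance is checked on one cell
  for (ci in 1:10) expect_lt(max(abs(m@means$positive[ci, ] - mu)), 0.2)
  expect_lt(max(abs(m@covs$positive[[1]] - S)), 0.3)
  expect_identical(unname(m@pairCounts["positive"]), 500L)

  # identical training displacements collapse to the ridge floor exactly
  const <- lapply(1:3, function(i) {
    a <- array(0.7, c(10, 10, 2),
               dimnames = list(cellNames(), NULL, c("dx", "dy")))
    a
  })
  mc <- fitExpressionModels(list(positive = const, negative = const,
                                 surprise = const), covFloor = 1e-6)
  expect_identical(mc@covs$positive[[1]], 1e-6 * diag(2))

  # order invariance of the moments
  mp <- fitExpressionModels(list(positive = rev(feats), negative = feats,
                                 surprise = feats))
  expect_equal(mp@means$positive, m@means$positive)
  expect_equal(mp@covs$positive, m@covs$positive)

  expect_error(fitExpressionModels(list(positive = feats,
                                        negative = feats)),
               "surprise")
})

test_that("classification takes the maximal summed log-density with a
           deterministic tie-break", {
  set.seed(9)
  m <- randomModel()

  # a feature equal to one class's means is assigned that class when the
  # classes are far apart
  sep <- m
  for (e in sep@classes)
    sep@means[[e]] <- sep@means[[e]] +
      30 * (match(e, sep@classes) - 2) * matrix(1, 10, 2)
  for (e in sep@classes) {
    f <- aperm(array(sep@means[[e]], c(10, 2, 10)), c(1, 3, 2))
    dimnames(f) <- list(cellNames(), NULL, c("dx", "dy"))
    expect_identical(classifyExpression(f, sep)$class, e)
  }

  # identical class models tie exactly; first class in fixed order wins
  tied <- m
  tied@means$negative <- tied@means$positive
  tied@covs$negative <- tied@covs$positive
  f <- randomFeature()
  sc <- classifyExpression(f, tied)$scores
  expect_identical(sc[["positive"]], sc[["negative"]])
  tiedAll <- tied
  tiedAll@means$surprise <- tied@means$positive
  tiedAll@covs$surprise <- tied@covs$positive
  expect_identical(classifyExpression(f, tiedAll)$class, "positive")

  # argmax agrees with the eigen-based enumeration oracle
  for (k in 1:60) {
    mk <- randomModel()
    fk <- randomFeature()
    expect_identical(classifyExpression(fk, mk)$class,
                     bruteClassify(fk, mk))
  }

  # cell-order mismatch is an error
  bad <- randomFeature()
  dimnames(bad)[[1]] <- rev(cellNames())
  expect_error(classifyExpression(bad, m), "cell order")
})

test_that("scores are invariant under relabeling data across cells", {
  set.seed(14)
  m <- randomModel()
  f <- randomFeature()
  perm <- sample(10)
  m2 <- m
  for (e in m@classes) {
    m2@means[[e]] <- m@means[[e]][perm, ]
    rownames(m2@means[[e]]) <- cellNames()
    m2@covs[[e]] <- m@covs[[e]][perm]
    names(m2@covs[[e]]) <- cellNames()
  }
  f2 <- f[perm, , ]
  dimnames(f2)[[1]] <- cellNames()
  expect_equal(classifyExpression(f, m)$scores,
               classifyExpression(f2, m2)$scores)
})

test_that("well-separated synthetic classes classify near-perfectly and
           zero separation collapses to chance", {
  set.seed(123)
  gen <- function(sepScale) {
    dirs <- list(positive = c(1, 0), negative = c(-0.5, 0.87),
                 surprise = c(-0.5, -0.87))
    sigma <- 0.5
    lapply(dirs, function(d) {
      lapply(1:50, function(i) {
        a <- array(NA_real_, c(10, 10, 2),
                   dimnames = list(cellNames(), NULL, c("dx", "dy")))
        for (ci in 1:10)
          a[ci, , ] <- matrix(rnorm(20, sd = sigma), 10, 2) +
            matrix(sepScale * 3 * sigma * d, 10, 2, byrow = TRUE)
        a
      })
    })
  }
  evalAcc <- function(sepScale) {
    d <- gen(sepScale)
    train <- lapply(d, function(x) x[1:25])
    m <- fitExpressionModels(train)
    preds <- unlist(lapply(names(d), function(e)
      vapply(d[[e]][26:50],
             function(f) classifyExpression(f, m)$class == e, logical(1))))
    mean(preds)
  }
  expect_gte(evalAcc(1), 0.95)      # >= 3 sigma mean separation per cell
  accNull <- evalAcc(0)
  expect_gte(accNull, 0.18); expect_lte(accNull, 0.49)
})

test_that("fitting then scoring the training set never gives -Inf", {
  set.seed(6)
  feats <- lapply(1:4, function(i) randomFeature())
  m <- fitExpressionModels(list(positive = feats, negative = feats,
                                surprise = feats))
  for (f in feats)
    expect_true(all(is.finite(classifyExpression(f, m)$scores)))
})
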