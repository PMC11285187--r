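# Lasso surrogate: splitting, penalty solutions, fidelity, ICC.

test_that("subject split is an exact, deterministic, leak-free partition", {
  ids10 <- sprintf("s%02d", 1:10)
  sp <- splitBySubject(ids10, 0.70, seed = 1)
  expect_length(sp$train, 7)
  expect_length(sp$validation, 3)
  expect_identical(sp, splitBySubject(ids10, 0.70, seed = 1))
  expect_error(splitBySubject(ids10, 1.2), "fraction")
  expect_error(splitBySubject("only_one", 0.7), "at least 2")

  set.seed(2)
  for (r in 1:100) {
    n <- sample(5:60, 1)
    ids <- sprintf("t%03d", sample.int(500, n))
    frac <- runif(1, 0.2, 0.9)
    sp <- splitBySubject(ids, frac, seed = r)
    expect_length(intersect(sp$train, sp$validation), 0)
    expect_setequal(c(sp$train, sp$validation), ids)
    expect_lte(abs(length(sp$train) - frac * n), 1)
  }
})

test_that("lasso reduces to OLS at lambda = 0", {
  set.seed(11)
  n <- 200; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  X <- scale(X, scale = apply(X, 2, function(v) sqrt(mean((v - mean(v))^2))))
  y <- X %*% runif(p, -1, 1) + rnorm(n, 0, 0.3)
  fit <- fitLasso(X, y, lambda = 0)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(fit$coef), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(ols[1]), tolerance = 1e-6)
})

test_that("lasso is identically zero at and above lambda_max", {
  set.seed(12)
  n <- 150; p <- 5
  X <- scale(matrix(rnorm(n * p), n, p))
  y <- rnorm(n)
  lmax <- max(abs(crossprod(X, y - mean(y)))) / n
  fit <- fitLasso(X, y, lambda = lmax * 1.0001)
  expect_equal(unname(fit$coef), rep(0, p))
  expect_equal(fit$intercept, mean(y))
})

test_that("univariate lasso equals the closed-form soft threshold", {
  # build x, y with rho = x' (y - ybar) / n = 0.5 exactly
  n <- 100
  x <- rep(c(1, -1), n / 2)                      # mean 0, 1/n variance 1
  y <- 0.5 * x
  fit <- fitLasso(cbind(x), y, lambda = 0.2)
  expect_equal(unname(fit$coef), 0.3, tolerance = 1e-12)
  fit2 <- fitLasso(cbind(x), y, lambda = 0.6)    # above |rho|
  expect_equal(unname(fit2$coef), 0)
  expect_error(fitLasso(cbind(c(NA, x[-1])), y, 0.1), "NaN/NA")
  expect_warning(fitLasso(cbind(x, rep(2, n)), y, 0.1), "zero-variance")
})

test_that("sparsity is non-increasing in lambda", {
  set.seed(13)
  n <- 120; p <- 20
  X <- scale(matrix(rnorm(n * p), n, p))
  y <- X[, 1:4] %*% c(2, -1.5, 1, -1) + rnorm(n)
  grid <- 10^seq(-3, 0.5, length.out = 12)
  nz <- vapply(grid, function(l) sum(fitLasso(X, y, l)$coef != 0), numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("surrogate reproduces ICA loadings on held-out subjects", {
  sim <- midSim()
  ica <- fitICA(sim$cohort, K = 4, seed = 31)
  sur <- trainSurrogate(sim$cohort, ica, seed = 32)
  expect_gte(min(sur@iccValidation), 0.99)

  # targets are affine in the features, so near-zero penalty attains
  # near-perfect held-out R^2
  sp <- splitBySubject(sim$cohort, seed = 32)
  val_rows <- sampleData(sim$cohort)$subject_id %in% sp$validation
  pred <- applySurrogate(sur, sim$cohort)
  for (k in 1:4) {
    r2 <- cor(pred@loadings[val_rows, k], ica@loadings[val_rows, k])^2
    expect_gt(r2, 0.999)
  }
})

test_that("surrogate application is deterministic, exact on its own input", {
  sim <- midSim()
  ica <- fitICA(sim$cohort, K = 4, seed = 31)
  sur <- trainSurrogate(sim$cohort, ica, seed = 32)
  m1 <- applySurrogate(sur, sim$cohort)
  m2 <- applySurrogate(sur, sim$cohort)
  expect_equal(m1@loadings, m2@loadings, tolerance = 0)

  # prospective scoring of an unseen cohort matches direct ICA projection
  gt <- midSim()$gt
  new <- simulateCohort(gt, nPerPhenotype = c(RR = 25, SP = 25, PP = 10),
                        seed = 99)
  m_sur <- applySurrogate(sur, new$cohort)
  m_ica <- icaMeasures(ica, new$cohort)
  for (k in 1:4) {
    expect_gte(iccAgreement(m_ica@loadings[, k], m_sur@loadings[, k]), 0.99)
  }
})

test_that("region renaming/reordering is a hard error, never silent", {
  sim <- midSim()
  ica <- fitICA(sim$cohort, K = 4, seed = 31)
  sur <- trainSurrogate(sim$cohort, ica, seed = 32)
  p <- cohortPieces(sim$cohort)
  vol <- p$volumes
  rownames(vol)[1] <- "renamed_region"
  bad <- MSCohort(vol, p$sampleData)
  expect_error(applySurrogate(sur, bad), "region")
  vol2 <- p$volumes[rev(seq_len(nrow(p$volumes))), ]
  bad2 <- MSCohort(vol2, p$sampleData)
  expect_error(applySurrogate(sur, bad2), "region")
})

test_that("an all-zero penalty grid is a flagged error", {
  sim <- midSim()
  ica <- fitICA(sim$cohort, K = 4, seed = 31)
  expect_error(trainSurrogate(sim$cohort, ica, lambdaGrid = 1e9, seed = 32),
               "all-zero")
  expect_error(trainSurrogate(sim$cohort, ica, lambdaGrid = numeric(0)),
               "empty lambda grid")
})

test_that("ICC(2,1) matches its ANOVA definition and limiting cases", {
  expect_equal(iccAgreement(1:10, 1:10), 1)
  expect_error(iccAgreement(c(1, 1, 1), c(1, 1, 1)), "zero total variance")
  expect_error(iccAgreement(1:2, 1:2), "at least 3")

  # independent noise: |ICC| near zero at n = 1e4
  set.seed(41)
  expect_lt(abs(iccAgreement(rnorm(1e4), rnorm(1e4))), 0.1)

  # hand-worked two-way ANOVA oracle on 6 pairs with a constant offset
  x <- c(2, 4, 6, 8, 9, 11)
  y <- x + 2
  n <- 6
  dat <- data.frame(score = c(x, y),
                    subj = factor(rep(1:6, 2)),
                    rater = factor(rep(1:2, each = 6)))
  # y = x + c fits exactly, so the F-test warning is expected noise here
  ms <- suppressWarnings(anova(lm(score ~ subj + rater, data = dat)))
  msr <- ms["subj", "Mean Sq"]; msc <- ms["rater", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  oracle <- (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
  expect_equal(iccAgreement(x, y), oracle, tolerance = 1e-12)
  expect_lt(iccAgreement(x, y), cor(x, y))
})

test_that("z-scored measures have exact zero mean and unit SD", {
  sim <- midSim()
  m <- latentMeasures(sim)
  z <- zscoreMeasures(m)
  expect_true(all(abs(colMeans(z@loadings)) < 1e-8))
  expect_true(all(abs(apply(z@loadings, 2, sd) - 1) < 1e-8))
  expect_true(z@zscored)

  # measures CSV round trip
  path <- withr::local_tempfile(fileext = ".csv")
  writeMeasures(m, path)
  back <- readMeasures(path)
  expect_equal(back@loadings, m@loadings, tolerance = 0, ignore_attr = TRUE)
  expect_equal(back@gmTotal, m@gmTotal, tolerance = 0)
})
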