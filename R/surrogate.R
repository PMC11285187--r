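# Lasso surrogate: subject-grouped splitting, fitting, scoring, ICC.

#' Split a cohort into training and validation subjects
#'
#' Partitions subject IDs (all visits of a subject stay on one side) with
#' the training share within one subject of `fraction`. Deterministic given
#' `seed`.
#'
#' @param x an [MSCohort-class] or a character vector of subject IDs
#' @param fraction training fraction, in (0, 1); default 0.70
#' @param seed integer seed
#' @return list with `train` and `validation` subject-ID vectors
#' @export
splitBySubject <- function(x, fraction = 0.70, seed = 1) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  ids <- if (methods::is(x, "MSCohort")) subjectIds(x) else unique(as.character(x))
  if (length(ids) < 2) stop("need at least 2 subjects to split")
  set.seed(seed)
  n_train <- round(fraction * length(ids))
  n_train <- min(max(n_train, 1), length(ids) - 1)
  train <- sort(sample(ids, n_train))
  list(train = train, validation = sort(setdiff(ids, train)))
}

#' Fit a single Lasso regression at a fixed penalty
#'
#' Minimizes \eqn{(1/2n)\|y - \beta_0 - X\beta\|^2 + \lambda\|\beta\|_1}
#' for column-standardized predictors (1/n variance convention). Columns
#' with zero variance are dropped (coefficient 0) with a warning. Uses
#' coordinate descent (glmnet) for p >= 2 and the exact univariate
#' soft-threshold solution for p = 1.
#'
#' @param X n x p standardized predictor matrix
#' @param y length-n response
#' @param lambda penalty, >= 0
#' @return list with `coef` (length p, named if X has column names) and
#'   `intercept`
#' @export
fitLasso <- function(X, y, lambda) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("NaN/NA inputs are not allowed")
  if (lambda < 0) stop("lambda must be >= 0")
  p <- ncol(X)
  sds <- colMeanSdN(X)$sd
  keep <- sds > 0
  if (any(!keep)) {
    warning(sprintf("dropping %d zero-variance column(s)", sum(!keep)))
  }
  beta <- numeric(p)
  names(beta) <- colnames(X)
  Xk <- X[, keep, drop = FALSE]
  if (ncol(Xk) == 0) {
    return(list(coef = beta, intercept = mean(y)))
  }
  if (ncol(Xk) == 1) {
    n <- nrow(Xk)
    xm <- mean(Xk); ym <- mean(y)
    xc <- Xk - xm; yc <- y - ym
    rho <- sum(xc * yc) / n
    vx <- sum(xc^2) / n
    b <- sign(rho) * max(abs(rho) - lambda, 0) / vx
    beta[keep] <- b
    return(list(coef = beta, intercept = ym - b * xm))
  }
  fit <- glmnet::glmnet(Xk, y, alpha = 1, lambda = lambda,
                        standardize = FALSE, thresh = 1e-12, maxit = 1e7)
  cf <- as.numeric(stats::coef(fit))
  beta[keep] <- cf[-1]
  list(coef = beta, intercept = cf[1])
}

#' Largest penalty with a non-null solution
#' @keywords internal
#' @noRd
lambdaMax <- function(X, y) {
  max(abs(crossprod(X, y - mean(y)))) / nrow(X)
}

#' Train the per-network Lasso surrogate
#'
#' One Lasso per network, mapping standardized regional volumes to the ICA
#' loading. The cohort is split 70/30 by subject; per network, the penalty
#' is chosen by subject-grouped k-fold cross-validation on the training
#' split over a log grid from lambda_max down `lambdaDecades` decades, and
#' fidelity is measured as ICC(2,1) between the ICA loadings and the
#' surrogate predictions on the held-out split. Standardization parameters
#' are frozen from the training split.
#'
#' @param cohort the [MSCohort-class] the ICA was fitted on
#' @param ica the matching [ICADecomposition-class]
#' @param lambdaGrid optional explicit penalty grid (shared by networks)
#' @param cvFolds folds for grouped cross-validation (default 5)
#' @param fraction training share of subjects (default 0.70)
#' @param seed integer seed for the split and fold assignment
#' @param nLambda grid length when `lambdaGrid` is NULL
#' @param lambdaDecades decades spanned below lambda_max
#' @return a [SurrogateModel-class]
#' @export
trainSurrogate <- function(cohort, ica, lambdaGrid = NULL, cvFolds = 5,
                           fraction = 0.70, seed = 1, nLambda = 30,
                           lambdaDecades = 4) {
  stopifnot(methods::is(cohort, "MSCohort"), methods::is(ica, "ICADecomposition"))
  keys <- sampleKeys(cohort)
  if (!identical(keys, ica@sampleKeys)) {
    stop("ICA was not fitted on this cohort (sample keys differ)")
  }
  if (!is.null(lambdaGrid) && length(lambdaGrid) == 0) stop("empty lambda grid")

  split <- splitBySubject(cohort, fraction = fraction, seed = seed)
  in_train <- keys$subject_id %in% split$train
  if (cvFolds > length(split$train)) stop("fewer training subjects than folds")

  # same features the ICA analysed
  X <- icaFeatures(regionVolumes(cohort), ica@normalize, sampleData(cohort)$tiv)
  std <- colMeanSdN(X[in_train, , drop = FALSE])
  degen <- std$sd == 0
  if (any(degen)) {
    warning(sprintf("%d region(s) with zero training SD excluded from the surrogate",
                    sum(degen)))
    std$sd[degen] <- 1
  }
  Xs <- sweep(sweep(X, 2, std$mean), 2, std$sd, `/`)
  Xs[, degen] <- 0
  Xtr <- Xs[in_train, , drop = FALSE]
  Xval <- Xs[!in_train, , drop = FALSE]

  # subject-grouped folds within the training split
  set.seed(deriveSeed(seed, 17))
  fold_of_subject <- sample(rep_len(seq_len(cvFolds), length(split$train)))
  names(fold_of_subject) <- split$train
  fold <- fold_of_subject[keys$subject_id[in_train]]

  K <- ica@K
  R <- ncol(X)
  coefs <- matrix(0, R, K, dimnames = list(colnames(X), rownames(ica@maps)))
  intercepts <- numeric(K)
  lambdas <- numeric(K)
  icc <- numeric(K)
  L <- ica@loadings

  for (k in seq_len(K)) {
    y <- L[in_train, k]
    grid <- lambdaGrid
    if (is.null(grid)) {
      lmax <- lambdaMax(Xtr, y)
      grid <- 10^seq(log10(lmax), log10(lmax) - lambdaDecades,
                     length.out = nLambda)
    }
    grid <- sort(as.numeric(grid), decreasing = TRUE)
    cv_mse <- matrix(NA_real_, cvFolds, length(grid))
    for (f in seq_len(cvFolds)) {
      tr <- fold != f
      fit <- glmnet::glmnet(Xtr[tr, , drop = FALSE], y[tr], alpha = 1,
                            lambda = grid, standardize = FALSE, thresh = 1e-9)
      pred <- stats::predict(fit, Xtr[!tr, , drop = FALSE])
      # glmnet may drop trailing lambdas on degenerate fits; align by column
      cols <- match(signif(grid, 10), signif(fit$lambda, 10))
      cv_mse[f, ] <- vapply(seq_along(grid), function(j) {
        if (is.na(cols[j])) return(NA_real_)
        mean((y[!tr] - pred[, cols[j]])^2)
      }, numeric(1))
    }
    mse <- colMeans(cv_mse)
    best <- which.min(mse)
    lambdas[k] <- grid[best]
    fit <- glmnet::glmnet(Xtr, y, alpha = 1, lambda = grid,
                          standardize = FALSE, thresh = 1e-10)
    j <- match(signif(grid[best], 10), signif(fit$lambda, 10))
    if (is.na(j)) j <- which.min(abs(fit$lambda - grid[best]))
    cf <- as.numeric(stats::coef(fit)[, j])
    coefs[, k] <- cf[-1]
    intercepts[k] <- cf[1]
    pred_val <- drop(Xval %*% coefs[, k]) + intercepts[k]
    if (stats::sd(pred_val) == 0) {
      stop(sprintf("network %d: all-zero surrogate (penalty grid too large); ICC undefined", k))
    }
    icc[k] <- iccAgreement(L[!in_train, k], pred_val)
  }

  obj <- methods::new("SurrogateModel",
    coef = coefs, intercept = intercepts, lambda = lambdas,
    center = std$mean, scale = std$sd,
    regionNames = colnames(X), networkNames = rownames(ica@maps),
    splitSeed = as.integer(seed), iccValidation = icc,
    normalize = ica@normalize)
  methods::validObject(obj)
  obj
}

#' Score a cohort with a fitted surrogate
#'
#' Pure prediction: per row, `loading_k = intercept_k + coef_k .
#' standardize(volumes)` with the training-split standardization; whole
#' brain GM (regional sum) is appended. No parameter is re-estimated.
#' Regions must match the model exactly (names and order).
#'
#' @param model a [SurrogateModel-class]
#' @param cohort an [MSCohort-class]
#' @return a [NetworkMeasures-class]
#' @export
applySurrogate <- function(model, cohort) {
  stopifnot(methods::is(model, "SurrogateModel"), methods::is(cohort, "MSCohort"))
  if (!identical(regionNames(cohort), model@regionNames)) {
    stop("region names/order mismatch between cohort and surrogate model")
  }
  if (any(model@scale <= 0)) stop("unstandardizable input: zero training SD")
  X <- icaFeatures(regionVolumes(cohort), model@normalize,
                   sampleData(cohort)$tiv)
  Xs <- sweep(sweep(X, 2, model@center), 2, model@scale, `/`)
  L <- Xs %*% model@coef +
    matrix(model@intercept, nrow(X), length(model@intercept), byrow = TRUE)
  colnames(L) <- model@networkNames
  methods::new("NetworkMeasures",
    loadings = L, gmTotal = wholeBrainGM(cohort),
    sampleKeys = sampleKeys(cohort), zscored = FALSE,
    zCenter = numeric(0), zScale = numeric(0))
}

#' Intra-class correlation, ICC(2,1), absolute agreement
#'
#' Two-way random-effects single-measure ICC for two raters
#' (Shrout--Fleiss): \eqn{(MS_R - MS_E) / (MS_R + MS_E + 2(MS_C - MS_E)/n)}.
#'
#' @param x,y paired measurements of length n >= 3
#' @return scalar ICC
#' @export
iccAgreement <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("need at least 3 paired values")
  if (stats::var(c(x, y)) == 0) stop("zero total variance; ICC undefined")
  row_mean <- (x + y) / 2
  grand <- mean(row_mean)
  col_mean <- c(mean(x), mean(y))
  msr <- 2 * sum((row_mean - grand)^2) / (n - 1)
  msc <- n * sum((col_mean - grand)^2) / 1
  sse <- sum((x - row_mean - col_mean[1] + grand)^2) +
    sum((y - row_mean - col_mean[2] + grand)^2)
  mse <- sse / (n - 1)
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

#' z-score network loadings against a reference
#'
#' @param measures a [NetworkMeasures-class]
#' @param reference optional [NetworkMeasures-class] supplying the
#'   centering/scaling statistics (defaults to `measures` itself)
#' @return a z-scored [NetworkMeasures-class]
#' @export
zscoreMeasures <- function(measures, reference = NULL) {
  stopifnot(methods::is(measures, "NetworkMeasures"))
  ref <- if (is.null(reference)) measures else reference
  ctr <- colMeans(ref@loadings)
  scl <- apply(ref@loadings, 2, stats::sd)
  if (any(scl == 0)) stop("zero-variance loading column; cannot z-score")
  L <- sweep(sweep(measures@loadings, 2, ctr), 2, scl, `/`)
  methods::new("NetworkMeasures",
    loadings = L, gmTotal = measures@gmTotal,
    sampleKeys = measures@sampleKeys, zscored = TRUE,
    zCenter = ctr, zScale = scl)
}

#' Tabular view of network measures
#' @param x a [NetworkMeasures-class]
#' @return data.frame with keys, one loading column per network, `gm_total`
#' @export
measuresTable <- function(x) {
  stopifnot(methods::is(x, "NetworkMeasures"))
  cbind(x@sampleKeys[, c("subject_id", "visit_index")],
        as.data.frame(x@loadings), gm_total = x@gmTotal)
}

#' Write network measures to CSV
#' @param x a [NetworkMeasures-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeMeasures <- function(x, path) {
  data.table::fwrite(formatExact(measuresTable(x)), path, sep = ",", na = "",
                     quote = FALSE)
  invisible(path)
}

#' Read network measures from CSV (inverse of [writeMeasures()])
#' @param path CSV path
#' @return a [NetworkMeasures-class]
#' @export
readMeasures <- function(path) {
  dt <- data.table::fread(path, sep = ",", na.strings = "",
                          colClasses = list(character = "subject_id"),
                          data.table = FALSE, showProgress = FALSE)
  net_cols <- setdiff(colnames(dt), c("subject_id", "visit_index", "gm_total"))
  methods::new("NetworkMeasures",
    loadings = as.matrix(dt[, net_cols, drop = FALSE]),
    gmTotal = dt$gm_total,
    sampleKeys = data.frame(subject_id = dt$subject_id,
                            visit_index = as.integer(dt$visit_index),
                            stringsAsFactors = FALSE),
    zscored = FALSE, zCenter = numeric(0), zScale = numeric(0))
}

setMethod("show", "SurrogateModel", function(object) {
  nz <- colSums(object@coef != 0)
  cat(sprintf("SurrogateModel: %d networks over %d regions (split seed %d)\n",
              length(object@networkNames), length(object@regionNames),
              object@splitSeed))
  cat(sprintf("  nonzero coefficients per network: %s\n",
              paste(nz, collapse = ",")))
  cat(sprintf("  held-out ICC: min %.4f, median %.4f\n",
              min(object@iccValidation), stats::median(object@iccValidation)))
})

setMethod("show", "NetworkMeasures", function(object) {
  cat(sprintf("NetworkMeasures: %d observations x %d networks%s\n",
              nrow(object@loadings), ncol(object@loadings),
              if (isTRUE(object@zscored)) " (z-scored)" else ""))
})
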