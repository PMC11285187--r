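# Empirical-Bayes location/scale (ComBat) harmonization across sites.

#' Harmonize measures across batches with parametric ComBat
#'
#' Location/scale empirical-Bayes harmonization of network measures and
#' whole-brain GM across scanner/site batches. The model per feature g,
#' batch i: observations are standardized as
#' \eqn{z = (y - \alpha_g - X\beta_g)/\sigma_g}, per-batch location and
#' scale estimates are shrunk towards parametric priors (normal for
#' location, inverse-gamma for scale) by iterated conditional posterior
#' means, and data are adjusted as
#' \eqn{y^* = \sigma_g(z - \gamma^*_{ig})/\sqrt{\delta^*_{ig}} + \alpha_g +
#' X\beta_g}. Biological covariate effects in `covariates` are estimated
#' jointly with batch and preserved in the output.
#'
#' With a single batch the transform is the identity (gamma* = 0,
#' delta* = 1).
#'
#' @param measures a [NetworkMeasures-class] (features are the network
#'   loadings plus `gm_total`) or a numeric observations x features matrix
#' @param batch batch labels (site/scanner), one per observation
#' @param covariates optional numeric design matrix of biological
#'   covariates to protect (no intercept column; it is added internally)
#' @param tol convergence tolerance of the EB iteration
#' @param maxIter EB iteration cap
#' @return list with `adjusted` (same class/shape as `measures`) and `fit`
#'   (a [CombatFit-class])
#' @export
combatFitTransform <- function(measures, batch, covariates = NULL,
                               tol = 1e-6, maxIter = 500) {
  is_nm <- methods::is(measures, "NetworkMeasures")
  Y <- if (is_nm) cbind(measures@loadings, gm_total = measures@gmTotal)
       else as.matrix(measures)
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("f%02d", seq_len(ncol(Y)))
  batch <- factor(as.character(batch))
  n <- nrow(Y)
  if (length(batch) != n) stop("batch must have one label per observation")
  nb <- table(batch)
  if (any(nb < 2)) {
    stop(sprintf("batch(es) with < 2 observations: %s",
                 paste(names(nb)[nb < 2], collapse = ", ")))
  }
  G <- ncol(Y)
  B <- nlevels(batch)

  if (B == 1) {
    fit <- methods::new("CombatFit",
      batches = levels(batch), featureNames = colnames(Y),
      alpha = colMeans(Y), beta = matrix(0, 0, G), sigma = apply(Y, 2, stats::sd),
      gammaStar = matrix(0, 1, G), deltaStar = matrix(1, 1, G),
      gammaBar = 0, tau2 = 0, aPrior = 0, bPrior = 0,
      covariateNames = character(0), iterations = 0L)
    return(list(adjusted = measures, fit = fit))
  }

  batch_design <- stats::model.matrix(~ 0 + batch)
  colnames(batch_design) <- levels(batch)
  Xc <- NULL
  if (!is.null(covariates)) {
    Xc <- as.matrix(covariates)
    if (nrow(Xc) != n) stop("covariates must have one row per observation")
    if (is.null(colnames(Xc))) colnames(Xc) <- sprintf("x%d", seq_len(ncol(Xc)))
  }
  D <- cbind(batch_design, Xc)
  if (qr(D)$rank < ncol(D)) {
    stop("design is rank deficient: covariates confounded with batch")
  }

  Bhat <- solve(crossprod(D), crossprod(D, Y))          # p x G
  prop <- as.numeric(nb) / n
  alpha <- as.numeric(prop %*% Bhat[seq_len(B), , drop = FALSE])
  var_pooled <- colMeans((Y - D %*% Bhat)^2)            # 1/n, as in ComBat
  if (any(var_pooled == 0)) stop("feature with zero residual variance")
  sig <- sqrt(var_pooled)

  stand_mean <- matrix(alpha, n, G, byrow = TRUE)
  if (!is.null(Xc)) {
    stand_mean <- stand_mean + Xc %*% Bhat[-seq_len(B), , drop = FALSE]
  }
  Z <- (Y - stand_mean) / matrix(sig, n, G, byrow = TRUE)

  gamma_hat <- matrix(NA_real_, B, G, dimnames = list(levels(batch), colnames(Y)))
  delta_hat <- gamma_hat
  for (i in seq_len(B)) {
    rows <- batch == levels(batch)[i]
    gamma_hat[i, ] <- colMeans(Z[rows, , drop = FALSE])
    delta_hat[i, ] <- apply(Z[rows, , drop = FALSE], 2, stats::var)
  }
  gamma_bar <- rowMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 1, stats::var)
  dmean <- rowMeans(delta_hat)
  dvar <- apply(delta_hat, 1, stats::var)
  a_prior <- (2 * dvar + dmean^2) / dvar
  b_prior <- (dmean * dvar + dmean^3) / dvar

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  iters <- 0L
  for (i in seq_len(B)) {
    rows <- which(batch == levels(batch)[i])
    ni <- length(rows)
    g_old <- gamma_hat[i, ]
    d_old <- delta_hat[i, ]
    it <- 0L
    repeat {
      it <- it + 1L
      g_new <- (tau2[i] * ni * gamma_hat[i, ] + d_old * gamma_bar[i]) /
        (tau2[i] * ni + d_old)
      sum2 <- colSums((Z[rows, , drop = FALSE] -
                         matrix(g_new, ni, G, byrow = TRUE))^2)
      d_new <- (0.5 * sum2 + b_prior[i]) / (ni / 2 + a_prior[i] - 1)
      change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                    abs(d_new - d_old) / (abs(d_old) + 1e-12))
      g_old <- g_new
      d_old <- d_new
      if (change < tol || it >= maxIter) break
    }
    gamma_star[i, ] <- g_old
    delta_star[i, ] <- d_old
    iters <- max(iters, it)
  }

  Zadj <- Z
  for (i in seq_len(B)) {
    rows <- which(batch == levels(batch)[i])
    Zadj[rows, ] <- (Z[rows, , drop = FALSE] -
                       matrix(gamma_star[i, ], length(rows), G, byrow = TRUE)) /
      matrix(sqrt(delta_star[i, ]), length(rows), G, byrow = TRUE)
  }
  Yadj <- Zadj * matrix(sig, n, G, byrow = TRUE) + stand_mean

  fit <- methods::new("CombatFit",
    batches = levels(batch), featureNames = colnames(Y),
    alpha = alpha, beta = if (is.null(Xc)) matrix(0, 0, G) else
      Bhat[-seq_len(B), , drop = FALSE],
    sigma = sig, gammaStar = gamma_star, deltaStar = delta_star,
    gammaBar = gamma_bar, tau2 = tau2, aPrior = a_prior, bPrior = b_prior,
    covariateNames = if (is.null(Xc)) character(0) else colnames(Xc),
    iterations = iters)

  adjusted <- if (is_nm) {
    methods::new("NetworkMeasures",
      loadings = Yadj[, seq_len(ncol(measures@loadings)), drop = FALSE],
      gmTotal = Yadj[, "gm_total"],
      sampleKeys = measures@sampleKeys, zscored = measures@zscored,
      zCenter = measures@zCenter, zScale = measures@zScale)
  } else Yadj
  list(adjusted = adjusted, fit = fit)
}

setMethod("show", "CombatFit", function(object) {
  cat(sprintf("CombatFit: %d batch(es) x %d feature(s); EB iterations: %d\n",
              length(object@batches), length(object@featureNames),
              object@iterations))
})
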