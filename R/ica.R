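# Spatial ICA network discovery, sign orientation, component matching.

#' Regional feature matrix entering ICA and the surrogate
#'
#' `normalize = "tiv"` divides each observation's regional volumes by its
#' total intracranial volume (proportional head-size correction, the
#' standard global-scaling step in morphometry); `"fraction"` divides by
#' the row sum (regional fractions of whole-brain GM); `"none"` uses raw
#' volumes. TIV normalization is exogenous to the grey-matter signal, so it
#' removes the global head-size direction without coupling the network
#' sources through the denominator.
#' @keywords internal
#' @noRd
icaFeatures <- function(X, normalize, tiv = NULL) {
  switch(normalize,
    tiv = {
      if (is.null(tiv)) stop("TIV normalization requires per-observation TIV")
      # scaled to keep feature magnitudes near volume units
      X / tiv * 1.45e6
    },
    fraction = X / rowSums(X),
    none = X,
    stop(sprintf("unknown normalization '%s'", normalize)))
}

#' Fit spatial ICA on a cohort's regional volumes
#'
#' FastICA with the logcosh contrast (a = 1), PCA whitening to K components
#' and symmetric (parallel) fixed-point updates, run on the observation x
#' region matrix: subject-visits are the samples, so the independent
#' sources are per-observation network loadings and the spatial maps are
#' the mixing rows. By default (for cohorts) the features are
#' TIV-normalized volumes (proportional head-size correction), which
#' removes the global head-size direction that otherwise dominates the
#' covariance and consumes a component; TIV additionally stays a covariate
#' in the statistical models. Loadings and maps are returned sign-oriented via
#' [orientSigns()] so that a lower loading always means less grey matter.
#' Deterministic given `seed`.
#'
#' @param x an [MSCohort-class], or a numeric observations x regions matrix
#' @param K number of components (must satisfy K <= min(n_obs, R))
#' @param seed integer seed for the random initial rotation
#' @param tol convergence tolerance on the rotation update
#' @param maxIter maximum fixed-point iterations; non-convergence is
#'   returned with `converged = FALSE` and a warning
#' @param normalize feature normalization: `"tiv"` (default for cohorts;
#'   proportional head-size correction), `"fraction"` (regional fractions
#'   of whole-brain GM) or `"none"` (raw volumes; the default, and only
#'   option, for plain matrices)
#' @return an [ICADecomposition-class]
#' @export
fitICA <- function(x, K = 20, seed = 1, tol = 1e-4, maxIter = 200,
                   normalize = NULL) {
  if (methods::is(x, "MSCohort")) {
    if (is.null(normalize)) normalize <- "tiv"
    X <- icaFeatures(regionVolumes(x), normalize, sampleData(x)$tiv)
    gm <- wholeBrainGM(x)
    keys <- sampleKeys(x)
    rnames <- regionNames(x)
  } else {
    if (is.null(normalize)) normalize <- "none"
    if (normalize == "tiv") stop("TIV normalization needs an MSCohort")
    X <- icaFeatures(as.matrix(x), normalize)
    gm <- rowSums(as.matrix(x))
    keys <- data.frame(subject_id = as.character(seq_len(nrow(X))),
                       visit_index = 0L, stringsAsFactors = FALSE)
    rnames <- colnames(X)
    if (is.null(rnames)) rnames <- sprintf("r%03d", seq_len(ncol(X)))
  }
  n <- nrow(X); R <- ncol(X)
  K <- as.integer(K)
  if (K > min(n, R)) {
    stop(sprintf("K = %d exceeds min(n_obs, R) = %d", K, min(n, R)))
  }
  if (n <= K) stop("need more observations than components")

  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = K)
  d <- sv$d[seq_len(K)]
  if (any(d < 1e-10 * d[1])) {
    stop("data rank below K; reduce the number of components")
  }
  # whitening with the n-1 divisor so cov(Z) is exactly the identity
  scl <- sqrt(n - 1) / d
  whitening <- t(sv$v) * scl           # K x R (rows scaled)
  dewhitening <- (sv$v) * rep(d / sqrt(n - 1), each = R)  # R x K
  Z <- Xc %*% t(whitening)             # n x K, cov = I

  set.seed(seed)
  W <- matrix(stats::rnorm(K * K), K, K)
  W <- symDecorrelate(W)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxIter)) {
    S <- Z %*% t(W)                    # n x K
    G <- tanh(S)
    gprime_mean <- colMeans(1 - G^2)
    W1 <- crossprod(G, Z) / n - gprime_mean * W
    W1 <- symDecorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("FastICA did not converge in %d iterations (delta tol %g)",
                    maxIter, tol))
  }

  loadings <- Z %*% t(W)
  maps <- W %*% t(dewhitening)         # K x R
  ori <- orientSigns(loadings, maps, gm)
  # fold the flips into the unmixing rotation so projection of new data is
  # a single affine map
  W <- ori$flags * W

  colnames(ori$loadings) <- sprintf("net%02d", seq_len(K))
  rownames(ori$maps) <- colnames(ori$loadings)
  colnames(ori$maps) <- rnames

  obj <- methods::new("ICADecomposition",
    K = K, center = mu, whitening = whitening, unmixing = W,
    maps = ori$maps, loadings = ori$loadings, orientFlags = ori$flags,
    converged = converged, iterations = it, seed = as.integer(seed),
    regionNames = rnames, sampleKeys = keys, normalize = normalize)
  methods::validObject(obj)
  obj
}

#' Symmetric decorrelation W <- (W W^T)^{-1/2} W
#' @keywords internal
#' @noRd
symDecorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% (t(e$vectors) / sqrt(pmax(e$values, 1e-300))) %*% W
}

#' Orient component signs against whole-brain grey matter
#'
#' For each component k, if the Pearson correlation between its loading and
#' the whole-brain GM volume is negative, both the loading column and the
#' map row are negated, so that after orientation a lower loading always
#' means lower GM volume. The reconstruction loadings %*% maps is unchanged.
#' Zero-variance loadings leave the flag at +1 with a warning.
#'
#' @param loadings n x K loading matrix
#' @param maps K x R spatial maps
#' @param gmTotal whole-brain GM per observation
#' @return list with `loadings`, `maps`, `flags` (+/-1 per component)
#' @export
orientSigns <- function(loadings, maps, gmTotal) {
  K <- ncol(loadings)
  stopifnot(nrow(maps) == K, length(gmTotal) == nrow(loadings))
  flags <- rep(1, K)
  for (k in seq_len(K)) {
    sk <- stats::sd(loadings[, k])
    if (!is.finite(sk) || sk == 0) {
      warning(sprintf("component %d has zero-variance loading; orientation undefined", k))
      next
    }
    if (stats::cor(loadings[, k], gmTotal) < 0) flags[k] <- -1
  }
  list(loadings = sweep(loadings, 2, flags, `*`),
       maps = flags * maps, flags = flags)
}

#' Project a cohort onto a fitted ICA decomposition
#'
#' Applies the frozen centering, whitening and (sign-oriented) unmixing to
#' new regional volumes; no re-estimation. This is the direct ICA analogue
#' of prospective surrogate scoring, and the reference against which the
#' Lasso surrogate is validated.
#'
#' @param ica an [ICADecomposition-class]
#' @param cohort an [MSCohort-class] with the same regions, or NULL to
#'   return the decomposition's own loadings
#' @return a [NetworkMeasures-class]
#' @export
icaMeasures <- function(ica, cohort = NULL) {
  if (is.null(cohort)) {
    stop("cohort is required; use loadings(ica) for the fit's own loadings")
  }
  if (!identical(regionNames(cohort), ica@regionNames)) {
    stop("region names/order mismatch between cohort and ICA model")
  }
  X <- icaFeatures(regionVolumes(cohort), ica@normalize, sampleData(cohort)$tiv)
  L <- sweep(X, 2, ica@center) %*% t(ica@whitening) %*% t(ica@unmixing)
  colnames(L) <- rownames(ica@maps)
  methods::new("NetworkMeasures",
    loadings = L, gmTotal = wholeBrainGM(cohort),
    sampleKeys = sampleKeys(cohort), zscored = FALSE,
    zCenter = numeric(0), zScale = numeric(0))
}

#' Match spatial maps between two decompositions
#'
#' Computes all pairwise Pearson correlations between the K_A x R and
#' K_B x R map matrices and finds the one-to-one assignment maximizing the
#' summed absolute correlation (optimal, Hungarian). Pairs with |r| >= 0.8
#' are flagged consistent, the stability criterion used for split-cohort
#' comparison.
#'
#' @param A,B [ICADecomposition-class] objects over the same regions, or
#'   plain K x R map matrices
#' @return data.frame with `component_a`, `component_b`, signed `r`,
#'   `abs_r`, `consistent`
#' @export
matchComponents <- function(A, B) {
  mapsA <- if (methods::is(A, "ICADecomposition")) A@maps else as.matrix(A)
  mapsB <- if (methods::is(B, "ICADecomposition")) B@maps else as.matrix(B)
  if (methods::is(A, "ICADecomposition") && methods::is(B, "ICADecomposition") &&
      !identical(A@regionNames, B@regionNames)) {
    stop("region names/order mismatch between decompositions")
  }
  if (ncol(mapsA) != ncol(mapsB)) stop("map matrices must share the region set")
  cc <- stats::cor(t(mapsA), t(mapsB))          # K_A x K_B
  KA <- nrow(cc); KB <- ncol(cc)
  n <- max(KA, KB)
  cost <- matrix(0, n, n)
  cost[seq_len(KA), seq_len(KB)] <- -abs(cc)
  assignment <- hungarianMin(cost)
  ka <- seq_len(KA)
  kb <- assignment[ka]
  keep <- kb <= KB
  out <- data.frame(component_a = ka[keep], component_b = kb[keep],
                    r = cc[cbind(ka[keep], kb[keep])])
  out$abs_r <- abs(out$r)
  out$consistent <- out$abs_r >= 0.8
  out[order(-out$abs_r), , drop = FALSE]
}

#' Loadings accessor for decompositions and measures
#' @param x an [ICADecomposition-class] or [NetworkMeasures-class]
#' @return numeric matrix, observations x networks
#' @export
networkLoadings <- function(x) {
  if (methods::is(x, "ICADecomposition")) x@loadings else x@loadings
}

#' Spatial maps accessor
#' @param x an [ICADecomposition-class]
#' @return K x R matrix of spatial maps
#' @export
spatialMaps <- function(x) x@maps

setMethod("show", "ICADecomposition", function(object) {
  cat(sprintf("ICADecomposition: K = %d over %d regions, %d observations\n",
              object@K, length(object@regionNames), nrow(object@loadings)))
  cat(sprintf("  converged: %s after %d iterations (seed %d); %d sign flips\n",
              object@converged, object@iterations, object@seed,
              sum(object@orientFlags < 0)))
})
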