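# S4 class definitions and validity methods.

#' @importFrom methods new validObject is setClass setGeneric setMethod
#'   setValidity show slot
NULL

.COHORT_COLS <- c("subject_id", "trial_id", "site_id", "phenotype", "arm",
                  "visit_index", "time_years", "age_baseline", "sex",
                  "disease_duration", "tiv", "edss")
.PHENOTYPES <- c("RR", "SP", "PP")
.ARMS <- c("treated", "comparator", "none")

#' MSCohort: longitudinal cohort of regional grey-matter volumes
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay, `volumes`
#' (regions x subject-visits, mm^3), and per-visit covariates in `colData`:
#' subject, trial, site (scanner batch), multiple sclerosis phenotype
#' (RR/SP/PP), treatment arm, visit index, time in years from baseline,
#' baseline age, sex, disease duration, total intracranial volume (TIV) and
#' EDSS (0--10 in half steps, possibly missing).
#'
#' Validity enforces: unique (subject, visit) pairs; exactly one baseline
#' (`time_years == 0`) row per subject; visit times strictly increasing with
#' visit index within subject; phenotype, arm, sex, baseline age and disease
#' duration constant within subject; non-negative finite volumes; positive
#' TIV; EDSS on the half-point grid in [0, 10] when present.
#'
#' @export
setClass("MSCohort", contains = "SummarizedExperiment")

setValidity("MSCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  missing_cols <- setdiff(.COHORT_COLS, colnames(cd))
  if (length(missing_cols) > 0) {
    return(sprintf("missing required column(s): %s",
                   paste(missing_cols, collapse = ", ")))
  }
  msgs <- character(0)
  sid <- as.character(cd$subject_id)
  vi <- as.integer(cd$visit_index)
  tt <- as.numeric(cd$time_years)
  key <- paste(sid, vi, sep = "\r")

  if (anyDuplicated(key)) {
    msgs <- c(msgs, sprintf("duplicate (subject_id, visit_index) pair(s): %s",
                            rowsMsg(unique(key[duplicated(key)]))))
  }
  if (any(!is.finite(tt)) || any(tt < 0)) {
    msgs <- c(msgs, "time_years must be finite and >= 0")
  }
  if (any(vi < 0)) msgs <- c(msgs, "visit_index must be >= 0")

  bad_ph <- !(as.character(cd$phenotype) %in% .PHENOTYPES)
  if (any(bad_ph)) msgs <- c(msgs, "phenotype must be one of RR, SP, PP")
  if (any(!(as.character(cd$arm) %in% .ARMS))) {
    msgs <- c(msgs, "arm must be one of treated, comparator, none")
  }
  if (any(!(as.character(cd$sex) %in% c("M", "F")))) {
    msgs <- c(msgs, "sex must be M or F")
  }
  if (any(!is.finite(as.numeric(cd$tiv)) | as.numeric(cd$tiv) <= 0)) {
    msgs <- c(msgs, "tiv must be finite and > 0")
  }
  ed <- as.numeric(cd$edss)
  ed_ok <- is.na(ed) | (ed >= 0 & ed <= 10 & abs(ed * 2 - round(ed * 2)) < 1e-8)
  if (!all(ed_ok)) {
    msgs <- c(msgs, sprintf("edss must lie in [0,10] on the half-point grid; offending rows: %s",
                            rowsMsg(which(!ed_ok))))
  }

  # per-subject invariants
  split_idx <- split(seq_along(sid), sid)
  no_baseline <- character(0)
  nonmono <- character(0)
  nonconst <- character(0)
  const_cols <- c("phenotype", "arm", "sex", "age_baseline", "disease_duration")
  for (s in names(split_idx)) {
    idx <- split_idx[[s]]
    idx <- idx[order(vi[idx])]
    if (sum(abs(tt[idx]) < 1e-12) != 1) no_baseline <- c(no_baseline, s)
    if (length(idx) > 1 && any(diff(tt[idx]) <= 0)) nonmono <- c(nonmono, s)
    for (cc in const_cols) {
      if (length(unique(as.character(cd[[cc]][idx]))) > 1) {
        nonconst <- c(nonconst, sprintf("%s(%s)", s, cc))
        break
      }
    }
  }
  if (length(no_baseline) > 0) {
    msgs <- c(msgs, sprintf("baseline missing: subject(s) without exactly one time_years == 0 row: %s",
                            rowsMsg(no_baseline)))
  }
  if (length(nonmono) > 0) {
    msgs <- c(msgs, sprintf("non-monotone visit times within subject(s): %s",
                            rowsMsg(nonmono)))
  }
  if (length(nonconst) > 0) {
    msgs <- c(msgs, sprintf("subject-level covariates not constant within subject(s): %s",
                            rowsMsg(nonconst)))
  }

  vol <- SummarizedExperiment::assay(object, "volumes")
  if (any(!is.finite(vol)) || any(vol < 0)) {
    bad <- which(apply(vol < 0 | !is.finite(vol), 2, any))
    msgs <- c(msgs, sprintf("negative or non-finite region volumes in row(s): %s",
                            rowsMsg(bad)))
  }
  if (is.null(rownames(object))) msgs <- c(msgs, "region names (rownames) required")
  if (length(msgs) == 0) TRUE else msgs
})

#' GroundTruth: planted structure of a synthetic cohort
#'
#' Holds everything the synthetic generator plants: sparse non-negative
#' spatial maps (rows sum to 1), baseline mean regional volumes,
#' phenotype-specific loading trajectories, additive treatment effects on a
#' subset of network slopes, EDSS weights on a designated clinical subset,
#' noise SDs and per-site multiplicative scanner gains. Used by tests and the
#' acceptance machinery as the oracle for every downstream stage.
#'
#' @slot K number of planted networks
#' @slot R number of regions
#' @slot regionNames region labels
#' @slot maps K x R non-negative sparse spatial maps, rows sum to 1
#' @slot muRegion baseline mean regional volumes (mm^3)
#' @slot baselineMean 3 x K matrix (RR/SP/PP) of baseline loading means
#' @slot baselineScale per-network SD of the Laplace baseline loadings
#' @slot slopes 3 x K matrix of loading drift per year by phenotype
#' @slot treatDelta additive slope change under treatment (0 off the
#'   affected set)
#' @slot clinicalWeights EDSS weights (nonzero on the clinical subset)
#' @slot sigmaLoading,sigmaRegion,sigmaEdss noise SDs
#' @slot siteGain sites x R multiplicative scanner gains, in [0.9, 1.1]
#' @slot refTiv reference total intracranial volume (mm^3)
#' @slot edssIntercept,edssAgeCoef EDSS generative intercept and age effect
#' @slot edssTimeAmp per-year growth of the EDSS sensitivity to the
#'   clinical networks
#' @slot seed integer seed the object was generated from
#' @export
setClass("GroundTruth", representation(
  K = "integer", R = "integer", regionNames = "character",
  maps = "matrix", muRegion = "numeric",
  baselineMean = "matrix", baselineScale = "numeric",
  slopes = "matrix", treatDelta = "numeric", clinicalWeights = "numeric",
  sigmaLoading = "numeric", sigmaRegion = "numeric", sigmaEdss = "numeric",
  siteGain = "matrix", refTiv = "numeric",
  edssIntercept = "numeric", edssAgeCoef = "numeric",
  edssTimeAmp = "numeric", seed = "integer"
))

setValidity("GroundTruth", function(object) {
  msgs <- character(0)
  K <- object@K; R <- object@R
  if (!all(dim(object@maps) == c(K, R))) msgs <- c(msgs, "maps must be K x R")
  if (any(object@maps < 0)) msgs <- c(msgs, "maps must be non-negative")
  if (any(abs(rowSums(object@maps) - 1) > 1e-8)) {
    msgs <- c(msgs, "map rows must sum to 1")
  }
  supp <- lapply(seq_len(K), function(k) which(object@maps[k, ] > 0))
  sizes <- lengths(supp)
  if (any(sizes < 3) || any(sizes > R / 4)) {
    msgs <- c(msgs, "each map support must have >= 3 and <= R/4 regions")
  }
  if (K > 1) {
    for (a in seq_len(K - 1)) {
      for (b in (a + 1):K) {
        ov <- length(intersect(supp[[a]], supp[[b]]))
        if (ov >= 0.5 * min(sizes[a], sizes[b])) {
          msgs <- c(msgs, sprintf("maps %d and %d share >= 50%% of their support", a, b))
        }
      }
    }
  }
  if (any(object@siteGain < 0.9 - 1e-12) || any(object@siteGain > 1.1 + 1e-12)) {
    msgs <- c(msgs, "site gains must lie in [0.9, 1.1]")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' ICADecomposition: spatial ICA fit on a cohort
#'
#' Stores the centering vector, PCA whitening matrix (K x R), orthogonal
#' unmixing rotation (K x K), spatial maps (K x R), per-observation loadings
#' (n x K), sign-orientation flags, and convergence state. Observations
#' (subject-visits) are the ICA samples: the independent sources are the
#' per-observation loadings and the maps are the mixing rows, so each fit
#' directly yields a network measure per participant and time point.
#'
#' @export
setClass("ICADecomposition", representation(
  K = "integer", center = "numeric", whitening = "matrix",
  unmixing = "matrix", maps = "matrix", loadings = "matrix",
  orientFlags = "numeric", converged = "logical", iterations = "integer",
  seed = "integer", regionNames = "character", sampleKeys = "data.frame",
  normalize = "character"
))

setValidity("ICADecomposition", function(object) {
  msgs <- character(0)
  K <- object@K
  if (nrow(object@maps) != K || nrow(object@whitening) != K ||
      !all(dim(object@unmixing) == c(K, K)) || ncol(object@loadings) != K) {
    msgs <- c(msgs, "inconsistent component dimensions")
  }
  if (ncol(object@maps) != length(object@regionNames)) {
    msgs <- c(msgs, "maps must have one column per region")
  }
  if (!all(object@orientFlags %in% c(-1, 1))) {
    msgs <- c(msgs, "orientFlags must be +/-1")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' SurrogateModel: per-network sparse linear scoring rule
#'
#' One Lasso model per network mapping regional volumes to the ICA loading.
#' Standardization parameters are frozen from the training split so
#' prospective application never re-estimates anything; `iccValidation`
#' holds the per-network ICC(2,1) on the held-out split.
#'
#' @export
setClass("SurrogateModel", representation(
  coef = "matrix", intercept = "numeric", lambda = "numeric",
  center = "numeric", scale = "numeric",
  regionNames = "character", networkNames = "character",
  splitSeed = "integer", iccValidation = "numeric",
  normalize = "character"
))

setValidity("SurrogateModel", function(object) {
  msgs <- character(0)
  R <- length(object@regionNames); K <- length(object@networkNames)
  if (!all(dim(object@coef) == c(R, K))) msgs <- c(msgs, "coef must be R x K")
  if (length(object@intercept) != K || length(object@lambda) != K) {
    msgs <- c(msgs, "intercept and lambda must have one entry per network")
  }
  if (any(object@lambda < 0)) msgs <- c(msgs, "lambda must be >= 0")
  if (length(msgs) == 0) TRUE else msgs
})

#' NetworkMeasures: per-visit network loadings plus whole-brain GM
#'
#' One row per subject-visit: sign-oriented network loadings (optionally
#' z-scored against a reference cohort) and total grey-matter volume
#' (`gmTotal`, the regional sum). Row identity with the source cohort is kept
#' through `sampleKeys`.
#'
#' @export
setClass("NetworkMeasures", representation(
  loadings = "matrix", gmTotal = "numeric", sampleKeys = "data.frame",
  zscored = "logical", zCenter = "numeric", zScale = "numeric"
))

setValidity("NetworkMeasures", function(object) {
  msgs <- character(0)
  n <- nrow(object@loadings)
  if (length(object@gmTotal) != n || nrow(object@sampleKeys) != n) {
    msgs <- c(msgs, "loadings, gmTotal and sampleKeys must agree in rows")
  }
  if (!all(c("subject_id", "visit_index") %in% colnames(object@sampleKeys))) {
    msgs <- c(msgs, "sampleKeys needs subject_id and visit_index")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' CombatFit: empirical-Bayes location/scale harmonization parameters
#'
#' Parametric ComBat fit: per-feature grand intercept, covariate effects and
#' pooled SD; per-batch, per-feature EB-shrunk location (`gammaStar`) and
#' scale (`deltaStar`); and the normal / inverse-gamma prior
#' hyper-parameters.
#'
#' @export
setClass("CombatFit", representation(
  batches = "character", featureNames = "character",
  alpha = "numeric", beta = "matrix", sigma = "numeric",
  gammaStar = "matrix", deltaStar = "matrix",
  gammaBar = "numeric", tau2 = "numeric", aPrior = "numeric",
  bPrior = "numeric", covariateNames = "character", iterations = "integer"
))

setValidity("CombatFit", function(object) {
  if (any(object@deltaStar <= 0)) return("deltaStar must be > 0")
  TRUE
})

#' MixedModelResult: fixed effects and variance components of one LMM
#'
#' REML fit with a random subject intercept: fixed-effect estimates, SEs,
#' Wald-z p-values, 95% CI (beta +/- 1.96 SE), between-subject and residual
#' variances.
#'
#' @export
setClass("MixedModelResult", representation(
  terms = "character", beta = "numeric", se = "numeric", ci95 = "matrix",
  p = "numeric", sigma2Subject = "numeric", sigma2Resid = "numeric",
  nObs = "integer", nSubjects = "integer", converged = "logical"
))

setValidity("MixedModelResult", function(object) {
  msgs <- character(0)
  if (object@sigma2Subject < 0 || object@sigma2Resid < 0) {
    msgs <- c(msgs, "variance components must be >= 0")
  }
  if (any(object@p < 0 | object@p > 1, na.rm = TRUE)) {
    msgs <- c(msgs, "p-values must lie in [0,1]")
  }
  if (any(abs(object@ci95[, 1] - (object@beta - 1.96 * object@se)) > 1e-10) ||
      any(abs(object@ci95[, 2] - (object@beta + 1.96 * object@se)) > 1e-10)) {
    msgs <- c(msgs, "ci95 must equal beta +/- 1.96 * se")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' AnalysisReport: per-network statistics for one analysis family
#'
#' `results` has one row per measure x term with estimate, SE, CI, raw p,
#' BH-adjusted q and a significance flag; `apc` carries annual percentage
#' change summaries per group where applicable.
#'
#' @export
setClass("AnalysisReport", representation(
  analysis = "character", results = "data.frame", apc = "data.frame",
  models = "list"
))

#' TreatmentReport: treatment-effect detection summary
#'
#' Per measure: time x arm interaction statistics, per-arm annual percentage
#' change, first-to-last-visit change difference, pooled SD, Cohen's d and
#' the per-arm sample size at alpha = 0.05, power = 0.80.
#'
#' @export
setClass("TreatmentReport", representation(
  results = "data.frame", models = "list", alpha = "numeric",
  power = "numeric", excludedSubjects = "integer"
))
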