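# JSON serialization of fitted models (full precision, self-describing).

serMat <- function(m) {
  list(values = as.numeric(m), nrow = nrow(m), ncol = ncol(m),
       rownames = rownames(m), colnames = colnames(m))
}

deserMat <- function(l) {
  m <- matrix(as.numeric(l$values), l$nrow, l$ncol)
  if (!is.null(l$rownames)) rownames(m) <- l$rownames
  if (!is.null(l$colnames)) colnames(m) <- l$colnames
  m
}

provenanceBlock <- function(extra = list()) {
  c(list(tool = "gmnets",
         version = as.character(utils::packageVersion("gmnets")),
         convention = "observations are ICA samples; maps are mixing rows"),
    extra)
}

writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Serialize an ICA decomposition to JSON
#' @param ica an [ICADecomposition-class]
#' @param path output path
#' @param provenance optional named list merged into the provenance block
#' @return `path`, invisibly
#' @export
writeICAModel <- function(ica, path, provenance = list()) {
  writeJson(list(
    class = "ICADecomposition", provenance = provenanceBlock(provenance),
    K = ica@K, center = ica@center, whitening = serMat(ica@whitening),
    unmixing = serMat(ica@unmixing), maps = serMat(ica@maps),
    loadings = serMat(ica@loadings), orientFlags = ica@orientFlags,
    converged = ica@converged, iterations = ica@iterations, seed = ica@seed,
    regionNames = ica@regionNames, normalize = ica@normalize,
    sampleKeys = list(subject_id = ica@sampleKeys$subject_id,
                      visit_index = ica@sampleKeys$visit_index)), path)
}

#' Read an ICA decomposition from JSON
#' @param path JSON path written by [writeICAModel()]
#' @return an [ICADecomposition-class]
#' @export
readICAModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(j$class, "ICADecomposition"))
  rn <- as.character(j$regionNames)
  methods::new("ICADecomposition",
    K = as.integer(j$K),
    center = stats::setNames(as.numeric(j$center), rn),
    whitening = deserMat(j$whitening), unmixing = deserMat(j$unmixing),
    maps = deserMat(j$maps), loadings = deserMat(j$loadings),
    orientFlags = as.numeric(j$orientFlags), converged = j$converged,
    iterations = as.integer(j$iterations), seed = as.integer(j$seed),
    regionNames = rn,
    normalize = as.character(j$normalize),
    sampleKeys = data.frame(subject_id = j$sampleKeys$subject_id,
                            visit_index = as.integer(j$sampleKeys$visit_index),
                            stringsAsFactors = FALSE))
}

#' Serialize a surrogate model to JSON
#' @param model a [SurrogateModel-class]
#' @param path output path
#' @param provenance optional named list merged into the provenance block
#' @return `path`, invisibly
#' @export
writeSurrogateModel <- function(model, path, provenance = list()) {
  writeJson(list(
    class = "SurrogateModel", provenance = provenanceBlock(provenance),
    coef = serMat(model@coef), intercept = model@intercept,
    lambda = model@lambda, center = model@center, scale = model@scale,
    regionNames = model@regionNames, networkNames = model@networkNames,
    splitSeed = model@splitSeed, iccValidation = model@iccValidation,
    normalize = model@normalize), path)
}

#' Read a surrogate model from JSON
#' @param path JSON path written by [writeSurrogateModel()]
#' @return a [SurrogateModel-class]
#' @export
readSurrogateModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(j$class, "SurrogateModel"))
  rn <- as.character(j$regionNames)
  methods::new("SurrogateModel",
    coef = deserMat(j$coef), intercept = as.numeric(j$intercept),
    lambda = as.numeric(j$lambda),
    center = stats::setNames(as.numeric(j$center), rn),
    scale = stats::setNames(as.numeric(j$scale), rn),
    regionNames = rn,
    networkNames = as.character(j$networkNames),
    splitSeed = as.integer(j$splitSeed),
    iccValidation = as.numeric(j$iccValidation),
    normalize = as.character(j$normalize))
}

#' Serialize a ground truth to JSON
#' @param gt a [GroundTruth-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeGroundTruth <- function(gt, path) {
  writeJson(list(
    class = "GroundTruth", provenance = provenanceBlock(),
    K = gt@K, R = gt@R, regionNames = gt@regionNames, maps = serMat(gt@maps),
    muRegion = gt@muRegion, baselineMean = serMat(gt@baselineMean),
    baselineScale = gt@baselineScale, slopes = serMat(gt@slopes),
    treatDelta = gt@treatDelta, clinicalWeights = gt@clinicalWeights,
    sigmaLoading = gt@sigmaLoading, sigmaRegion = gt@sigmaRegion,
    sigmaEdss = gt@sigmaEdss, siteGain = serMat(gt@siteGain),
    refTiv = gt@refTiv, edssIntercept = gt@edssIntercept,
    edssAgeCoef = gt@edssAgeCoef, edssTimeAmp = gt@edssTimeAmp,
    seed = gt@seed), path)
}

#' Read a ground truth from JSON
#' @param path JSON path written by [writeGroundTruth()]
#' @return a [GroundTruth-class]
#' @export
readGroundTruth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(j$class, "GroundTruth"))
  methods::new("GroundTruth",
    K = as.integer(j$K), R = as.integer(j$R),
    regionNames = as.character(j$regionNames), maps = deserMat(j$maps),
    muRegion = as.numeric(j$muRegion), baselineMean = deserMat(j$baselineMean),
    baselineScale = as.numeric(j$baselineScale), slopes = deserMat(j$slopes),
    treatDelta = as.numeric(j$treatDelta),
    clinicalWeights = as.numeric(j$clinicalWeights),
    sigmaLoading = as.numeric(j$sigmaLoading),
    sigmaRegion = as.numeric(j$sigmaRegion),
    sigmaEdss = as.numeric(j$sigmaEdss), siteGain = deserMat(j$siteGain),
    refTiv = as.numeric(j$refTiv), edssIntercept = as.numeric(j$edssIntercept),
    edssAgeCoef = as.numeric(j$edssAgeCoef),
    edssTimeAmp = as.numeric(j$edssTimeAmp), seed = as.integer(j$seed))
}

#' Serialize a ComBat fit to JSON
#' @param fit a [CombatFit-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeCombatFit <- function(fit, path) {
  writeJson(list(
    class = "CombatFit", provenance = provenanceBlock(),
    batches = fit@batches, featureNames = fit@featureNames,
    alpha = fit@alpha, beta = serMat(fit@beta), sigma = fit@sigma,
    gammaStar = serMat(fit@gammaStar), deltaStar = serMat(fit@deltaStar),
    gammaBar = fit@gammaBar, tau2 = fit@tau2, aPrior = fit@aPrior,
    bPrior = fit@bPrior, covariateNames = fit@covariateNames,
    iterations = fit@iterations), path)
}

#' Serialize an analysis or treatment report to JSON
#' @param report an [AnalysisReport-class] or [TreatmentReport-class]
#' @param path output path
#' @param provenance optional named list merged into the provenance block
#' @return `path`, invisibly
#' @export
writeReport <- function(report, path, provenance = list()) {
  if (methods::is(report, "AnalysisReport")) {
    writeJson(list(class = "AnalysisReport",
                   provenance = provenanceBlock(provenance),
                   analysis = report@analysis, results = report@results,
                   apc = report@apc), path)
  } else if (methods::is(report, "TreatmentReport")) {
    writeJson(list(class = "TreatmentReport",
                   provenance = provenanceBlock(provenance),
                   alpha = report@alpha, power = report@power,
                   excludedSubjects = report@excludedSubjects,
                   results = report@results), path)
  } else stop("unsupported report class")
}
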