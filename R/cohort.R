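# Cohort container: construction, accessors, CSV I/O.

#' Construct an MSCohort
#'
#' @param volumes numeric matrix of regional grey-matter volumes, regions x
#'   subject-visits (mm^3), with region names as rownames.
#' @param sampleData data.frame (or DataFrame) of per-visit covariates with
#'   the columns `subject_id`, `trial_id`, `site_id`, `phenotype`, `arm`,
#'   `visit_index`, `time_years`, `age_baseline`, `sex`, `disease_duration`,
#'   `tiv`, `edss`.
#'
#' Rows are sorted by (subject_id, visit_index) and validated against the
#' cohort invariants (see [MSCohort-class]).
#'
#' @return a validated [MSCohort-class]
#' @export
MSCohort <- function(volumes, sampleData) {
  if (!is.matrix(volumes)) volumes <- as.matrix(volumes)
  sampleData <- as.data.frame(sampleData)
  if (nrow(sampleData) == 0) stop("empty cohort: no subject-visit rows")
  if (ncol(volumes) != nrow(sampleData)) {
    stop("volumes must have one column per sampleData row")
  }
  missing_cols <- setdiff(.COHORT_COLS, colnames(sampleData))
  if (length(missing_cols) > 0) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  ord <- order(as.character(sampleData$subject_id),
               as.integer(sampleData$visit_index))
  volumes <- volumes[, ord, drop = FALSE]
  sampleData <- sampleData[ord, , drop = FALSE]
  sampleData$subject_id <- as.character(sampleData$subject_id)
  sampleData$visit_index <- as.integer(sampleData$visit_index)
  colnames(volumes) <- paste(sampleData$subject_id, sampleData$visit_index,
                             sep = ".")
  obj <- methods::new(
    "MSCohort",
    SummarizedExperiment::SummarizedExperiment(
      assays = list(volumes = volumes),
      colData = S4Vectors::DataFrame(sampleData, row.names = colnames(volumes))
    )
  )
  methods::validObject(obj)
  obj
}

#' @describeIn MSCohort region labels
#' @param x an `MSCohort`
#' @export
regionNames <- function(x) rownames(x)

#' Regional volume matrix, observations x regions
#'
#' The transpose of the `volumes` assay, convenient for model fitting where
#' subject-visits are the statistical units.
#' @param x an [MSCohort-class]
#' @return numeric matrix, one row per subject-visit
#' @export
regionVolumes <- function(x) t(SummarizedExperiment::assay(x, "volumes"))

#' Per-visit covariate table
#' @param x an [MSCohort-class]
#' @return a plain `data.frame` of covariates
#' @export
sampleData <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

#' Subject/visit identity keys
#' @param x an [MSCohort-class] or [NetworkMeasures-class]
#' @return data.frame with `subject_id` and `visit_index`
#' @export
sampleKeys <- function(x) {
  if (methods::is(x, "NetworkMeasures")) {
    return(x@sampleKeys[, c("subject_id", "visit_index")])
  }
  cd <- sampleData(x)
  data.frame(subject_id = cd$subject_id, visit_index = cd$visit_index,
             stringsAsFactors = FALSE)
}

#' @describeIn MSCohort unique subject identifiers
#' @export
subjectIds <- function(x) unique(sampleData(x)$subject_id)

#' Whole-brain grey-matter volume per subject-visit
#'
#' Defined as the sum of the regional grey-matter volumes, the whole-brain
#' measure reconstructible from a regional segmentation.
#'
#' @param x an [MSCohort-class]
#' @return numeric vector, one value per subject-visit (mm^3)
#' @export
wholeBrainGM <- function(x) {
  unname(colSums(SummarizedExperiment::assay(x, "volumes")))
}

#' Read a cohort from CSV
#'
#' Expects one row per subject-visit; covariate columns as in
#' [MSCohort()]; region columns identified by `regionPrefix`. Missing EDSS
#' is an empty field. The returned object is validated, with distinct errors
#' for missing columns, duplicate subject-visits, missing baselines,
#' non-monotone visit times and negative volumes.
#'
#' @param path CSV file path
#' @param regionPrefix prefix naming the region columns (default `"gmv_"`)
#' @return a validated [MSCohort-class]
#' @export
readCohort <- function(path, regionPrefix = "gmv_") {
  dt <- data.table::fread(path, sep = ",", na.strings = "",
                          colClasses = list(character = "subject_id"),
                          data.table = FALSE, showProgress = FALSE)
  region_cols <- grep(paste0("^", regionPrefix), colnames(dt), value = TRUE)
  if (length(region_cols) == 0) {
    stop(sprintf("no region columns with prefix '%s' found", regionPrefix))
  }
  missing_cols <- setdiff(.COHORT_COLS, colnames(dt))
  if (length(missing_cols) > 0) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  vol <- t(as.matrix(dt[, region_cols, drop = FALSE]))
  rownames(vol) <- sub(paste0("^", regionPrefix), "", region_cols)
  MSCohort(vol, dt[, .COHORT_COLS, drop = FALSE])
}

#' Write a cohort to CSV
#'
#' Inverse of [readCohort()]: comma-separated, UTF-8, `.` decimal, missing
#' values as empty fields; values survive a read/write round trip exactly.
#'
#' @param x an [MSCohort-class]
#' @param path output CSV path
#' @param regionPrefix prefix for region columns (default `"gmv_"`)
#' @return `path`, invisibly
#' @export
writeCohort <- function(x, path, regionPrefix = "gmv_") {
  stopifnot(methods::is(x, "MSCohort"))
  if (ncol(x) == 0) stop("empty cohort: nothing to write")
  vol <- regionVolumes(x)
  colnames(vol) <- paste0(regionPrefix, colnames(vol))
  out <- cbind(sampleData(x)[, .COHORT_COLS, drop = FALSE],
               as.data.frame(vol))
  # 17 significant digits so values survive the round trip exactly
  data.table::fwrite(formatExact(out), path, sep = ",", na = "",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

setMethod("show", "MSCohort", function(object) {
  cd <- sampleData(object)
  cat(sprintf("MSCohort: %d subject-visits, %d subjects, %d regions\n",
              ncol(object), length(unique(cd$subject_id)), nrow(object)))
  cat(sprintf("  phenotypes: %s\n",
              paste(sprintf("%s=%d", names(table(cd$phenotype)),
                            as.integer(table(cd$phenotype))), collapse = " ")))
  cat(sprintf("  sites: %d; trials: %d; time span %.2g-%.2g years\n",
              length(unique(cd$site_id)), length(unique(cd$trial_id)),
              min(cd$time_years), max(cd$time_years)))
})
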