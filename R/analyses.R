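# Analysis families: phenotype trajectories, EDSS associations, stepwise
# predictor selection.

#' Align measures with cohort covariates into one analysis frame
#' @keywords internal
#' @noRd
analysisFrame <- function(measures, cohort) {
  stopifnot(methods::is(measures, "NetworkMeasures"),
            methods::is(cohort, "MSCohort"))
  if (!identical(sampleKeys(measures), sampleKeys(cohort))) {
    stop("measures and cohort rows do not match (subject/visit keys differ)")
  }
  cd <- sampleData(cohort)
  df <- data.frame(
    subject_id = cd$subject_id,
    phenotype = factor(cd$phenotype, levels = .PHENOTYPES),
    arm = factor(cd$arm),
    time_years = cd$time_years,
    age_baseline = cd$age_baseline,
    sex = factor(cd$sex, levels = c("F", "M")),
    disease_duration = cd$disease_duration,
    tiv_l = cd$tiv / 1e6,             # litres; keeps the design well scaled
    edss = cd$edss,
    stringsAsFactors = FALSE
  )
  cbind(df, as.data.frame(measures@loadings), gm_total = measures@gmTotal)
}

#' Measure column names of a NetworkMeasures object, plus whole-brain GM
#' @keywords internal
#' @noRd
measureNames <- function(measures, includeWholeBrain = TRUE) {
  c(colnames(measures@loadings), if (includeWholeBrain) "gm_total")
}

#' Phenotype trajectory analysis
#'
#' Per measure (each network loading and whole-brain GM), fits the
#' random-intercept model
#' `measure ~ phenotype * time + age_baseline + sex + disease_duration +
#' tiv + arm`, with the requested reference phenotype. Reports baseline
#' contrasts (phenotype main effects) and slope contrasts
#' (phenotype x time), with BH-FDR applied across measures within each
#' contrast family, and annual percentage change per phenotype group.
#'
#' @param measures a [NetworkMeasures-class]
#' @param cohort the matching [MSCohort-class]
#' @param reference reference phenotype level (default "SP")
#' @param alpha FDR level
#' @return an [AnalysisReport-class]
#' @export
phenotypeTrajectories <- function(measures, cohort, reference = "SP",
                                  alpha = 0.05) {
  df <- analysisFrame(measures, cohort)
  present <- levels(droplevels(df$phenotype))
  if (!reference %in% present) {
    stop(sprintf("phenotype '%s' absent from data", reference))
  }
  if (length(present) < 2) stop("need at least 2 phenotypes")
  df$phenotype <- stats::relevel(droplevels(df$phenotype), ref = reference)

  covar_terms <- c("age_baseline", "sex", "disease_duration", "tiv_l")
  if (nlevels(droplevels(df$arm)) > 1) covar_terms <- c(covar_terms, "arm")
  fml <- stats::as.formula(paste(
    "~ phenotype * time_years +", paste(covar_terms, collapse = " + ")))
  X <- stats::model.matrix(fml, df)

  msrs <- measureNames(measures)
  other <- setdiff(present, reference)
  base_terms <- paste0("phenotype", other)
  slope_terms <- paste0("phenotype", other, ":time_years")

  models <- list()
  rows <- list()
  apc_rows <- list()
  for (m in msrs) {
    res <- fitLMM(df[[m]], X, df$subject_id)
    models[[m]] <- res
    for (tm in c(base_terms, slope_terms)) {
      rec <- lmmTerm(res, tm)
      rec$measure <- m
      rec$family <- if (grepl(":time_years$", tm)) "slope" else "baseline"
      rec$contrast <- sub(":time_years$", "", sub("^phenotype", "", tm))
      rows[[length(rows) + 1]] <- rec
    }
    # per-group APC: reference slope is the time term; others add interaction
    msd <- stats::sd(df[[m]])
    for (g in present) {
      sl <- res@beta[match("time_years", res@terms)]
      if (g != reference) {
        sl <- sl + res@beta[match(paste0("phenotype", g, ":time_years"),
                                  res@terms)]
      }
      bmean <- mean(df[[m]][df$phenotype == g & df$time_years == 0])
      apc <- annualPctChange(sl, bmean, msd)
      apc_rows[[length(apc_rows) + 1]] <- data.frame(
        measure = m, group = g, slope = unname(sl), baseline_mean = bmean,
        apc = apc$apc, is_percentage = apc$isPercentage,
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  results$q <- NA_real_
  results$significant <- FALSE
  for (fam in unique(paste(results$family, results$contrast))) {
    idx <- paste(results$family, results$contrast) == fam
    adj <- bhFdr(results$p[idx], alpha)
    results$q[idx] <- adj$q
    results$significant[idx] <- adj$reject
  }
  results <- results[, c("measure", "family", "contrast", "beta", "se",
                         "lower", "upper", "p", "q", "significant")]
  methods::new("AnalysisReport",
    analysis = sprintf("phenotype trajectories (reference %s)", reference),
    results = results, apc = do.call(rbind, apc_rows), models = models)
}

#' EDSS association analysis
#'
#' Per selected network (z-scored loading) and optionally whole-brain GM,
#' fits `EDSS ~ loading * time + age_baseline + sex + disease_duration +
#' tiv + arm` with a random subject intercept, on complete EDSS cases. The
#' loading main effect is the baseline association and loading x time the
#' progression association; BH-FDR across the selected measures within each
#' family.
#'
#' @param measures a [NetworkMeasures-class]
#' @param cohort the matching [MSCohort-class]
#' @param networks network names (or indices) to test; default all
#' @param includeWholeBrain also test z-scored whole-brain GM
#' @param alpha FDR level
#' @return an [AnalysisReport-class]
#' @export
edssAssociation <- function(measures, cohort, networks = NULL,
                            includeWholeBrain = TRUE, alpha = 0.05) {
  zm <- if (isTRUE(measures@zscored)) measures else zscoreMeasures(measures)
  df <- analysisFrame(zm, cohort)
  if (all(is.na(df$edss))) stop("all EDSS values missing")
  df <- df[!is.na(df$edss), , drop = FALSE]
  if (is.null(networks)) networks <- colnames(zm@loadings)
  if (is.numeric(networks)) networks <- colnames(zm@loadings)[networks]
  if (isTRUE(includeWholeBrain)) {
    df$gm_total_z <- (df$gm_total - mean(df$gm_total)) / stats::sd(df$gm_total)
    networks <- c(networks, "gm_total_z")
  }

  covar_terms <- c("age_baseline", "sex", "disease_duration", "tiv_l")
  if (nlevels(droplevels(df$arm)) > 1) covar_terms <- c(covar_terms, "arm")

  models <- list(); rows <- list()
  for (m in networks) {
    df$.z <- df[[m]]
    fml <- stats::as.formula(paste(
      "~ .z * time_years +", paste(covar_terms, collapse = " + ")))
    X <- stats::model.matrix(fml, df)
    res <- fitLMM(df$edss, X, df$subject_id)
    models[[m]] <- res
    for (fam in c("baseline", "progression")) {
      tm <- if (fam == "baseline") ".z" else ".z:time_years"
      rec <- lmmTerm(res, tm)
      rec$measure <- m
      rec$family <- fam
      rows[[length(rows) + 1]] <- rec
    }
  }
  results <- do.call(rbind, rows)
  results$q <- NA_real_; results$significant <- FALSE
  for (fam in unique(results$family)) {
    idx <- results$family == fam
    adj <- bhFdr(results$p[idx], alpha)
    results$q[idx] <- adj$q
    results$significant[idx] <- adj$reject
  }
  results <- results[, c("measure", "family", "beta", "se", "lower", "upper",
                         "p", "q", "significant")]
  methods::new("AnalysisReport", analysis = "EDSS association",
               results = results, apc = data.frame(), models = models)
}

#' Subject-level frame for cross-sectional / change-score regression
#'
#' One row per subject: baseline (time == 0) network measures and
#' whole-brain GM, subject covariates, number of visits, and the outcome --
#' either baseline EDSS or the per-subject OLS slope of EDSS on time
#' (subjects need >= 2 non-missing EDSS visits for the slope outcome).
#'
#' @param measures a [NetworkMeasures-class]
#' @param cohort the matching [MSCohort-class]
#' @param outcome `"edss_baseline"` or `"edss_slope"`
#' @return data.frame, one row per subject with an `outcome` column
#' @export
subjectLevelData <- function(measures, cohort,
                             outcome = c("edss_baseline", "edss_slope")) {
  outcome <- match.arg(outcome)
  df <- analysisFrame(measures, cohort)
  msrs <- measureNames(measures)
  by_subj <- split(df, df$subject_id)
  rows <- lapply(by_subj, function(d) {
    d <- d[order(d$time_years), , drop = FALSE]
    base <- d[d$time_years == 0, , drop = FALSE][1, , drop = FALSE]
    out <- if (outcome == "edss_baseline") {
      base$edss
    } else {
      dd <- d[!is.na(d$edss), , drop = FALSE]
      if (nrow(dd) < 2) NA_real_ else
        unname(stats::coef(stats::lm(edss ~ time_years, data = dd))[2])
    }
    cbind(base[, c("subject_id", "phenotype", "arm", "age_baseline", "sex",
                   "disease_duration", "tiv_l", msrs), drop = FALSE],
          n_visits = nrow(d), outcome = out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[!is.na(out$outcome), , drop = FALSE]
}

#' Bidirectional stepwise selection with forced covariates
#'
#' AIC-driven bidirectional stepwise linear regression starting from the
#' full model (all candidates + covariates), with the covariates always
#' retained via the lower scope. With no candidates, the covariate-only
#' model is returned.
#'
#' @param data data.frame with the outcome, candidates and covariates
#' @param outcome outcome column name
#' @param candidates candidate predictor column names
#' @param covariates forced covariate column names
#' @return list with `selected` (candidate names retained), `model` (the
#'   final `lm`), and `adjustedR2`
#' @export
stepwiseSelection <- function(data, outcome, candidates, covariates) {
  data <- data[stats::complete.cases(data[, c(outcome, candidates, covariates)]),
               , drop = FALSE]
  n <- nrow(data)
  p_full <- length(candidates) + length(covariates)
  if (n <= p_full + 1) stop("n too small for the full model")
  lower_fml <- stats::as.formula(paste(
    outcome, "~", if (length(covariates)) paste(covariates, collapse = " + ")
    else "1"))
  if (length(candidates) == 0) {
    m <- stats::lm(lower_fml, data = data)
    return(list(selected = character(0), model = m,
                adjustedR2 = summary(m)$adj.r.squared))
  }
  full_fml <- stats::as.formula(paste(
    outcome, "~", paste(c(covariates, candidates), collapse = " + ")))
  full <- stats::lm(full_fml, data = data)
  final <- stats::step(full, scope = list(lower = lower_fml, upper = full_fml),
                       direction = "both", trace = 0)
  kept <- intersect(candidates, attr(stats::terms(final), "term.labels"))
  list(selected = kept, model = final,
       adjustedR2 = summary(final)$adj.r.squared)
}

setMethod("show", "AnalysisReport", function(object) {
  cat(sprintf("AnalysisReport: %s\n", object@analysis))
  sig <- object@results
  cat(sprintf("  %d tests; %d significant after BH-FDR\n",
              nrow(sig), sum(sig$significant)))
  print(utils::head(sig[order(sig$q), ], 10), row.names = FALSE, digits = 3)
})
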