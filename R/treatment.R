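# Treatment-effect detection, first-to-last-visit effect sizes, per-arm
# sample size.

#' Time x treatment-arm mixed models per measure
#'
#' Per measure (each network loading and whole-brain GM), fits
#' `measure ~ time * arm + age_baseline + sex + tiv` with a random subject
#' intercept; the time x arm interaction is the treatment-effect test,
#' BH-corrected across measures. Annual percentage change is reported per
#' arm (comparator slope = time term; treated adds the interaction).
#'
#' @param measures a [NetworkMeasures-class]
#' @param cohort the matching [MSCohort-class]; both `treated` and
#'   `comparator` arms must be present
#' @param alpha FDR level
#' @return list with `results` (one row per measure) and `models`
#' @export
treatmentModel <- function(measures, cohort, alpha = 0.05) {
  df <- analysisFrame(measures, cohort)
  df <- df[df$arm %in% c("treated", "comparator"), , drop = FALSE]
  arms <- unique(as.character(df$arm))
  if (length(arms) < 2) stop("single-arm data: need treated and comparator")
  df$arm <- factor(as.character(df$arm), levels = c("comparator", "treated"))
  X <- stats::model.matrix(~ time_years * arm + age_baseline + sex + tiv_l, df)

  msrs <- measureNames(measures)
  models <- list(); rows <- list()
  for (m in msrs) {
    res <- fitLMM(df[[m]], X, df$subject_id)
    models[[m]] <- res
    rec <- lmmTerm(res, "time_years:armtreated")
    rec$measure <- m
    sl_comp <- res@beta[match("time_years", res@terms)]
    sl_trt <- sl_comp + rec$beta
    msd <- stats::sd(df[[m]])
    b_comp <- mean(df[[m]][df$arm == "comparator" & df$time_years == 0])
    b_trt <- mean(df[[m]][df$arm == "treated" & df$time_years == 0])
    rec$apc_treated <- annualPctChange(sl_trt, b_trt, msd)$apc
    rec$apc_comparator <- annualPctChange(sl_comp, b_comp, msd)$apc
    rows[[length(rows) + 1]] <- rec
  }
  results <- do.call(rbind, rows)
  adj <- bhFdr(results$p, alpha)
  results$q <- adj$q
  results$significant <- adj$reject
  results <- results[, c("measure", "beta", "se", "lower", "upper", "p", "q",
                         "significant", "apc_treated", "apc_comparator")]
  rownames(results) <- NULL
  list(results = results, models = models)
}

#' First-to-last-visit change and Cohen's d per measure
#'
#' Per subject, the change between the earliest and latest available visit;
#' per measure, the arm difference of mean change and Cohen's d using the
#' pooled SD of the change score across both arms. Subjects with a single
#' visit are excluded (count reported). By default the change scores are
#' unadjusted; `residualize` optionally removes subject-level covariate
#' effects from them (OLS residuals, arms pooled) before the effect size
#' is computed.
#'
#' @param measures a [NetworkMeasures-class]
#' @param cohort the matching [MSCohort-class]
#' @param residualize optional character vector of subject-level covariate
#'   columns (e.g. `c("age_baseline", "sex")`) to residualize the change
#'   scores on
#' @return list with `effects` (measure, delta_change, pooled_sd, cohens_d,
#'   n_treated, n_comparator) and `excluded` (single-visit subjects)
#' @export
firstLastEffectSize <- function(measures, cohort, residualize = NULL) {
  df <- analysisFrame(measures, cohort)
  df <- df[df$arm %in% c("treated", "comparator"), , drop = FALSE]
  if (length(unique(as.character(df$arm))) < 2) {
    stop("single-arm data: need treated and comparator")
  }
  msrs <- measureNames(measures)
  by_subj <- split(df, df$subject_id)
  n_excluded <- sum(vapply(by_subj, nrow, integer(1)) < 2)
  if (n_excluded > 0) {
    message(sprintf("%d subject(s) with a single visit excluded from the change score",
                    n_excluded))
  }
  chg <- lapply(by_subj, function(d) {
    if (nrow(d) < 2) return(NULL)
    d <- d[order(d$time_years), , drop = FALSE]
    delta <- as.numeric(d[nrow(d), msrs]) - as.numeric(d[1, msrs])
    cbind(d[1, c("arm", "age_baseline", "sex", "disease_duration", "tiv_l"),
            drop = FALSE],
          as.data.frame(t(delta)))
  })
  chg <- do.call(rbind, chg)
  colnames(chg)[-(1:5)] <- msrs
  chg$arm <- as.character(chg$arm)
  if (!is.null(residualize)) {
    bad <- setdiff(residualize, c("age_baseline", "sex", "disease_duration",
                                  "tiv_l"))
    if (length(bad) > 0) {
      stop(sprintf("unknown residualization covariate(s): %s",
                   paste(bad, collapse = ", ")))
    }
    fml <- stats::as.formula(paste("~", paste(residualize, collapse = " + ")))
    Xr <- stats::model.matrix(fml, chg)
    for (m in msrs) {
      fitted <- Xr %*% stats::coef(stats::lm.fit(Xr, chg[[m]]))
      chg[[m]] <- as.numeric(chg[[m]] - fitted + mean(chg[[m]]))
    }
  }

  rows <- lapply(msrs, function(m) {
    x_t <- chg[[m]][chg$arm == "treated"]
    x_c <- chg[[m]][chg$arm == "comparator"]
    n1 <- length(x_t); n2 <- length(x_c)
    sp <- sqrt(((n1 - 1) * stats::var(x_t) + (n2 - 1) * stats::var(x_c)) /
                 (n1 + n2 - 2))
    if (!is.finite(sp) || sp == 0) {
      stop(sprintf("measure %s: zero pooled SD of the change score; effect size undefined", m))
    }
    data.frame(measure = m, delta_change = mean(x_t) - mean(x_c),
               pooled_sd = sp, cohens_d = (mean(x_t) - mean(x_c)) / sp,
               n_treated = n1, n_comparator = n2, stringsAsFactors = FALSE)
  })
  list(effects = do.call(rbind, rows), excluded = as.integer(n_excluded))
}

#' Per-arm sample size for a two-sample t-test
#'
#' Smallest integer n per arm such that a two-sided two-sample t-test at
#' level `alpha` with standardized effect `d` (noncentrality d * sqrt(n/2),
#' df 2n - 2) achieves the target power. Noncentral-t computation via
#' [stats::power.t.test()], with the ceiling applied.
#'
#' @param d Cohen's d (nonzero; the sign is irrelevant)
#' @param alpha two-sided significance level
#' @param power target power
#' @return integer n per arm
#' @export
sampleSizePerArm <- function(d, alpha = 0.05, power = 0.80) {
  if (!is.finite(d) || d == 0) stop("d = 0: sample size is infinite")
  n <- stats::power.t.test(delta = abs(d), sd = 1, sig.level = alpha,
                           power = power, type = "two.sample",
                           alternative = "two.sided")$n
  max(2L, as.integer(ceiling(n - 1e-9)))
}

#' Monte-Carlo power of the two-sample t-test
#'
#' Simulates `nsim` pairs of normal samples of size `n` with standardized
#' mean difference `d` and returns the percentage of two-sided pooled-SD
#' t-tests rejecting at level `alpha`.
#'
#' @param d standardized mean difference
#' @param n sample size per arm
#' @param nsim number of simulated trials
#' @param alpha two-sided level
#' @param seed integer seed
#' @return rejection percentage (0--100)
#' @export
ttestPowerSim <- function(d, n, nsim = 10000, alpha = 0.05, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * nsim, mean = d), n, nsim)
  y <- matrix(stats::rnorm(n * nsim, mean = 0), n, nsim)
  mx <- colMeans(x); my <- colMeans(y)
  vx <- (colSums(x^2) - n * mx^2) / (n - 1)
  vy <- (colSums(y^2) - n * my^2) / (n - 1)
  tt <- (mx - my) / sqrt((vx + vy) / n)
  crit <- stats::qt(1 - alpha / 2, df = 2 * n - 2)
  100 * mean(abs(tt) > crit)
}

#' Full treatment-effect report
#'
#' Combines the time x arm mixed models, the first-to-last-visit effect
#' sizes and per-arm sample-size estimates (for measures with nonzero d)
#' into a [TreatmentReport-class].
#'
#' @param measures a [NetworkMeasures-class]
#' @param cohort the matching [MSCohort-class]
#' @param alpha significance/FDR level
#' @param power target power for the sample-size column
#' @return a [TreatmentReport-class]
#' @export
treatmentAnalysis <- function(measures, cohort, alpha = 0.05, power = 0.80) {
  tm <- treatmentModel(measures, cohort, alpha = alpha)
  fl <- firstLastEffectSize(measures, cohort)
  res <- merge(tm$results, fl$effects, by = "measure", sort = FALSE)
  res$n_per_arm <- vapply(res$cohens_d, function(d) {
    if (!is.finite(d) || d == 0) NA_integer_
    else sampleSizePerArm(d, alpha = alpha, power = power)
  }, integer(1))
  methods::new("TreatmentReport", results = res, models = tm$models,
               alpha = alpha, power = power, excludedSubjects = fl$excluded)
}

setMethod("show", "TreatmentReport", function(object) {
  r <- object@results
  cat(sprintf("TreatmentReport: %d measures; %d with a treatment effect (BH-FDR, alpha %.2g)\n",
              nrow(r), sum(r$significant), object@alpha))
  print(utils::head(r[order(r$q), c("measure", "beta", "p", "q",
                                    "apc_treated", "apc_comparator",
                                    "cohens_d", "n_per_arm")], 10),
        row.names = FALSE, digits = 3)
})
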