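# REML linear mixed models, BH-FDR, annual percentage change.

#' Fit a random-intercept linear mixed model (REML)
#'
#' One observation per visit with a random subject intercept plus residual
#' ("visit nested within subject" with a single row per visit reduces to
#' exactly this structure; a visit-level random effect would be confounded
#' with the residual). REML estimation, generalized least squares for the
#' fixed effects, Wald z inference, 95% CI = beta +/- 1.96 SE.
#'
#' @param y numeric response, one value per observation
#' @param X fixed-effects design matrix (include the intercept column)
#' @param subject subject identifier per observation
#' @return a [MixedModelResult-class]
#' @export
fitLMM <- function(y, X, subject) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X must have one row per observation")
  if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(ncol(X)))
  keep <- is.finite(y) & apply(is.finite(X), 1, all)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  subject <- as.character(subject)[keep]
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effects design")
  if (length(y) <= ncol(X) + 2) stop("too few observations for the design")

  dat <- list(.y = y, .X = X, .sid = factor(subject))
  fit <- suppressMessages(lme4::lmer(
    .y ~ 0 + .X + (1 | .sid), data = dat, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)))
  beta <- lme4::fixef(fit)
  names(beta) <- sub("^\\.X", "", names(beta))
  se <- sqrt(Matrix::diag(stats::vcov(fit)))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  vc <- lme4::VarCorr(fit)
  s2_subj <- as.numeric(vc$.sid)
  s2_res <- stats::sigma(fit)^2
  conv <- length(fit@optinfo$conv$lme4$messages) == 0 &&
    fit@optinfo$conv$opt == 0
  ci <- cbind(beta - 1.96 * se, beta + 1.96 * se)
  colnames(ci) <- c("lower", "upper")

  obj <- methods::new("MixedModelResult",
    terms = names(beta), beta = unname(beta), se = unname(se), ci95 = unname(ci),
    p = unname(p), sigma2Subject = s2_subj, sigma2Resid = s2_res,
    nObs = length(y), nSubjects = length(unique(subject)),
    converged = isTRUE(conv))
  methods::validObject(obj)
  obj
}

#' Extract one term's statistics from a MixedModelResult
#' @keywords internal
#' @noRd
lmmTerm <- function(res, term) {
  i <- match(term, res@terms)
  if (is.na(i)) stop(sprintf("term '%s' not in the fitted model", term))
  data.frame(term = term, beta = res@beta[i], se = res@se[i],
             lower = res@ci95[i, 1], upper = res@ci95[i, 2], p = res@p[i],
             stringsAsFactors = FALSE)
}

#' Benjamini--Hochberg false-discovery-rate correction
#'
#' Step-up BH procedure: returns monotone q-values and rejection flags at
#' level `alpha`.
#'
#' @param p vector of p-values in [0, 1]
#' @param alpha FDR level (default 0.05)
#' @return list with `q` and logical `reject`
#' @export
bhFdr <- function(p, alpha = 0.05) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, reject = !is.na(q) & q <= alpha)
}

#' Annual percentage change from a slope and a baseline mean
#'
#' APC = 100 * slope / |baseline mean| (% per year). When the baseline mean
#' is within `eps` * SD(measure) of zero a percentage is meaningless; the
#' absolute slope is returned with `isPercentage = FALSE`.
#'
#' @param slope model slope per year (measure units/year)
#' @param baselineMean group mean of the measure at baseline (time == 0)
#' @param measureSd SD of the measure, for the near-zero guard (defaults to
#'   |baselineMean| so the guard only triggers on exact zero)
#' @param eps near-zero threshold, as a fraction of `measureSd`
#' @return list with `apc` and `isPercentage`
#' @export
annualPctChange <- function(slope, baselineMean, measureSd = NULL,
                            eps = 1e-6) {
  if (is.null(measureSd) || !is.finite(measureSd)) measureSd <- 1
  if (abs(baselineMean) < eps * max(measureSd, .Machine$double.eps)) {
    return(list(apc = slope, isPercentage = FALSE))
  }
  list(apc = 100 * slope / abs(baselineMean), isPercentage = TRUE)
}

setMethod("show", "MixedModelResult", function(object) {
  cat(sprintf("MixedModelResult: %d obs / %d subjects; sigma2 subject %.4g, residual %.4g%s\n",
              object@nObs, object@nSubjects, object@sigma2Subject,
              object@sigma2Resid,
              if (object@converged) "" else " (NOT converged)"))
  df <- data.frame(term = object@terms, beta = object@beta, se = object@se,
                   p = object@p)
  print(utils::head(df, 12), row.names = FALSE)
})
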