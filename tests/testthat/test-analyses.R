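# Analysis families: trajectories, EDSS associations, stepwise selection.

test_that("phenotype-by-time contrasts detect the planted slope pattern", {
  sim <- midSim()
  gt <- sim$gt
  m <- latentMeasures(sim)
  rep_sp <- phenotypeTrajectories(m, sim$cohort, reference = "SP")
  res <- rep_sp@results

  # planted: every phenotype pair differs in slope by construction
  slope_rr <- res[res$family == "slope" & res$contrast == "RR" &
                    res$measure == "net01", ]
  truth <- gt@slopes["RR", 1] - gt@slopes["SP", 1]
  expect_lt(abs(slope_rr$beta - truth), 4 * slope_rr$se)
  expect_true(slope_rr$significant)

  # whole-brain GM is analysed alongside the networks
  expect_true("gm_total" %in% res$measure)
  expect_equal(sort(unique(res$contrast)), c("PP", "RR"))
})

test_that("switching the reference level is a pure reparameterization", {
  sim <- midSim()
  m <- latentMeasures(sim)
  rep_sp <- phenotypeTrajectories(m, sim$cohort, reference = "SP")
  rep_rr <- phenotypeTrajectories(m, sim$cohort, reference = "RR")
  a <- rep_sp@results
  b <- rep_rr@results
  for (fam in c("baseline", "slope")) {
    beta_rr_vs_sp <- a$beta[a$family == fam & a$contrast == "RR" &
                              a$measure == "net02"]
    beta_sp_vs_rr <- b$beta[b$family == fam & b$contrast == "SP" &
                              b$measure == "net02"]
    expect_equal(beta_rr_vs_sp, -beta_sp_vs_rr, tolerance = 1e-8)
  }
  expect_error(phenotypeTrajectories(m, sim$cohort, reference = "XX"),
               "absent")
})

test_that("per-group annual percentage change is reported for every measure", {
  sim <- midSim()
  m <- latentMeasures(sim)
  rep_sp <- phenotypeTrajectories(m, sim$cohort)
  apc <- rep_sp@apc
  expect_setequal(unique(apc$measure), c(colnames(m@loadings), "gm_total"))
  expect_setequal(unique(apc$group), c("RR", "SP", "PP"))
  # gm_total has a real baseline mean, so its APC is a true percentage
  expect_true(all(apc$is_percentage[apc$measure == "gm_total"]))
})

test_that("EDSS models flag clinical networks in both families", {
  sim <- midSim()   # clinical networks 1-3 of 4
  m <- latentMeasures(sim)
  er <- edssAssociation(m, sim$cohort)@results
  clin <- paste0("net0", 1:3)
  for (fam in c("baseline", "progression")) {
    fam_res <- er[er$family == fam, ]
    expect_true(all(fam_res$significant[fam_res$measure %in% clin]))
    expect_false(fam_res$significant[fam_res$measure == "net04"])
  }
})

test_that("EDSS associations are invariant to loading rescaling", {
  sim <- midSim()
  m <- latentMeasures(sim)
  m2 <- m
  m2@loadings[, 2] <- m2@loadings[, 2] * 2     # doubling is undone by z-scoring
  e1 <- edssAssociation(m, sim$cohort)@results
  e2 <- edssAssociation(m2, sim$cohort)@results
  expect_equal(e1$p, e2$p, tolerance = 1e-8)
  expect_equal(e1$beta, e2$beta, tolerance = 1e-8)
})

test_that("EDSS rows with missing scores are dropped per analysis", {
  sim <- midSim()
  p <- cohortPieces(sim$cohort)
  p$sampleData$edss[1:10] <- NA
  cohort <- MSCohort(p$volumes, p$sampleData)
  m <- latentMeasures(sim)
  m@sampleKeys <- sampleKeys(cohort)
  er <- edssAssociation(m, cohort)
  expect_s4_class(er, "AnalysisReport")
  p$sampleData$edss[] <- NA
  cohort2 <- MSCohort(p$volumes, p$sampleData)
  expect_error(edssAssociation(m, cohort2), "missing")
})

test_that("stepwise selection finds the real predictor among noise", {
  set.seed(71)
  hits <- 0L
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    n <- 2000
    dat <- as.data.frame(matrix(rnorm(n * 8), n, 8))
    colnames(dat) <- paste0("cand", 1:8)
    dat$age <- rnorm(n, 50, 8)
    dat$outcome <- 0.15 * dat$cand3 + 0.02 * dat$age + rnorm(n)
    sel <- stepwiseSelection(dat, "outcome", paste0("cand", 1:8), "age")
    if ("cand3" %in% sel$selected) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("stepwise keeps forced covariates and handles empty candidates", {
  set.seed(72)
  n <- 200
  dat <- data.frame(outcome = rnorm(n), age = rnorm(n, 50, 8),
                    cand1 = rnorm(n))
  sel <- stepwiseSelection(dat, "outcome", character(0), "age")
  expect_identical(sel$selected, character(0))
  expect_true("age" %in% attr(terms(sel$model), "term.labels"))

  sel2 <- stepwiseSelection(dat, "outcome", "cand1", "age")
  expect_true("age" %in% attr(terms(sel2$model), "term.labels"))
})

test_that("adjusted R^2 follows its formula", {
  # n = 20, p = 3, R^2 = 0.5 -> 1 - 0.5 * 19/16 = 0.40625
  set.seed(73)
  n <- 20
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rnorm(n)
  fit <- lm(y ~ X)
  r2 <- summary(fit)$r.squared
  expect_equal(summary(fit)$adj.r.squared,
               1 - (1 - r2) * (n - 1) / (n - 3 - 1), tolerance = 1e-12)
})

test_that("subject-level frames carry baselines, visit counts and outcomes", {
  sim <- midSim()
  m <- latentMeasures(sim)
  base <- subjectLevelData(m, sim$cohort, "edss_baseline")
  expect_equal(nrow(base), length(subjectIds(sim$cohort)))
  expect_true(all(base$n_visits == 4))
  sl <- subjectLevelData(m, sim$cohort, "edss_slope")
  expect_equal(nrow(sl), length(subjectIds(sim$cohort)))
  expect_true(is.numeric(sl$outcome))
})

test_that("downstream statistics ignore component relabeling", {
  sim <- midSim()
  m <- latentMeasures(sim)
  perm <- c(3, 1, 4, 2)
  m2 <- m
  m2@loadings <- m@loadings[, perm] * rep(c(-1, 1, -1, 1),
                                          each = nrow(m@loadings))
  colnames(m2@loadings) <- colnames(m@loadings)
  r1 <- treatmentModel(m, sim$cohort)$results
  r2 <- treatmentModel(m2, sim$cohort)$results
  # p-values map through the permutation; signs may flip, evidence does not
  expect_equal(r2$p[match(paste0("net0", 1:4), r2$measure)],
               r1$p[match(paste0("net0", perm), r1$measure)],
               tolerance = 1e-8)
})
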