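# Treatment effects, change-score effect sizes, sample size.

test_that("time-by-arm models flag exactly the treated networks", {
  # treatment effect planted on networks 1-3 of 4
  sim <- midSim()
  m <- latentMeasures(sim)
  tr <- treatmentModel(m, sim$cohort)
  res <- tr$results
  treated <- paste0("net0", 1:3)
  expect_true(all(res$significant[res$measure %in% treated]))
  expect_false(res$significant[res$measure == "net04"])
  # treated arm loses less volume: positive interaction after orientation
  expect_true(all(res$beta[res$measure %in% treated] > 0))
})

test_that("arm relabeling flips the interaction sign but not the evidence", {
  sim <- midSim()
  m <- latentMeasures(sim)
  p <- cohortPieces(sim$cohort)
  p$sampleData$arm <- ifelse(p$sampleData$arm == "treated", "comparator",
                             "treated")
  flipped <- MSCohort(p$volumes, p$sampleData)
  r1 <- treatmentModel(m, sim$cohort)$results
  r2 <- treatmentModel(m, flipped)$results
  expect_equal(r2$beta, -r1$beta, tolerance = 1e-8)
  expect_equal(r2$p, r1$p, tolerance = 1e-8)
})

test_that("single-arm cohorts are rejected", {
  gt <- makeGroundTruth(K = 2, R = 12, seed = 91)
  sim <- simulateCohort(gt, nPerPhenotype = c(RR = 10, SP = 0, PP = 0),
                        armSplit = NA, visits = 3, seed = 92)
  m <- latentMeasures(sim)
  expect_error(treatmentModel(m, sim$cohort), "single-arm")
  expect_error(firstLastEffectSize(m, sim$cohort), "single-arm")
})

test_that("change-score effect size follows its construction", {
  set.seed(93)
  n <- 2000
  mkMeasures <- function(delta_shift) {
    # two visits per subject; treated change shifted by delta_shift SDs
    sid <- sprintf("s%04d", seq_len(2 * n))
    arm <- rep(c("treated", "comparator"), each = n)
    base <- rnorm(2 * n)
    chg <- rnorm(2 * n)                      # change SD 1 by construction
    chg[arm == "treated"] <- chg[arm == "treated"] + delta_shift
    keys <- data.frame(subject_id = rep(sid, each = 2),
                       visit_index = rep(0:1, 2 * n),
                       stringsAsFactors = FALSE)
    L <- cbind(net01 = as.numeric(rbind(base, base + chg)))
    sd_df <- data.frame(
      subject_id = keys$subject_id, trial_id = "T", site_id = "s1",
      phenotype = "RR", arm = rep(arm, each = 2),
      visit_index = keys$visit_index, time_years = rep(0:1, 2 * n),
      age_baseline = 40, sex = "F", disease_duration = 5, tiv = 1.4e6,
      edss = 3, stringsAsFactors = FALSE)
    vol <- matrix(1000 + runif(4 * 2 * n * 2), 4, 2 * n * 2,
                  dimnames = list(sprintf("r%03d", 1:4), NULL))
    cohort <- MSCohort(vol, sd_df)
    meas <- new("NetworkMeasures", loadings = L,
                gmTotal = wholeBrainGM(cohort),
                sampleKeys = sampleKeys(cohort), zscored = FALSE,
                zCenter = numeric(0), zScale = numeric(0))
    list(m = meas, cohort = cohort)
  }
  null <- mkMeasures(0)
  d0 <- firstLastEffectSize(null$m, null$cohort)$effects
  expect_lt(abs(d0$cohens_d[d0$measure == "net01"]), 0.05)

  shifted <- mkMeasures(1)
  d1 <- firstLastEffectSize(shifted$m, shifted$cohort)$effects
  expect_lt(abs(d1$cohens_d[d1$measure == "net01"] - 1), 0.1)
})

test_that("covariate residualization of change scores is available", {
  sim <- midSim()
  m <- latentMeasures(sim)
  plain <- firstLastEffectSize(m, sim$cohort)$effects
  resid <- firstLastEffectSize(m, sim$cohort,
                               residualize = c("age_baseline", "sex"))$effects
  expect_true(all(is.finite(resid$cohens_d)))
  # arms are randomized within phenotype, so adjustment moves d only a little
  expect_lt(max(abs(resid$cohens_d - plain$cohens_d)), 0.25)
  expect_error(firstLastEffectSize(m, sim$cohort, residualize = "bogus"),
               "unknown residualization")
})

test_that("single-visit subjects are excluded with a count", {
  sim <- midSim()
  m <- latentMeasures(sim)
  keep <- !(sampleKeys(sim$cohort)$subject_id %in% subjectIds(sim$cohort)[1] &
              sampleKeys(sim$cohort)$visit_index > 0)
  cohort2 <- MSCohort(t(regionVolumes(sim$cohort))[, keep, drop = FALSE],
                      sampleData(sim$cohort)[keep, ])
  m2 <- new("NetworkMeasures", loadings = m@loadings[keep, , drop = FALSE],
            gmTotal = m@gmTotal[keep], sampleKeys = sampleKeys(cohort2),
            zscored = FALSE, zCenter = numeric(0), zScale = numeric(0))
  expect_message(out <- firstLastEffectSize(m2, cohort2), "1 subject")
  expect_equal(out$excluded, 1L)
})

test_that("degenerate change scores give an undefined-d error", {
  sim <- smallSim()
  m <- latentMeasures(sim)
  m@loadings[] <- 1                  # identical within and across arms
  m@gmTotal[] <- 1
  expect_error(firstLastEffectSize(m, sim$cohort), "pooled SD")
})

test_that("per-arm sample size matches the noncentral-t oracle", {
  # independent enumeration: smallest n whose noncentral-t power reaches
  # the target
  oracleN <- function(d, alpha = 0.05, power = 0.80) {
    for (n in 2:5000) {
      crit <- qt(1 - alpha / 2, df = 2 * n - 2)
      ncp <- d * sqrt(n / 2)
      pw <- 1 - pt(crit, df = 2 * n - 2, ncp = ncp) +
        pt(-crit, df = 2 * n - 2, ncp = ncp)
      if (pw >= power) return(n)
    }
    stop("no n found")
  }
  expect_equal(sampleSizePerArm(0.5), 64)
  expect_equal(oracleN(0.5), 64)
  expect_equal(sampleSizePerArm(1.0), 17)
  expect_equal(oracleN(1.0), 17)
  expect_equal(sampleSizePerArm(0.4), oracleN(0.4))
  expect_equal(sampleSizePerArm(0.1), oracleN(0.1))

  expect_gt(sampleSizePerArm(0.25), sampleSizePerArm(0.5))
  expect_equal(sampleSizePerArm(-0.5), sampleSizePerArm(0.5))
  expect_error(sampleSizePerArm(0), "infinite")
})

test_that("n per arm decreases in |d| across the treatment report", {
  sim <- midSim()
  m <- latentMeasures(sim)
  rep <- treatmentAnalysis(m, sim$cohort)
  res <- rep@results
  ok <- is.finite(res$n_per_arm)
  expect_true(all(res$n_per_arm[ok] >= 2))
  ord <- order(abs(res$cohens_d[ok]), decreasing = TRUE)
  expect_true(all(diff(res$n_per_arm[ok][ord]) >= 0))
})
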