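# Shared fixtures: small synthetic cohorts built in code, cached per session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# tiny cohort for I/O and validation tests: 3 networks over 20 regions
smallSim <- function() {
  fixture("smallSim", function() {
    gt <- makeGroundTruth(K = 3, R = 20, seed = 11)
    sim <- simulateCohort(gt, nPerPhenotype = c(RR = 12, SP = 10, PP = 8),
                          visits = 3, seed = 12)
    sim$gt <- gt
    sim
  })
}

# mid-size cohort for statistical machinery: 4 networks over 32 regions
midSim <- function() {
  fixture("midSim", function() {
    gt <- makeGroundTruth(K = 4, R = 32, seed = 21)
    sim <- simulateCohort(gt, nPerPhenotype = c(RR = 60, SP = 60, PP = 30),
                          visits = 4, seed = 22)
    sim$gt <- gt
    sim
  })
}

# latent loadings wrapped as NetworkMeasures, labels aligned with the
# planted networks (no ICA mixing); for analysis-module tests
latentMeasures <- function(sim) {
  L <- sim$loadings
  new("NetworkMeasures", loadings = L,
      gmTotal = wholeBrainGM(sim$cohort),
      sampleKeys = sampleKeys(sim$cohort), zscored = FALSE,
      zCenter = numeric(0), zScale = numeric(0))
}

# mutate one colData column of a cohort and return the raw pieces for
# revalidation via the constructor
cohortPieces <- function(cohort) {
  list(volumes = t(regionVolumes(cohort)),  # regions x observations
       sampleData = sampleData(cohort))
}

expect_validity_error <- function(volumes, sampleData, pattern) {
  expect_error(MSCohort(volumes, sampleData), pattern)
}

# brute-force assignment oracle for small matching problems
bruteForceMatch <- function(cc) {
  K <- nrow(cc)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- -Inf; best_p <- NULL
  for (p in perms(seq_len(K))) {
    s <- sum(abs(cc[cbind(seq_len(K), p)]))
    if (s > best) { best <- s; best_p <- p }
  }
  list(assignment = best_p, total = best)
}
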