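# FastICA network discovery: recovery, orientation, matching, invariants.

rlaplaceTest <- function(n, sd = 1) (rexp(n) - rexp(n)) * sd / sqrt(2)

test_that("noiseless planted networks are recovered near-perfectly", {
  set.seed(61)
  K <- 5; R <- 40; n <- 1500
  gt <- makeGroundTruth(K = K, R = R, seed = 61)
  S <- matrix(rlaplaceTest(n * K, sd = rep(gt@baselineScale, each = n)), n, K)
  X <- S %*% gt@maps
  fit <- fitICA(X, K = K, seed = 62)
  mm <- matchComponents(fit@maps, gt@maps)
  expect_equal(nrow(mm), K)
  expect_gt(min(mm$abs_r), 0.99)
  expect_true(fit@converged)
})

test_that("recovery degrades monotonically as noise grows", {
  set.seed(63)
  K <- 4; R <- 30; n <- 1200
  gt <- makeGroundTruth(K = K, R = R, seed = 63)
  S <- matrix(rlaplaceTest(n * K, sd = rep(gt@baselineScale, each = n)), n, K)
  signal <- S %*% gt@maps
  min_r <- vapply(c(0, 300, 3000), function(noise_sd) {
    X <- signal + matrix(rnorm(n * R, 0, noise_sd), n, R)
    # at the highest noise level the fixed point may not fully converge;
    # only the recovered maps matter here
    fit <- suppressWarnings(fitICA(X, K = K, seed = 64))
    min(matchComponents(fit@maps, gt@maps)$abs_r)
  }, numeric(1))
  expect_true(all(diff(min_r) <= 1e-6))
  expect_gt(min_r[1], 0.99)
})

test_that("rank-1 data with K = 1 reproduces the planted map up to scale", {
  set.seed(65)
  n <- 400; R <- 15
  map <- runif(R)
  s <- rlaplaceTest(n, 3)
  fit <- fitICA(s %*% t(map), K = 1, seed = 66)
  expect_gt(abs(cor(as.numeric(fit@maps), map)), 0.999999)
})

test_that("component-count preconditions are enforced", {
  set.seed(67)
  X <- matrix(rnorm(40 * 20), 40, 20)
  expect_error(fitICA(X, K = 30, seed = 1), "exceeds min")
  expect_error(fitICA(X, K = 21, seed = 1), "exceeds min")
})

test_that("whitened data has exactly identity covariance", {
  sim <- midSim()
  fit <- fitICA(sim$cohort, K = 4, seed = 71)
  X <- regionVolumes(sim$cohort) / sampleData(sim$cohort)$tiv * 1.45e6
  Z <- sweep(X, 2, fit@center) %*% t(fit@whitening)
  expect_equal(cov(Z), diag(4), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("reconstruction explains at least the top-K PCA variance", {
  sim <- midSim()
  fit <- fitICA(sim$cohort, K = 4, seed = 72)
  X <- regionVolumes(sim$cohort) / sampleData(sim$cohort)$tiv * 1.45e6
  Xc <- sweep(X, 2, fit@center)
  recon <- fit@loadings %*% fit@maps
  pca_var <- sum(svd(Xc, nu = 0, nv = 0)$d[1:4]^2)
  expect_gte(sum(recon^2), pca_var - 1e-6 * pca_var)
  # and the residual is orthogonal to the reconstruction
  expect_lt(abs(sum(recon * (Xc - recon))) / sum(recon^2), 1e-8)
})

test_that("sign orientation aligns loadings with whole-brain GM", {
  sim <- midSim()
  fit <- fitICA(sim$cohort, K = 4, seed = 73)
  gm <- wholeBrainGM(sim$cohort)
  for (k in 1:4) expect_gte(cor(fit@loadings[, k], gm), 0)

  # orientation leaves the reconstruction untouched
  set.seed(74)
  L <- matrix(rnorm(50 * 3), 50, 3)
  M <- matrix(rnorm(3 * 10), 3, 10)
  gm2 <- rnorm(50)
  ori <- orientSigns(L, M, gm2)
  expect_equal(ori$loadings %*% ori$maps, L %*% M, tolerance = 1e-12)

  # explicit flip cases
  o1 <- orientSigns(cbind(gm2), matrix(1, 1, 10), gm2)
  expect_equal(o1$flags, 1)
  o2 <- orientSigns(cbind(-gm2), matrix(1, 1, 10), gm2)
  expect_equal(o2$flags, -1)
  expect_gt(cor(o2$loadings[, 1], gm2), 0.999)
  expect_warning(orientSigns(cbind(rep(1, 50)), matrix(1, 1, 10), gm2),
                 "zero-variance")
})

test_that("matching is exact against a brute-force assignment oracle", {
  set.seed(75)
  for (K in c(3, 5)) {
    A <- matrix(rnorm(K * 25), K, 25)
    B <- matrix(rnorm(K * 25), K, 25)
    cc <- cor(t(A), t(B))
    mm <- matchComponents(A, B)
    oracle <- bruteForceMatch(cc)
    expect_equal(sum(mm$abs_r), oracle$total, tolerance = 1e-12)
  }
})

test_that("self-match and permuted/sign-flipped match are identities", {
  sim <- midSim()
  fit <- fitICA(sim$cohort, K = 4, seed = 76)
  self <- matchComponents(fit, fit)
  expect_equal(self$component_b[order(self$component_a)], 1:4)
  expect_equal(self$r, rep(1, 4), tolerance = 1e-12)

  perm <- c(3, 1, 4, 2); flips <- c(-1, 1, -1, 1)
  B <- fit@maps[perm, ] * flips
  mm <- matchComponents(fit@maps, B)
  mm <- mm[order(mm$component_a), ]
  expect_equal(order(perm), mm$component_b)
  expect_equal(abs(mm$r), rep(1, 4), tolerance = 1e-12)
  expect_true(all(mm$consistent))
})

test_that("split-cohort fits recover every planted network", {
  # two disjoint cohorts from one ground truth; K above K_true so the
  # planted networks and any residual nuisance directions all fit
  gt <- makeGroundTruth(K = 6, R = 48, seed = 81)
  c1 <- simulateCohort(gt, nPerPhenotype = c(RR = 90, SP = 90, PP = 45),
                       seed = 82)
  c2 <- simulateCohort(gt, nPerPhenotype = c(RR = 90, SP = 90, PP = 45),
                       seed = 83)
  f1 <- fitICA(c1$cohort, K = 8, seed = 84)
  f2 <- fitICA(c2$cohort, K = 8, seed = 85)
  for (f in list(f1, f2)) {
    vs_truth <- matchComponents(f@maps, gt@maps)
    expect_gte(min(vs_truth$abs_r), 0.8)
  }
  expect_error(matchComponents(f1@maps, gt@maps[, 1:30]), "region")
})

test_that("ICA is deterministic given the seed", {
  sim <- smallSim()
  f1 <- fitICA(sim$cohort, K = 3, seed = 90)
  f2 <- fitICA(sim$cohort, K = 3, seed = 90)
  expect_equal(f1@maps, f2@maps)
  expect_equal(f1@loadings, f2@loadings)
})
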