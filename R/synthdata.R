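# Synthetic longitudinal cohorts with planted network structure.

#' Create the planted ground truth for a synthetic cohort
#'
#' Draws K sparse non-negative spatial maps over R regions (rows sum to 1,
#' supports of 5--10 regions sharing < 50% pairwise), baseline mean regional
#' volumes, per-network Laplace baseline-loading scales (a mild geometric
#' variance taper across networks), network-specific phenotype baseline
#' profiles, phenotype-specific loading slopes, an additive treatment
#' effect on the slopes of a designated subset of networks, EDSS weights on
#' a designated clinical subset, and per-site multiplicative scanner gains
#' (region-specific by default), the location/scale structure ComBat's
#' model absorbs.
#'
#' @param K number of networks (>= 1)
#' @param R number of regions (>= 4 K)
#' @param nSites number of acquisition sites
#' @param seed integer seed; the construction is deterministic given it
#' @param supportRange min/max regions per network map
#' @param muRange range of baseline mean regional volumes (mm^3)
#' @param componentScale per-network SD of the network's volume signal
#'   along its unit map direction (mm^3), i.e. the planted component SD;
#'   the per-network loading SD is `componentScale / ||map_k||`.
#' @param baselineShift SD (in loading-SD units) of the network-specific
#'   per-phenotype baseline means: each network gets its own random
#'   phenotype profile, so baseline group differences exist without forcing
#'   a common cross-network pattern
#' @param slopeBase per-phenotype loading drift per year, in units of the
#'   network's baseline loading SD, multiplied by a per-network factor
#'   drawn in `[0.6, 1.4]`
#' @param treatNetworks indices of networks whose slope treatment changes
#' @param treatDelta additive slope change under treatment (loading SD per
#'   year; positive slows loss)
#' @param clinicalNetworks indices of networks driving EDSS
#' @param clinicalEffect EDSS SD contributed by each clinical network
#'   (negative: lower loading, i.e. less grey matter, means higher EDSS)
#' @param sigmaLoading visit-level loading noise SD, as a fraction of the
#'   network's baseline loading SD
#' @param sigmaRegion region-level volume noise SD (mm^3)
#' @param sigmaEdss EDSS noise SD
#' @param siteGainRange half-width of a per-site global scale factor
#'   around 1 (default 0: site effects are purely region-specific)
#' @param siteRegionJitter SD of the per-region, per-site gain
#' @param refTiv reference total intracranial volume (mm^3)
#' @param edssIntercept,edssAgeCoef EDSS generative intercept and per-year
#'   baseline-age effect
#' @param edssTimeAmp per-year growth of the EDSS sensitivity to the
#'   clinical networks, `w_k(t) = w_k (1 + edssTimeAmp * t)`: disability
#'   becomes increasingly driven by accumulated network damage, planting a
#'   loading-by-time progression association
#' @return a validated [GroundTruth-class]
#' @export
makeGroundTruth <- function(K = 8, R = 60, nSites = 3, seed = 1,
                            supportRange = c(5, 10),
                            muRange = c(5000, 11000),
                            componentScale = 450 * 0.95^(seq_len(K) - 1),
                            baselineShift = 0.15,
                            slopeBase = c(RR = -0.03, SP = -0.07, PP = -0.055),
                            treatNetworks = seq_len(min(3, K)),
                            treatDelta = 0.04,
                            clinicalNetworks = seq_len(min(3, K)),
                            clinicalEffect = -0.5,
                            sigmaLoading = 0.15, sigmaRegion = 30,
                            sigmaEdss = 0.6, edssTimeAmp = 0.25,
                            siteGainRange = 0, siteRegionJitter = 0.002,
                            refTiv = 1.45e6,
                            edssIntercept = 4.0, edssAgeCoef = 0.03) {
  K <- as.integer(K); R <- as.integer(R)
  if (K < 1) stop("K must be >= 1")
  if (R < 4 * K) stop("infeasible support constraints: need R >= 4*K")
  supportRange <- pmin(pmax(supportRange, 3), floor(R / 4))
  if (supportRange[1] > supportRange[2]) {
    stop("infeasible support constraints: empty support size range")
  }
  set.seed(seed)

  # sparse non-negative maps with limited pairwise support overlap
  supports <- vector("list", K)
  maps <- matrix(0, K, R)
  for (k in seq_len(K)) {
    ok <- FALSE
    for (attempt in seq_len(500)) {
      s <- if (supportRange[1] == supportRange[2]) supportRange[1] else
        sample(supportRange[1]:supportRange[2], 1)
      cand <- sort(sample.int(R, s))
      ok <- TRUE
      for (j in seq_len(k - 1)) {
        if (length(intersect(cand, supports[[j]])) >=
            0.5 * min(s, length(supports[[j]]))) { ok <- FALSE; break }
      }
      if (ok) { supports[[k]] <- cand; break }
    }
    if (!ok) stop("infeasible support constraints: could not place disjoint-enough maps")
    w <- stats::rgamma(length(supports[[k]]), shape = 2, rate = 1)
    maps[k, supports[[k]]] <- w / sum(w)
  }

  regionNames <- sprintf("r%03d", seq_len(R))
  muRegion <- stats::runif(R, muRange[1], muRange[2])

  # loading SD per network: prescribed component SD along the unit map
  # direction, so planted component variances follow the taper exactly
  baselineScale <- as.numeric(componentScale) / sqrt(rowSums(maps^2))

  phen <- .PHENOTYPES
  baselineMean <- matrix(stats::rnorm(3 * K, 0, baselineShift), 3, K) *
    matrix(baselineScale, 3, K, byrow = TRUE)
  dimnames(baselineMean) <- list(phen, NULL)
  slopeFactor <- stats::runif(K, 0.6, 1.4)
  slopes <- outer(unname(slopeBase[phen]), slopeFactor * baselineScale)
  dimnames(slopes) <- list(phen, NULL)

  td <- numeric(K)
  td[treatNetworks] <- treatDelta * baselineScale[treatNetworks]
  cw <- numeric(K)
  cw[clinicalNetworks] <- clinicalEffect / baselineScale[clinicalNetworks]

  g <- stats::runif(nSites, 1 - siteGainRange, 1 + siteGainRange)
  siteGain <- g * matrix(1 + stats::rnorm(nSites * R, 0, siteRegionJitter),
                         nSites, R)
  siteGain <- pmin(pmax(siteGain, 0.9), 1.1)
  rownames(siteGain) <- sprintf("site%02d", seq_len(nSites))

  obj <- methods::new("GroundTruth",
    K = K, R = R, regionNames = regionNames, maps = maps,
    muRegion = muRegion, baselineMean = baselineMean,
    baselineScale = as.numeric(baselineScale), slopes = slopes,
    treatDelta = td, clinicalWeights = cw,
    sigmaLoading = sigmaLoading, sigmaRegion = sigmaRegion,
    sigmaEdss = sigmaEdss, siteGain = siteGain, refTiv = refTiv,
    edssIntercept = edssIntercept, edssAgeCoef = edssAgeCoef,
    edssTimeAmp = edssTimeAmp, seed = as.integer(seed))
  methods::validObject(obj)
  obj
}

#' Simulate a longitudinal cohort from a ground truth
#'
#' Generative model per subject i, network k, visit time t:
#' \deqn{l_{ik}(t) = b_{ik} + (s_{p_i k} + \delta_k 1[\mathrm{treated}]) t + \epsilon}
#' with Laplace baselines \eqn{b_{ik}} (phenotype-specific means) and
#' Gaussian visit noise; regional volumes
#' \deqn{v_{ir}(t) = \frac{\mathrm{tiv}_i}{\mathrm{tiv}_{ref}}\, g_{s_i r}
#'   \left(\mu_r + \sum_k l_{ik}(t) m_{kr} + \eta\right)}
#' and EDSS as an affine function of the clinical-network loadings and
#' baseline age, plus noise, rounded to half points and clipped to [0, 10].
#' Non-positive volumes trigger a resample of the region noise up to
#' `retryCap` times, then an error.
#'
#' @param gt a [GroundTruth-class]
#' @param nPerPhenotype named vector of subjects per phenotype
#'   (names in RR/SP/PP)
#' @param armSplit fraction of each phenotype assigned to the treated arm;
#'   set `NA` to label every subject `none` (an observational cohort)
#' @param visits number of visits per subject
#' @param spacingYears years between consecutive visits
#' @param jitterSd SD of visit-time jitter (visits after baseline)
#' @param seed integer seed
#' @param trialId trial label stored in the cohort
#' @param tivCV coefficient of variation of total intracranial volume
#' @param retryCap resampling attempts for non-positive volumes
#' @return list with `cohort` (an [MSCohort-class]), `loadings` (the latent
#'   n_obs x K loading matrix, for tests), and `subjects` (subject-level
#'   data.frame)
#' @export
simulateCohort <- function(gt,
                           nPerPhenotype = c(RR = 240, SP = 240, PP = 120),
                           armSplit = 0.5, visits = 4, spacingYears = 1,
                           jitterSd = 0, seed = 1, trialId = "SYNTH",
                           tivCV = 0.05, retryCap = 10) {
  stopifnot(methods::is(gt, "GroundTruth"))
  methods::validObject(gt)
  if (visits < 1) stop("visits must be >= 1")
  set.seed(seed)

  phen_all <- rep(names(nPerPhenotype), times = nPerPhenotype)
  N <- length(phen_all)
  if (N < 1) stop("empty cohort requested")
  K <- gt@K; R <- gt@R

  # subject-level draws
  age_mean <- c(RR = 37.5, SP = 49.5, PP = 50.0)
  age_sd <- c(RR = 9, SP = 8.5, PP = 9)
  dd_mean <- c(RR = 4.9, SP = 13.5, PP = 4.0)
  dd_sd <- c(RR = 5.2, SP = 8.4, PP = 4.3)

  arm <- rep("none", N)
  if (!is.na(armSplit)) {
    for (p in unique(phen_all)) {
      idx <- which(phen_all == p)
      tr <- sample(idx, round(armSplit * length(idx)))
      arm[tr] <- "treated"
      arm[setdiff(idx, tr)] <- "comparator"
    }
  }
  sex <- ifelse(stats::runif(N) < 0.35, "M", "F")
  age <- pmin(pmax(stats::rnorm(N, age_mean[phen_all], age_sd[phen_all]), 18), 75)
  dd <- pmax(stats::rnorm(N, dd_mean[phen_all], dd_sd[phen_all]), 0.2)
  tiv <- gt@refTiv * exp(stats::rnorm(N, 0, tivCV)) *
    ifelse(sex == "M", 1.06, 0.95)
  site <- sample(rownames(gt@siteGain), N, replace = TRUE)
  sid <- sprintf("%s_S%05d", trialId, seq_len(N))

  # baseline loadings (Laplace) and visit times
  B <- gt@baselineMean[phen_all, , drop = FALSE] +
    t(matrix(rlaplaceSd(N * K, 0, rep(gt@baselineScale, N)), K, N))  # N x K
  times <- matrix(rep((seq_len(visits) - 1) * spacingYears, each = N), N, visits)
  if (jitterSd > 0 && visits > 1) {
    times[, -1] <- times[, -1] +
      matrix(stats::rnorm(N * (visits - 1), 0, jitterSd), N, visits - 1)
    times <- t(apply(times, 1, function(tt) {
      tt[-1] <- pmax(tt[-1], seq_len(visits - 1) * spacingYears * 0.25)
      cummax(tt) + c(0, cumsum(rep(1e-6, visits - 1)))
    }))
    times[, 1] <- 0
  }

  # observation-level latent loadings
  slope_subj <- gt@slopes[phen_all, , drop = FALSE] +
    outer(as.numeric(arm == "treated"), gt@treatDelta)   # N x K
  obs_subj <- rep(seq_len(N), each = visits)
  obs_time <- as.vector(t(times))
  visit_noise_sd <- rep(gt@sigmaLoading * gt@baselineScale,
                        each = N * visits)
  L <- B[obs_subj, , drop = FALSE] +
    slope_subj[obs_subj, , drop = FALSE] * obs_time +
    matrix(stats::rnorm(N * visits * K, 0, visit_noise_sd), N * visits, K)

  # regional volumes
  n_obs <- N * visits
  signal <- matrix(gt@muRegion, n_obs, R, byrow = TRUE) + L %*% gt@maps
  eta <- matrix(stats::rnorm(n_obs * R, 0, gt@sigmaRegion), n_obs, R)
  raw <- signal + eta
  for (attempt in seq_len(retryCap)) {
    bad <- which(apply(raw <= 0, 1, any))
    if (length(bad) == 0) break
    raw[bad, ] <- signal[bad, , drop = FALSE] +
      matrix(stats::rnorm(length(bad) * R, 0, gt@sigmaRegion), length(bad), R)
  }
  if (any(raw <= 0)) {
    stop("non-positive volumes persisted after resampling; lower sigmaRegion")
  }
  vol <- raw * gt@siteGain[site[obs_subj], , drop = FALSE] *
    (tiv[obs_subj] / gt@refTiv)

  # EDSS from clinical networks, with time-growing sensitivity
  edss_lin <- gt@edssIntercept +
    as.vector(L %*% gt@clinicalWeights) * (1 + gt@edssTimeAmp * obs_time) +
    gt@edssAgeCoef * (age[obs_subj] - 40) +
    stats::rnorm(n_obs, 0, gt@sigmaEdss)
  edss <- pmin(pmax(round(edss_lin * 2) / 2, 0), 10)

  sampleData <- data.frame(
    subject_id = sid[obs_subj], trial_id = trialId,
    site_id = site[obs_subj], phenotype = phen_all[obs_subj],
    arm = arm[obs_subj], visit_index = rep(seq_len(visits) - 1L, times = N),
    time_years = obs_time, age_baseline = age[obs_subj], sex = sex[obs_subj],
    disease_duration = dd[obs_subj], tiv = tiv[obs_subj], edss = edss,
    stringsAsFactors = FALSE
  )
  vol_t <- t(vol)
  rownames(vol_t) <- gt@regionNames
  cohort <- MSCohort(vol_t, sampleData)
  # MSCohort sorts by (subject, visit); generation order already matches
  colnames(L) <- sprintf("net%02d", seq_len(K))
  list(cohort = cohort, loadings = L, subjects = data.frame(
    subject_id = sid, phenotype = phen_all, arm = arm, sex = sex,
    age_baseline = age, disease_duration = dd, tiv = tiv, site_id = site,
    stringsAsFactors = FALSE))
}

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d networks over %d regions, %d sites (seed %d)\n",
              object@K, object@R, nrow(object@siteGain), object@seed))
  cat(sprintf("  support sizes: %s; clinical networks: %s; treated networks: %s\n",
              paste(rowSums(object@maps > 0), collapse = ","),
              paste(which(object@clinicalWeights != 0), collapse = ","),
              paste(which(object@treatDelta != 0), collapse = ",")))
})
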