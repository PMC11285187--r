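---
title: "Longitudinal grey-matter network measures: models and methods"
author: "gmnets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal grey-matter network measures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Brain atrophy in multiple sclerosis is usually tracked with whole-brain or
whole grey-matter (GM) volumes, but neurodegeneration is regionally
heterogeneous and differs between the relapsing--remitting (RR), secondary
progressive (SP) and primary progressive (PP) phenotypes. Networks of
co-varying regional GM volumes — structural covariance networks — capture
that regional structure: a data-driven decomposition of the subject-visit
by region volume matrix yields spatial maps (which regions co-vary) and,
per subject and visit, a scalar loading expressing how strongly that
pattern is present. Lower loading, after sign orientation, means less grey
matter in the network.

Independent component analysis can only be estimated on a whole cohort at
once; adding a participant or visit requires refitting everything, which
rules out prospective use, for example interim analyses in a trial. The
pipeline implemented here therefore has two halves:

1. **Discovery** (training cohort): spatial ICA on regional GM volumes
   yields K networks and their loadings.
2. **Prospective scoring** (any cohort): one sparse (Lasso) linear model
   per network, trained to map the same regional volumes to the ICA
   loading, is frozen and applied to unseen participants and visits with
   no re-estimation.

Downstream, network measures and whole-brain GM are harmonized across
scanners/sites (ComBat) and fed into linear mixed models: phenotype
trajectory contrasts, disability (EDSS) associations, stepwise predictor
selection, treatment-effect detection and per-arm sample-size estimates.

## Data model

`MSCohort` wraps a `SummarizedExperiment`: one `volumes` assay (regions x
subject-visits, mm^3) and per-visit covariates (subject, trial, site,
phenotype, arm, visit index, time in years from baseline, baseline age,
sex, disease duration, total intracranial volume, EDSS). Validity enforces
the longitudinal invariants: one baseline row per subject, strictly
increasing visit times, constant subject-level covariates, non-negative
volumes, EDSS on the half-point grid in [0, 10] (missing allowed; rows are
dropped per analysis, never imputed).

## Spatial ICA

`fitICA()` is FastICA with the logcosh contrast (a = 1), PCA whitening to
K components and symmetric (parallel) fixed-point updates, tolerance 1e-4,
at most 200 iterations — conventional FastICA settings. Observations
(subject-visits) are the samples: sources are per-observation loadings and
the spatial maps are the mixing rows, so a fit directly yields a network
measure per participant and time point. Whitening uses the n-1 divisor so
the whitened covariance is exactly the identity; the K-component
reconstruction equals the top-K principal subspace by construction.

**Feature normalization.** By default the features entering ICA (and the
surrogate) are TIV-normalized volumes — each observation's regional
volumes divided by its total intracranial volume, the standard
proportional head-size correction in morphometry. The reason is
structural: head size multiplies every region, so raw volumes contain a
single global-scale direction whose variance dwarfs any covariance
network (at a realistic TIV coefficient of variation of ~5% it is roughly
40x the strongest network in our simulations). ICA then spends one of its
K components on head size, and K components cannot resolve K networks.
Dividing by TIV removes that direction exactly, and — unlike dividing by
the row total (regional fractions) — the denominator is exogenous to the
GM signal, so it does not couple the network sources. TIV additionally
remains a fixed-effect covariate in every statistical model, which is
where between-head-size confounding belongs. Raw-volume ICA remains
available (`normalize = "none"`), as does the fraction variant.

**Sign orientation.** ICA signs are arbitrary; `orientSigns()` correlates
each loading with whole-brain GM (the regional sum) and negates
loading/map pairs with negative correlation, so a lower loading always
reads as lower GM volume. The reconstruction is unchanged.

**Component matching.** `matchComponents()` computes all pairwise Pearson
correlations between two sets of spatial maps over the shared region
vector and returns the one-to-one assignment maximizing the summed |r|
(Hungarian algorithm — exact, rather than greedy, because near-ties
between similar components otherwise make the matching order-dependent).
Pairs with |r| >= 0.8 are flagged consistent, the conventional
split-cohort stability bar.

## Lasso surrogate

`trainSurrogate()` fits one Lasso per network with the regional features
as inputs and the ICA loading as target, minimizing
(1/2n)||y - b0 - Xb||^2 + lambda ||b||_1. The cohort is split 70/30 **by
subject** (all visits of a subject on one side — a row-level split would
leak within-person correlation into the validation); the penalty is chosen
per network by 5-fold subject-grouped cross-validation over a log grid
from lambda_max (the smallest all-zero penalty) down four decades.
Standardization parameters (per-region mean/SD, 1/n convention) are frozen
from the training split and serialized with the coefficients; prospective
application is a pure affine map.

Fidelity is reported as ICC(2,1) — two-way random effects, absolute
agreement, Shrout–Fleiss — between ICA loadings and surrogate predictions
on the held-out subjects. Because ICA loadings are themselves affine in
the features, a well-chosen penalty attains ICC near 1; the validation bar
used throughout is ICC >= 0.99 for every network.

## ComBat harmonization

`combatFitTransform()` implements parametric empirical-Bayes
location/scale harmonization: per feature, standardize residuals about the
covariate fit; estimate per-batch location (gamma) and scale (delta);
shrink them towards normal / inverse-gamma priors by iterated conditional
posterior means (tolerance 1e-6, cap 500 — tighter than the reference
implementation's 1e-4, at negligible cost); adjust and restore the
covariate structure. Protected biological covariates (defaults: baseline
age, sex, time) are estimated jointly with batch and preserved. A single
batch is an exact no-op by construction. The fit (EB posteriors and
priors) is serializable, so the same adjustment is inspectable and
reproducible. Harmonization is applied to the network measures and
whole-brain GM — after surrogate scoring, before statistics — not to raw
regional volumes.

## Mixed models and derived summaries

All longitudinal models are linear mixed models with a random subject
intercept plus residual, fitted by REML. The design has one row per
visit, so "visit nested within subject" is statistically exactly this
structure — a visit-level random effect would be confounded with the
residual. Inference is Wald z (CI = beta +/- 1.96 SE); with hundreds of
subjects the normal approximation is adequate, and it is documented as a
limitation for very small cohorts. Analysis families:

- **Phenotype trajectories**: measure ~ phenotype x time + baseline age +
  sex + disease duration + TIV + arm; baseline contrasts are the
  phenotype main effects, slope contrasts the interactions; the reference
  level is switchable (SP by default) and switching is a pure
  reparameterization.
- **EDSS associations**: EDSS ~ z-scored loading x time + the same
  covariates, complete EDSS cases; loading main effect = baseline
  association, loading x time = progression association.
- **Stepwise selection**: bidirectional AIC stepwise from the full model
  with covariates forced (lower scope), for baseline EDSS or the
  per-subject OLS slope of EDSS on time; reports retained candidates and
  adjusted R^2.
- **Treatment effects**: measure ~ time x arm + baseline age + sex + TIV;
  the interaction is the treatment test.

Benjamini–Hochberg FDR is applied across the K measures (+ whole-brain
GM) within one contrast within one analysis — that is the natural family:
the K networks answer the same question in parallel.

**Annual percentage change** is 100 x slope / |group baseline mean|.
ICA-scale loadings are near zero-mean, so a percentage of the baseline
mean can be numerically meaningless; when the baseline mean is within
1e-6 SD of zero the absolute slope is returned with a flag instead.
Whole-brain GM, with its large positive mean, always yields a true
percentage.

**Effect size and sample size.** Per subject, the change between first
and last available visits (single-visit subjects excluded, counted);
Cohen's d = arm difference of mean change / pooled change SD. The per-arm
sample size is the smallest integer n at which the two-sided two-sample
t-test with noncentrality d sqrt(n/2) and df 2n-2 reaches the target
power (alpha = 0.05, power = 0.80 by default), computed by the
noncentral-t method of `power.t.test`, ceiling applied.

## The synthetic generator

`makeGroundTruth()` / `simulateCohort()` plant everything the pipeline is
supposed to find, so every stage can be validated against ground truth:

- K sparse non-negative spatial maps (rows sum to 1; supports of 5–10
  regions sharing < 50% pairwise).
- Per-subject baseline loadings are **Laplace** — leptokurtic sources are
  what makes the networks identifiable by ICA; Gaussian ones would not
  be. Planted component SDs follow a mild geometric taper
  (450 x 0.95^(k-1) mm^3 along the unit map direction).
- Phenotype structure: each network has its own random phenotype baseline
  profile (SD 0.15 loading-SD). A shared cross-network phenotype pattern
  would correlate the sources and genuinely degrade ICA separability — we
  observed exactly that before making profiles network-specific — and
  network-specific phenotype effects are also what the motivating
  clinical results show.
- Trajectories: phenotype-specific slopes (RR -0.03, SP -0.07, PP -0.055
  loading-SD/year, times a per-network factor in [0.6, 1.4]); treatment
  adds +0.04 SD/year on a designated subset (networks 1–3), i.e. roughly
  halves SP-range loss. Slopes are expressed per loading SD so that
  detectability does not depend arbitrarily on map norms; visit-level
  loading noise is 0.15 SD, which puts first-to-last change effect sizes
  near d ~ 0.5.
- EDSS: affine in the clinical-network loadings (networks 1–3, each
  contributing 0.5 EDSS SD) and baseline age, with sensitivity growing at
  25%/year, then noise (SD 0.6), rounding to half points, clipping to
  [0, 10]. The sensitivity growth plants a genuine loading x time
  progression association — with purely contemporaneous dependence the
  interaction term is structurally zero, which no test could then detect.
- Nuisance: multiplicative per-region site gains (SD 0.2%, three sites),
  TIV lognormal (CV 5%) with a sex effect, volumes scaled by TIV/reference.

Default cohort sizes mirror a mid-sized trial pool: 600 subjects (240 RR
/ 240 SP / 120 PP, each phenotype split 50/50 treated/comparator), four
annual visits, 60 regions, 8 networks.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: registration/segmentation error structure,
lesion effects on segmentation, dropout and informative missingness,
visit-schedule irregularity beyond optional jitter, scanner upgrades
mid-trial, floor/ceiling dynamics of EDSS beyond rounding/clipping, and
site effects as severe as real multi-vendor pools. Results on it validate
the estimators and their calibration, not clinical effect sizes.

## Numerical choices and degenerate inputs

- Whitening divisor n-1 (so `cov(Z)` is exactly I); data below rank K is
  an error rather than a silent degenerate fit.
- FastICA non-convergence returns `converged = FALSE` with a warning
  rather than failing, matching common practice.
- Zero-variance loadings make sign orientation undefined: flag left at
  +1, warning.
- Lasso: zero-variance predictors dropped with a warning; single-predictor
  problems solved by the exact soft threshold; an all-zero fitted
  surrogate (penalty grid too coarse/large) is a flagged error because
  ICC against a constant is undefined.
- ICC requires n >= 3 pairs and non-zero total variance.
- ComBat requires >= 2 observations per batch and a batch/covariate
  design of full rank; one batch returns the input exactly.
- Sample size is undefined at d = 0 (error), >= 2 otherwise.
- CSV writers render doubles with 17 significant digits so read(write(x))
  is value-exact.

## Validation problem sizes

The shipped validation suite runs ICA fidelity and stability at the
default study conditions (600-subject cohort for surrogate fidelity; two
disjoint 400-subject cohorts for stability), 10,000 simulated trials for
sample-size self-consistency, 500-replicate Monte Carlo for CI coverage
and for the type-I error of the phenotype x time and time x arm tests
(both held within (0.03, 0.07) at nominal 0.05), and small closed-form
oracles (balanced-ANOVA REML, BH step-up, univariate soft threshold,
noncentral-t sample sizes) checked exactly. These sizes were chosen so the
whole suite stays desk-scale on a single CPU while keeping Monte-Carlo
standard errors well inside the asserted bands.

## Known limitations

- Wald z rather than Satterthwaite degrees of freedom; anticonservative
  for very small numbers of subjects.
- The surrogate is a linear scoring rule; it reproduces ICA loadings, not
  a better measure — garbage networks in, garbage measures out.
- ComBat is the parametric variant; no longitudinal ComBat.
- The EDSS change outcome for stepwise selection is the per-subject OLS
  slope, which ignores EDSS's ordinal nature.
- Component matching assumes the two decompositions share the region set
  and order; there is no partial-region matching.
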