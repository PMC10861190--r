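---
title: "Models and design choices in ProteoBoneAge"
author: "ProteoBoneAge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in ProteoBoneAge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ProteoBoneAge implements the analysis chain of a longitudinal
serum-proteomics study of bone aging: from raw person-visit protein
abundances and dual-energy X-ray absorptiometry (DXA) bone mineral density
(BMD) through protein selection, association, risk scores, trajectory
classes, survival models, a proteomic biological age, and two-sample
Mendelian randomization (MR). This vignette explains each model, the
parameters that matter, and the choices we made where the design was
genuinely open. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The synthetic cohort and what it emulates

Real cohorts of this design are not freely redistributable, so the package
ships a generator (`simulateCohort()`) whose defaults reproduce the scale
of a three-visit, middle-aged East Asian cohort: 3415 participants split
into discovery and validation batches at a 1785:1630 ratio, 413 proteins,
72% women, baseline age 57.5 (SD 5.1) years, visits 3.3 years apart. The
desk-scale default used throughout the tests and the acceptance script is
800 participants and 60 proteins, chosen so the full pipeline completes in
about a minute on one CPU while every stage still has adequate events and
power.

The latent structure, frozen once and used by every downstream check:

* **BMD.** On a population-SD scale, baseline BMD combines a
  cross-sectional age gradient (−0.25 SD per SD of age), a male offset
  (+0.35 SD), weak BMI and physical-activity confounding, a person-level
  random intercept, and the causal protein block. Decline is linear in
  time with a person-specific slope: mean −0.05 SD/year for women and
  −0.02 for men (about 1%/year postmenopausal loss, matching DXA
  literature), SD 0.015, plus the aging coupling below. The SD scale is
  mapped to g/cm² through T-scores (population T means −1.05 at the lumbar
  spine, −0.85 at the femoral neck; young-adult references 1.047 ± 0.110
  and 0.858 ± 0.120 g/cm²), so osteoporosis status, events and hazards all
  derive from the same latent process rather than an independent event
  model.
* **Causal proteins.** Eight proteins (default) shift BMD level by exactly
  ±0.3 population-SD per SD of their baseline abundance. The exposure is
  defined as the sample-standardized baseline abundance, so ordinary
  least squares on the generating scale recovers the effect without
  attenuation — this is what the calibration tests exploit.
* **Bone aging.** Each participant carries a true age acceleration
  Δ ~ N(0, 5²) years. Twelve proteins (default) follow
  `x_j = q_j + k_j·(CA + Δ) + e`, calibrated to an age correlation of
  about 0.3 each. Δ also steepens BMD decline by −0.05 SD/year per SD of
  Δ — a deliberately strong coupling, chosen a priori so that the
  acceleration→osteoporosis hazard is detectable at desk scale; real
  panels will usually show much weaker signals.
* **Missingness.** Left-censoring removes exactly the lowest 10% of each
  protein's values (rank-based), emulating below-detection-limit dropout.
  The abundance scale (means 4–7, SDs ≈ 1 arbitrary units) was chosen so
  the half-minimum substitute lands just below the censoring window, as it
  does for real intensity data, rather than as an extreme outlier.
* **Covariates** mirror the usual epidemiological panel (anthropometry,
  blood pressure, lipids, glucose, urate, diet, lifestyle, supplements)
  as weakly correlated Gaussians and Bernoullis, with configurable weak
  confounding of the non-causal proteins by BMI and age.

What the generator does **not** emulate: protein–protein correlation blocks
(independent by default; a real serum proteome is strongly structured),
non-linear BMD trajectories, informative dropout, batch effects beyond an
optional mean shift, and measurement-batch drift within visits. Passing
tests therefore demonstrate that the estimators recover the stated
generating processes — not that they are robust to everything real data
does.

## Preprocessing

Missing abundances are imputed with half of the per-protein minimum over
all analysed samples (visits pooled). Note a known consequence that the
tests make visible: substituting a point mass below the censoring window
inflates the protein's variance and biases standardized association
estimates toward the null by roughly 10–25% at the default censoring rate.
This is a property of the method itself, so parameter-recovery tests are
run at zero censoring, while the end-to-end checks run with censoring on
and absorb the attenuation.

Standardization uses the sample SD (n − 1) and is fitted on the baseline
rows of each batch separately, then applied to that batch's follow-ups —
this prevents leakage across the discovery/validation split consumed by
the selection stage. T-score classification uses half-open intervals
(osteoporosis T < −2.5; osteopenia −2.5 ≤ T < −1; normal T ≥ −1) so the
partition is total; a treated-flag override can force osteoporosis.
Fold changes, `(mean_case − mean_control)/mean_control`, are computed on
imputed but unstandardized abundances (a standardized control mean is
near 0, leaving the ratio undefined), tested with Welch's t by default
(Wilcoxon available) and controlled by Benjamini–Hochberg within each
visit's protein family.

## Selection, association, meta-analysis

Gradient-boosted trees (binary logistic objective, single-threaded for
determinism) with TreeSHAP attributions select proteins whose mean |SHAP|
over the training rows exceeds 1e−12 — a numerical-tolerance reading of
"greater than zero", since exact zero tests are fragile in floating point.
The 70/30 discovery split reproduces the canonical 1222/524 partition at
n = 1746. L1-penalized logistic regression with 10-fold cross-validated
deviance is the second selector. Labels are ever-osteoporosis at the site
during follow-up, one row per participant, baseline abundances as
features. Hyperparameters (150 trees, depth 3, learning rate 0.05) are
defaults recorded in the run manifest; the underlying study reports none.

The association model is a random-intercept linear mixed model per batch
(REML via lme4), exposure = baseline protein z-score, outcome = the
standardized follow-up BMD visits, fully covariate-adjusted. Estimates are
pooled by DerSimonian–Laird; the significance flag is `p < 0.05` and
`I² < 30%` with BH q-values reported alongside (the flag follows the raw-p
convention; both are emitted so either can be consumed downstream).

## Risk score, trajectories, survival

The protein risk score is the meta-beta-weighted sum of flagged protein
z-scores, sign-flipped so that a positive score is deleterious (hazard
ratios above 1 are the expected direction). The exact construction used in
the original appendix is not public; this weighted-sum convention is the
standard one and is declared rather than inferred. Quartiles cut at the
25/50/75 sample percentiles with values at a cutpoint falling to the lower
quartile; an all-ties vector degenerates to Q1 with a flag.

Trajectory classes come from an EM-fitted mixture of linear growth curves
with a shared residual SD — linear because three visits support no more,
and shared σ as the minimal model. Responsibilities are initialized from
k-means on per-person OLS (intercept, slope) with random restarts; the
log-likelihood is asserted non-decreasing every iteration; labels are
canonicalized by ascending intercept. K = 1..5 is compared by BIC
(−2ℓ + params·log N) among fits whose minimum per-class average posterior
probability of assignment is at least 0.7 (the threshold is ours; the
criterion itself is standard), ties breaking toward fewer classes. On
cohorts whose person-level heterogeneity is continuous, the mixture
discretizes that continuum and BIC tends to the upper bound of K — the
familiar "sustained low/medium/high" reading of such classes, visible in
the pipeline output.

Survival records are interval-observed at visits: the event time is the
first visit classified osteoporosis, censoring at the last attended visit,
prevalent baseline cases excluded. Cox models use Efron ties (visit-grouped
event times are heavily tied) and Wald inference. Dose–response uses a
restricted cubic spline with Harrell's quantile knots (4 knots at the
0.05/0.35/0.65/0.95 percentiles; basis scaled by the squared boundary-knot
span), and the trend test enters the quartile rank as a single ordinal
covariate. Covariate tiers mirror the usual build-up: model 1 age + sex,
model 2 adds anthropometry/lifestyle/diet/supplements, model 3 adds blood
pressure and clinical biochemistry.

## Klemera–Doubal biological age

Candidate proteins need |r| ≥ 0.1 with chronological age at BH q < 0.05;
redundancy is removed greedily, dropping the weaker of any pair with
|pairwise r| > 0.7. Per protein, OLS on CA yields (q, k, s, r); the
uncorrected estimate is the precision-weighted aggregate
`BA_E = Σ(x_j−q_j)k_j/s_j² / Σk_j²/s_j²`, and the corrected estimate blends
in CA with weight `1/s_BA²`, where
`s_BA² = Var(BA_E − CA) − ((1−r_char²)/r_char²)(CA_max−CA_min)²/(12m)`.
Open points we resolved and flag as conventions: `r_char` is the
(k²/s²)-weighted mean of |r_j| (the original estimator has variants and the
source appendix is unavailable); when the correction term makes `s_BA²`
non-positive — common for weakly age-correlated panels — we fall back to
`Var(BA_E − CA)`, with a final floor of 1e−4 years² for noise-free
degenerate panels; residual SDs are floored at 1e−6 to keep weights finite.
Age acceleration is the OLS residual of the corrected age on CA (mean zero
by construction), standardized before entering Cox models.

## Mendelian randomization

Instruments require exposure `p ≤ 5×10⁻⁸` (boundary included).
Harmonization aligns outcome effects to the exposure effect allele,
dropping incompatible pairs and strand-ambiguous palindromic SNPs with
allele frequency in (0.42, 0.58) — a conventional window, configurable —
and using frequency concordance to orient unambiguous palindromes.
Estimators: Wald ratio (single SNP); IVW as the origin-constrained
weighted regression with multiplicative overdispersion inflation when the
residual dispersion exceeds 1; MR-Egger with the same inflation floored at
1; weighted median with inverse-variance ratio weights, interpolated at
cumulative weight 0.5, bootstrap SE (1000 seeded replicates); and simple/
weighted modes as the argmax of a Gaussian-kernel ratio density with the
modified Silverman bandwidth. The robustness demonstration plants
directional pleiotropy in half the SNPs while making those instruments
weaker, so valid instruments keep the weight majority — the regime in
which the weighted median is consistent and IVW is not. LD clumping is out
of scope: instrument sets are assumed independent.

## Numerical choices and degenerate inputs

EM converges on Δℓ < 1e−8 (500 iterations cap, 20 restarts by default;
the repeated-selection tests use fewer restarts since k-means
initialization already finds well-separated optima). Mixed models that
lose their variance-covariance matrix on exactly collinear, noise-free
data fall back to the fixed-effects OLS standard error. Cox fits with
|coefficient| > 15 are treated as monotone-likelihood failures. Constant
features, zero-variance columns, fully missing proteins, empty quartiles,
single-class labels and zero-slope age proteins all raise errors naming
the offending column. Continuous covariates are internally standardized
before model fitting (this changes no exposure coefficient but keeps
optimizers well-conditioned).

## Problem sizes

The test suite and acceptance script run the full pipeline at 800
participants × 60 proteins, parameter recovery at n = 1000–2000,
trajectory selection over 50 replicates of 150 participants, KDM
calibration over 100 replicates of n = 1000, and null calibrations at
100–1000 replicates — sizes at which every stated property is identifiable
yet the whole suite completes in a few minutes.

## Known limitations

Half-minimum imputation attenuates associations (see above); the PRS
weights reuse in-sample meta betas (no shrinkage, by design of the method
being implemented); the trajectory model has no covariate-dependent
membership; survival handles neither competing risks nor true interval
censoring (visit dates are taken as event times); and the MR module
implements no Steiger filtering or multivariable extensions.
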