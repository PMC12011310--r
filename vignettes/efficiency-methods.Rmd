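---
title: "Separated versus combined mixed models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separated versus combined mixed models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlmmeff)
```

## The model and the question

Multiple longitudinal biomarkers of one disease process are usually
correlated: subjects who decline faster on one measure tend to decline on
the others, and errors of measures recorded on the same day may share
noise. The multivariate linear mixed model (MLMM) stacks the K per-measure
models,

$$Y_i = X_i\beta + Z_i b_i + e_i,\qquad
b_i \sim N(0, D),\quad e_i \sim N(0, \Sigma_i),$$

with $X_i = \bigoplus_k X_{ik}$ and $Z_i = \bigoplus_k Z_{ik}$ block
diagonal, observations ordered measure-major and time-ascending. $D$ is
blocked by measure; $\Sigma_i$ expands a K×K per-observation residual
covariance $R$: within a measure errors are independent with variance
$R_{kk}$, and across measures two errors covary (by $R_{kk'}$) only when
the observations are simultaneous (tie tolerance $10^{-9}$). Fitting K
univariate LMMs is equivalent to working under the *separated* components —
$D$ and $R$ with every cross-measure entry set to zero — while the
*combined* model keeps them free.

The question the package answers is not "which model fits better" but
"how much precision do the separated fits give up, assuming the combined
model is true". Both working models yield linear estimators, so their
exact mean squared errors under the true model are computable without any
simulation:

* **Fixed effects.** Each working model gives a GLS estimator
  $\hat\beta_w = (\sum_i X_i' W_{wi} X_i)^{-1}\sum_i X_i'W_{wi}Y_i$ with
  $W_{wi} = V_{wi}^{-1}$. Both are unbiased, so the MSE is pure variance:
  $\mathrm{tr}\sum_i A_{wi} V_i A_{wi}'$ evaluated at the true $V_i$.
* **Random effects.** With $\beta$ known,
  $\hat b_{wi} = L_{wi}(Y_i - X_i\beta)$ with
  $L_{wi} = D_w Z_i' W_{wi}$, and the error splits as
  $(L_{wi}Z_i - I)b_i + L_{wi}e_i$ with $b_i \perp e_i$. Averaging the
  conditional bias over $b_i \sim N(0,D)$ gives
  squared bias $\mathrm{tr}[(L_{wi}Z_i-I)D(L_{wi}Z_i-I)']$ and variance
  $\mathrm{tr}[L_{wi}\Sigma_i L_{wi}']$. With $\beta$ estimated, the extra
  term $-L_{wi}X_i(\hat\beta_w-\beta)$ couples all subjects through
  $\hat\beta_w-\beta=\sum_j A_{wj}(Z_jb_j+e_j)$; the implementation
  accumulates the exact trace forms over subjects (cost linear in m after
  pooling the two p×p cross-subject kernels).
* **Predictions.** The estimand is the conditional mean trajectory
  $X_i\beta + Z_ib_i$; the error is
  $X_i(\hat\beta_w-\beta) + Z_i(\hat b_{wi}-b_i)$ and the same machinery
  applies, with coordinates aggregated per measure.

Efficiency is reported as the MSE ratio of the combined to the separated
estimator. Because the combined working model coincides with the
evaluation model, its linear predictor is MSE-optimal and every ratio is
at most 1 — a property the test suite asserts over the entire default grid.

Two exact identities anchor the code: with all cross-measure covariances
zero the models coincide (every ratio is 1 to numerical precision), and
with fixed-effect designs identical across measures *and subjects*, with
$Z$ a shared sub-matrix of $X$ and complete data, the separated fixed
effects are exactly fully efficient — the mixed-model analogue of the
seemingly-unrelated-regressions result for OLS.

## Aggregation choices

Overall MSEs sum coordinates with equal weight (the measures are intended
to live on comparable, quantile-normalized scales), and ratios default to
the ratio of pooled traces across subjects ("ratio of means"). Whether a
subject-average ratio should instead average per-subject ratios is not
determined by the estimands themselves; both are available
(`mse_ratio(..., method = "mean_of_ratios")`), and the pooled version is
the default because it is the trace form the decompositions naturally
produce. Working-model weights always come from zeroing the cross-measure
blocks of the *true* components rather than from refitted univariate
estimates, which isolates the structural cost of separation from
estimation noise.

## The bivariate grid study

The grid study explores a two-measure model with random intercept and
slope per measure. Measure 1 is observed at $n_1 \in \{6, 9, 15\}$ equally
spaced times scaled to $[-1, 1]$; measure 2 retains
$n_2 = \mathrm{round}((1-p_{miss})n_1)$ of those rows, either the first
$n_2$ ("drop-out") or a uniformly drawn subset ("random"), with
$p_{miss}\in\{0, 1/3, 2/3\}$. $\beta$ is treated as known. The covariance
scenarios fix the diagonals — case A all ones; case B residual variance 4
for measure 2 (noisier measure); case C slope variance 4 for measure 2
(more heterogeneous trajectories) — and vary four correlations: the
within-measure intercept-slope correlations $\rho_{k1}=\rho_{k2}=\rho_k
\in \{-0.5, 0, 0.5\}$, and the cross-measure correlations
$\rho_b, \rho_r \in \{-0.9, -0.7, \dots, 0.9\}$ of random effects and
residuals. A single $\rho_b$ populates all four cross-measure entries of
$D$ — the only reading under which the scenario has exactly four free
correlations.

Four free correlations can produce an indefinite $D$, so the raw matrix is
repaired by spectral clipping: eigenvalues below the floor (default 0) are
raised, the matrix is rebuilt and rows/columns rescaled so the original
diagonal is preserved exactly. This is the standard clip-and-rescale
variant of the Rebonato–Jäckel repair; the precise variant is a
documented choice, it is idempotent on PSD input, and tests pin its output
on hand-computed cases.

Cells combining large $|\rho_b|$ and $|\rho_r|$ of *opposite* sign are
excluded from summaries: two correlation sources of one disease process
pulling in opposite directions with both magnitudes ≥ 0.5 is biologically
implausible. The mask threshold is configurable; the headline grid
quantities are computed over the remaining "likely" cells. For the random
pattern the per-cell MSEs are averaged over 20 seeded pattern draws
(deterministically derived from a base seed and the cell index) before the
ratio is formed; drop-out and complete-data cells are deterministic.
Jointly negating $(\rho_b,\rho_r)$ is equivalent to negating the second
measure's data, so results are invariant — a symmetry the suite checks to
$10^{-10}$ with matched pattern seeds.

## Monte-Carlo oracle

Every closed form is validated against simulation: draw $b_i$ and $e_i$
from the true components, apply the working-model estimator, and average
squared errors. The average conditional squared bias is estimated *without
reference to the closed forms* by drawing two independent error vectors
per random-effect draw; the cross-product of the two resulting estimation
errors is unbiased for the squared conditional bias, and variance follows
by subtraction. Fixed effects are unconditionally unbiased, so their
empirical squared bias is the variance-debiased squared mean error.
Sampling uses eigenvalue-floored symmetric square roots, replicates are
processed in chunks of 10^4, and each report carries Monte-Carlo standard
errors and z-scores. The acceptance suite runs 20 seeded configurations
spanning K ∈ {1, 2, 5}, both working models, known and estimated $\beta$,
at $10^5$ replicates each, requiring $|z| \le 3$ for MSE, squared bias and
variance.

## The synthetic five-marker cohort

The case-study-scale machinery runs on synthetic cohorts emulating a
scleroderma registry's structure (the registry itself is not distributable):
five Gaussian measures on the quantile-normalized scale, irregular visits
over 0–40 years since onset, cardiac measures sparser than pulmonary and
skin measures. Per-measure visit counts follow a negative binomial whose
*truncated* (≥ 4, the inclusion criterion) mean and sd are calibrated to
the registry summary intensities (pFVC 12.83/6.20, pDLCO 12.40/6.01, EF
9.13/3.71, RVSP 7.47/3.28, mRSS 19.09/7.61); calibration is by direct
moment matching of the truncated distribution, so empirical cohort
intensities land on the targets rather than below them. Times are drawn
from a per-subject clinic-day process (uniform order statistics), with the
two pulmonary measures sharing pulmonary-test days, the two cardiac
measures sharing echocardiogram days, and the skin score on clinic days.
How often real measure pairs share exact dates is not known to us; this
construction is the modelling choice that makes cross-measure residual
correlation identifiable, and it is deliberately generous about shared
days.

Fixed effects per measure are an intercept, a natural spline of time with
3 df (interior knots at the 33rd/66th percentiles of pooled times,
boundary knots at 0/40), seven baseline covariates (age of onset, sex,
race, skin type, three autoantibodies, with invented but fixed
distributions) and covariate-by-spline interactions — 32 columns per
measure, identical definitions across measures. Random effects are
intercept and linear time. The default truth sets intercept variance 1,
slope variance 0.005 (per year; prior experience with normalized scales
puts plausible 40-year slope excursions near ±2 sd), intercept-slope
correlation −0.2, residual variance 0.5, and a between-measure correlation
matrix with lungs at 0.8, RVSP at 0.55–0.6 with the lungs and 0.5 with
skin, and EF uncorrelated; the 10×10 D is the Kronecker product of the
measure-level and effect-level correlation matrices scaled by the
variances, which is positive definite by construction. The default β
values are fixed, mild, and immaterial: efficiency ratios depend only on
(X, Z, D, R).

What passing tests on this generator shows — and does not. The generator
reproduces the *structural* features that drive efficiency ratios:
relative visit intensities, shared-day patterns, correlation topology, and
Gaussian marginals. It does not reproduce real marginal distributions,
informative (MNAR) visit processes, treatment effects, or non-smooth
trajectory changes, so cohort-level results here demonstrate correctness
of the machinery and qualitative patterns (e.g. the sparse, strongly
correlated measure benefits most from joint modelling), not registry
point estimates.

## Estimating components without a joint fit

The efficiency formulas need (D, R), which the combined model is by
assumption too burdensome to fit. The package therefore estimates them
from separated fits plus moments. Within-measure blocks come from
per-measure `lme4::lmer` maximum-likelihood fits — a deliberate departure
from writing a bespoke EM loop: the per-measure LMM fit is a completely
standard step, `lme4` is the reference implementation, and ML (rather than
REML) keeps the estimates comparable with the moment step. Cross-measure
blocks use unshrunken per-subject effect estimates
$b^*_{ik} = (Z_{ik}'Z_{ik})^{-1}Z_{ik}'(Y_{ik}-X_{ik}\hat\beta_k)$ —
ordinary projections, not BLUPs, precisely so that shrinkage cannot
attenuate cross-covariances. Their empirical cross-covariance estimates
$D_{kk'}$ up to a shared-time residual term, which is removed using
$\hat R_{kk'}$, itself a moment estimator built from products of
conditional residuals at shared times with an exact correction for the
attenuation the projection induces
($E[\hat e_k \hat e_{k'}'] = R_{kk'}(I-H_k)S(I-H_{k'})'$). Subjects
lacking two usable observations for a measure drop out of that measure's
pairs only. The assembled matrices pass through the PSD repair. This
moment scheme stands in for the multivariate DerSimonian–Laird estimators
in the literature; its adequacy is established by parameter recovery
(within-measure components to 10% relative, cross-correlations to ±0.1
absolute at m = 2000) and by the requirement that efficiency ratios at the
estimates track ratios at the truth to ±0.05.

The yearly-correlation comparison (empirical correlations of subject-year
means versus the correlations implied by estimated components) is the
diagnostic for whether the estimated structure matches the data; the
separated components imply exactly zero cross-measure correlation, making
the cost of separation visible at a glance. Within-measure blocks of the
empirical version are mildly attenuated relative to the implied ones
because within-year averaging reduces residual variance; cross-measure
blocks are essentially unaffected, and the tests compare those.

## Numerical choices and degenerate inputs

* Marginal covariances are inverted by Cholesky; a failed factorization
  (e.g. zero residual variance with zero D) raises a "degenerate marginal
  covariance" error rather than producing a pseudo-inverse silently.
* The PSD repair floor is 0 by default; a positive floor (1e-8) is the
  documented option when a repaired matrix must later be inverted.
* Shared-time matching uses an absolute tie tolerance of 1e-9 (times are
  stored in years; clock-level ties are exact in the generator).
* Per-subject fixed-effect blocks may be rank deficient (baseline
  covariates are constant within subject); identifiability is checked
  where it belongs, at the pooled GLS information matrix, which errors if
  singular. The `marker_design` rank check can be disabled for exactly
  this case.
* Seeds: all grid randomness derives from one base seed and the cell
  index via fixed integer arithmetic below 2^31; reruns are byte-stable.

## Problem sizes

The shipped tests evaluate the full default grid (16,200 cells across both
missingness patterns, 20 pattern draws per stochastic cell), validate the
closed forms at 10^5 Monte-Carlo replicates on 20 configurations, and run
parameter recovery on one m = 2000 synthetic cohort with ratio comparison
on 250 subjects — sizes chosen so the whole suite completes on a single
CPU in well under half an hour while keeping Monte-Carlo standard errors
small enough for 3-sigma closed-form checks to be sharp.

## Known limitations

* Residual dependence is shared-time only; serial correlation models
  (AR(1) and friends) and time-varying residual variances are out of
  scope.
* Missingness is assumed ignorable (MAR); informative visit processes
  would bias both working models and are not modelled.
* Gaussian outcomes only, as appropriate after quantile normalization;
  heavy-tailed or discrete outcomes are not covered.
* Efficiency is computed at fixed covariance components; uncertainty in
  estimated components propagates into the ratios only through the
  recovery guarantees above, not through analytic standard errors.
* The mean structure is assumed correctly specified for both working
  models; costs of mean misspecification are a different question the
  framework does not address.
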