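---
title: "Compositional nutrient diagnosis for orchard N trials: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional nutrient diagnosis for orchard N trials: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(nutriclr)
```

`nutriclr` implements the analysis chain used to diagnose the nutrient
status of a perennial fruit crop from a multi-season nitrogen-rate trial:
foliar compositions on the centered log-ratio scale, season-level climate
indices, cutoff classification of performance targets, nutrient standards
derived from the high-performing population, critical values by segmented
regression, and dose-response, variance-partition and carryover stages.
This vignette records the statistical models behind each stage, the
defaults and why they were chosen, and the design decisions that were
genuinely open.

## Foliar compositions and the clr scale

A leaf analysis reports five macronutrients (N, P, K, Ca, Mg, g/kg dry
matter) and five micronutrients (Cu, Fe, Mn, Zn, B, mg/kg). These ten
numbers are parts of a whole — the 1000 g/kg of tissue dry matter — so they
carry relative, not absolute, information: raising one concentration
necessarily dilutes the others. Treating them as unconstrained variables
produces spurious correlations; the standard remedy is log-ratio analysis.

The package completes each composition with a *filling value*,

$$F_v = 1000 - \sum_{\text{macros}} x_i - \tfrac{1}{1000}\sum_{\text{micros}} x_i,$$

the unquantified remainder of dry matter (mostly C, H and O), so that the
11 parts close exactly to the measurement unit. Each part (micros converted
to g/kg) is then mapped to its centered log-ratio

$$\mathrm{clr}(x_i) = \ln\!\frac{x_i}{G}, \qquad
  G = \Big(\prod_{j=1}^{11} x_j\Big)^{1/11},$$

which yields a zero-sum real vector on which Euclidean distances, means and
classifiers are legitimate. The inverse transform exponentiates and
re-closes to the unit. Two conventions matter and are fixed throughout:

* **all clr arithmetic uses the g/kg scale for every part** — the filling
  value is defined on the 1000 g unit, and the magnitude of published clr
  norms (clr_Cu near −5 implies Cu expressed in g/kg) confirms that
  convention;
* component order is N, P, K, Ca, Mg, Cu, Fe, Mn, Zn, B, Fv everywhere;
  published tables vary the micronutrient order, which is presentation
  only.

Zeros (values below detection) are incompatible with logs; `replace_zeros()`
uses multiplicative replacement — the zero becomes 0.65 x the detection
limit and the remaining parts are rescaled to preserve the total. The 0.65
fraction is the common compositional-data default; the choice matters
little because the replacement only affects censored micronutrients.

Numerically, algebraic identities (clr sum, closure, round trips) are held
to 1e-9; user-supplied clr vectors are accepted if they sum to zero within
1e-6 and are recentred with a warning otherwise. Scale invariance and the
round-trip identity are asserted property-style in the test suite;
sub-compositional dominance is *not* claimed.

## Climate indices

Growing degree-days are accumulated between full bloom and harvest,
inclusive on both ends (nothing in the agronomic definition excludes either
day). Method 1 sums unclamped daily means minus the base temperature, so
cold days subtract thermal time; Method 2 first clamps Tmin and Tmax into
the threshold band [TLT, TUT] = [7, 35] °C, bounding each daily term in
[0, 28] degree-days. The defaults Tbase = TLT = 7 °C and TUT = 35 °C are the
peach convention (growth triggers near 7 °C and ceases above 35 °C). On mild
climates the two methods are nearly collinear (r > 0.99), which the test
suite and the acceptance script both verify on simulated seasons.

Chilling hours count hours **below** 7.2 °C over the dormant season. Source
material on this index sometimes prints the inequality the other way; the
Weinberger convention, and the agronomic reading (a warm winter gives *few*
chilling hours and a failed crop), fix the direction used here. The package
computes the count from hourly temperatures; when only daily extremes
exist, the generator's diurnal interpolation supplies hours and the
pipeline notes it. The dormant window defaults to May 1 – August 31
(Southern-Hemisphere autumn–winter). Chill portions and Utah chill units
are deliberately out of scope.

## Cutoff classification and the norm population

Each target (yield, firmness, hue, chroma, TSS, TTA, phenolics,
carotenoids, antioxidant content) is binarized at an agronomic cutoff.
Orientation is explicit per target: all default to high-is-good except
titratable acidity, where commercial guidance favors *low* acidity. Values
exactly at the cutoff map to the favorable class — a deterministic,
documented tie rule. Rows with a missing measurement are dropped per
target, not imputed.

Two classifier families are cross-validated with stratified 10-fold CV on
standardized features: k-nearest neighbors (k = 5, Euclidean distance) and
an L2-penalized logistic linear classifier (the regularized linear
decision rule that stochastic-gradient training converges to; fitted here
by coordinate descent). Folds are assigned from specimen keys, so row
order never changes the assignment; standardization is estimated on each
training fold only. Both models are reported per target and the better one
is flagged by out-of-fold AUC — accuracy alone would hide poorly
calibrated scores.

The confusion matrix uses the norm-population convention of nutrient
diagnosis rather than the epidemiological one: *true negatives* are
specimens predicted **and** observed high-performing. They are the
nutritionally balanced population from which standards are derived; that
is the entire purpose of the classification stage. Classification accuracy
is (TN + TP)/n and AUC is the rank (Mann–Whitney) statistic with ties
counted 1/2.

## Nutrient standards, sufficiency ranges, critical values

The clr standards are the per-component mean and (n−1) standard deviation
over the true negatives; the means again sum to zero. Concentration ranges
are produced in two modes because published norm tables are not consistent
with any single rule:

* **parametric-ci** (default): the clr bound
  $\bar z_i \pm t_{1-\alpha/2,\,n-1}\, s_i/\sqrt n$ (α = 0.01) is
  exponentiated with the other components held at their mean, then closed
  to the unit. This reproduces the narrow published N range (28–30 g/kg
  from a clr mean of 3.16 ± 0.108 at n = 58).
* **empirical-quantile**: α/2 and 1−α/2 quantiles of the per-specimen
  closed concentrations; much wider, matching ranges in published tables
  that behave like mean ± 2 SD.

Both modes ship; reports state which was used rather than silently picking
one.

The sufficiency range is the highest-density interval holding 90% of the
kernel-density mass (Gaussian kernel, Silverman bandwidth, 4096 grid
points) of a nutrient among the norm population — "highest density", not
equal tails, because the quantity of interest is where high-performing
concentrations concentrate. For symmetric unimodal samples the two
coincide within estimation error; the tests check this against central
quantiles, and against the analytic 0.90-length interval of a uniform
sample.

Critical values come from the linear-plateau model, the standard agronomic
segmented response: linear up to a breakpoint, constant beyond (or the
mirrored plateau-then-trend shape; the two orientations compete by SSE).
The breakpoint is located by grid search over observed predictor values
and their midpoints with exact least squares per candidate, evaluated in
O(1) per candidate from prefix sums. Uncertainty comes from a
case-resampling bootstrap (default 200 resamples, percentile interval).
An earlier formulation of this estimand used hierarchical Bayesian
regression with Gibbs sampling; the grid-plus-bootstrap route estimates
the same quantity deterministically and without an MCMC dependency, which
is why it was chosen. A flat response is rejected as breakpoint-
indeterminate rather than fitted. Noise-free recovery is exact whenever
the true breakpoint lies on the candidate grid, and the bootstrap interval
covers a true breakpoint in ≥90% of simulated replicates at moderate noise
(10% of the plateau level, n = 200) — both are asserted in the tests.
Where the response is linear throughout (acidity on clr_P),
`linear_effect()` reports the OLS slope and Pearson r instead.

## Dose response, variance partition, carryover

Per-season dose trends use the randomized-complete-block ANOVA with
orthogonal polynomial contrasts on the equally spaced N rates; linear and
quadratic components are tested at the 5% level, the CV is
100·√MSE / mean, and the dose of maximum observed mean is reported.
Whether published trend tables used block as a factor or plot means is not
stated in most sources; the block-factor ANOVA is used here and documented.

The variance partition is the main-effects ANOVA (season, dose, block)
expressed as shares of the total sum of squares. A conditional-inference
tree could display the same decomposition, but the published quantities
are variance proportions, and sum-of-squares shares are the direct,
dependency-free estimator of those.

Feature ranking scores each standardized feature by the simple-regression
F statistic, F = (n−2) r² / (1−r²), the "univariate regression" convention
of the data-mining tools this workflow mirrors (score magnitudes of 0–165
at n = 80 are consistent with F values). Perfect collinearity returns a
capped sentinel rather than infinity.

The carryover stage predicts each plot's next-season target from its
previous-season foliar clr composition (stored nutrients), its
previous-season target (stored carbohydrates) and the current
fertilization, with gradient boosting (200 trees, depth 3, learning rate
0.1, fixed seed) as the default learner; any regressor with a fit/predict
contract could be substituted. Training uses all seasons before the test
season — 60 records when the last of four seasons is held out. For the
first trial season to have prior-season features, the generator emits a
pre-trial baseline season under uniform management (the orchard's pre-trial
N regime); without it the first season's 20 records would be orphans and
the published 60/20 train/test split would be unreachable. The no-carryover
baseline (`use_prior_target = FALSE`) quantifies what the stored-reserve
proxy contributes.

## What the synthetic generator emulates

The generator is first-class, tested code; every downstream stage is
validated against its known ground truth. It emulates:

* the 4-season x 5-dose x 4-block design (80 records) with per-season
  quadratic dose response fitted once from published season-mean yields;
* yield variance shares of season 0.73, dose 0.07, block 0.05, residual
  0.15 — the season and dose main effects of the quadratic surface are
  rescaled to their specified shares, the season x dose interaction is
  folded into the residual budget, block effects are an
  exactly-standardized random pattern, and iid noise fills the remaining
  residual variance;
* logistic-normal foliar compositions: independent clr Gaussians centred
  on published high-yield norms (recentred exactly onto the simplex, since
  the printed means sum to −0.014 from rounding), projected to zero sum
  and inverse-clr-closed. This is exactly the distributional assumption
  the clr standards make;
* breakpoint physiology: yield and antioxidant content decline linearly
  below clr_Cu = −5.410; pulp firmness gains a 0.6 N step above
  clr_P = 0.556; acidity declines at −0.3% per clr_P unit;
* a lag-1 carryover: each plot carries 0.3 x its previous-season
  idiosyncratic yield deviation (measured against its season-by-dose cell
  mean, so design-factor variances are not distorted);
* Southern-Hemisphere weather: daily means on a seasonal cosine (18 °C
  mean, 6 °C half-amplitude, warmest mid-January), 8 °C diurnal range,
  2 °C daily noise, hourly temperatures from a piecewise cosine anchored
  at dawn Tmin and mid-afternoon Tmax, and gamma wet-day rainfall scaled
  to 1509 mm/year. A winter under these defaults accumulates a few hundred
  sub-7.2 °C hours, the plausible range for a low-chill site;
* quality-target season effects sized so the final season is a commercial
  failure (low yield, hue, chroma, antioxidants), giving every target both
  performance classes in realistic proportions.

Residual CVs for yield fall out of the variance shares at 8–12%, matching
the published coefficient-of-variation column for this kind of trial.

What it does **not** emulate: real phenology or photosynthesis, spatial
autocorrelation between blocks, correlated measurement error across
nutrients, inter-annual weather persistence, or alternate bearing beyond
the lag-1 term. Passing the recovery tests therefore shows the estimators
are correct under the stated logistic-normal, additive-effects model — not
that real orchard data satisfy that model.

## Worked example

```{r pipeline, eval = FALSE}
report <- run_pipeline(pipeline_config(), seed = 1)
print(report)
```

The report prints per-season climate indices, the per-target
classification table (best model, AUC, CA, confusion counts), the clr
standards with back-transformed ranges, the N sufficiency range, the
clr_Cu and clr_P critical values, the variance partition, per-season dose
trends, and the carryover prediction for the held-out season (which
overpredicts the failure season — the carryover story the package exists
to quantify).

## Problem sizes and runtime choices

The reference analyses run on the 80-record design; parameter-recovery
tests use up to 5040 simulated compositions (clr location recovery), 100
replicate fits of 200 points (bootstrap coverage), and 10 paired
replicates of the carryover comparison — sizes at which every check
completes in seconds while keeping Monte-Carlo error well inside the
asserted tolerances. The density grid (4096 points), bootstrap default
(200 resamples) and the capped F sentinel (1e6) are the only purely
numerical constants; none is load-bearing for the scientific conclusions.

## Known limitations

* The breakpoint bootstrap is a percentile interval; for very small
  samples (n near the minimum of 10) it can undercover and should be read
  qualitatively.
* The relative-yield normalization used in some published critical-value
  plots is never defined precisely in the sources this workflow mirrors;
  where needed, the package normalizes within season (percent of the
  season maximum) and says so.
* The SGD-family classifier is represented by its penalized-likelihood
  limit, not by a literal stochastic-gradient trajectory; results differ
  only through the optimizer's stochasticity, which is not of scientific
  interest here.
* Concentration ranges depend on the chosen mode (parametric vs
  empirical); the package surfaces the discrepancy instead of resolving
  it, because the underlying convention in published norm tables is
  indeterminate.
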