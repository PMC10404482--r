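---
title: "Validating body-fat devices against a four-compartment criterion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating body-fat devices against a four-compartment criterion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biavalid)
```

## The problem

Consumer bioelectrical impedance analysers estimate body-fat percentage
(BFP) cheaply, but their accuracy must be judged against a laboratory
criterion. The accepted criterion is a four-compartment (4C) model that
partitions body mass into fat, water, bone mineral and residual, combining
body mass (BM, calibrated scale), body volume (BV, air-displacement
plethysmography), total body water (TBW, bioimpedance spectroscopy) and
DXA bone mineral content (BMC). biavalid implements the complete
validation workflow for a panel of devices measured in duplicate at a
baseline visit, with an optional follow-up visit 12–16 weeks later for
longitudinal validity.

## The criterion model

Bone mineral is `Mo = 1.0436 × BMC` (the ashing correction), and fat mass
follows the Wang 4C equation

$$FM = 2.748\,BV - 0.699\,TBW + 1.129\,Mo - 2.051\,BM,$$

with $\%BF = 100\,FM/BM$. The equation is linear and homogeneous of degree
one, which the unit tests exploit (finite-difference linearity, scale
invariance of BFP). Physically inconsistent inputs can put BFP outside
[0, 100]; the package flags such records with a warning but returns the
value, because a validation pipeline should surface suspect rows rather
than silently drop them. Body volume is used as supplied — thoracic gas and
clothing corrections are assumed to have been applied upstream by the
instrument.

## Reliability

With exactly two readings per participant the within-subject SD is
$|d|/\sqrt{2}$, so the pooled precision error is
$PE = \sqrt{\sum_i d_i^2 / 2n}$ — algebraically exact for duplicates, with
no need for general ANOVA machinery. The least significant change is
$LSC = 2.77 \times PE$; the printed multiplier 2.77 (rather than
$1.96\sqrt{2} = 2.7719$) is the default to match conventional reporting,
with the unrounded variant behind `exact_multiplier = TRUE`. Pairs with a
missing second reading are dropped from the reliability metrics only
(complete-case per metric), and the complete-case count is the PE
denominator.

Some consumer devices return a near-identical value on an immediate retest
("reading lock"), which makes PE an artefact of firmware rather than a
precision estimate. `detect_reading_lock()` flags a device when the largest
absolute duplicate difference is at most 0.1 % (one display unit). The
comparison uses a $10^{-9}$ slack because readings held at 0.1 %-resolution
differ from their nominal values by a few ULPs.

## Agreement

All agreement statistics treat the device as the predictor ($x$) and the 4C
criterion as the response ($y$); differences are device minus criterion.

* **CE / TE.** Constant error is the mean difference (reported with its
  sample SD); total error is the RMSE. They satisfy
  $TE^2 = CE^2 + \frac{n-1}{n} SD^2$, asserted as an invariant.
* **OLS.** The standard error of the estimate is the residual SD of the
  $y$-on-$x$ fit, $\sqrt{RSS/(n-2)}$. Intercept/slope standard errors are
  computed from closed forms rather than `summary.lm()` so that exact fits
  (synthetic data with zero noise) do not warn.
* **Deming.** The errors-in-variables slope uses the closed form in the
  error-variance ratio $\delta$. $\delta$ defaults to 1 (orthogonal
  regression), the standard choice when replicate-based error estimates for
  both methods are unavailable; it is configurable. Confidence intervals
  use the leave-one-out jackknife, standard practice for Deming fits. As
  $\delta \to \infty$ the fit approaches OLS $y$-on-$x$ and as
  $\delta \to 0$ the inverse of OLS $x$-on-$y$ (tested numerically).
* **CCC.** Lin's concordance correlation is computed with population
  ($1/n$) moments per its original definition.
* **Bland–Altman.** Bias and 95 % limits of agreement (multiplier 1.96, the
  Bland–Altman convention) plus a regression of differences on pairwise
  means; proportional bias is declared when that slope differs from zero in
  a two-sided t-test at $\alpha = 0.05$. No multiplicity correction is
  applied across devices — each device is an independent validation
  question. The individual-level ranking metric is the LOA *width*
  (upper − lower), which captures dispersion irrespective of bias sign.
* **TOST.** Equivalence is declared when the 90 % two-sided t-interval of
  the mean difference lies wholly inside the region — ±2 % for
  cross-sectional and ±1 % for longitudinal comparisons (the tighter
  longitudinal region reflects the small mean change a 12–16 week interval
  produces). With zero variance the interval degenerates to the observed
  mean. The textbook t-interval TOST is implemented; equivalence decisions
  are monotone in the region width.
* **Change scores** use the *first* baseline replicate for both device and
  criterion, matching the convention of taking the first of duplicate
  readings for validity analyses; only participants complete at both
  visits are retained.

## Ranking

Each device is scored within five domains — PE (reliability), TE (group
validity) and LOA width (individual validity), the latter two in both modes
— by competition ranking (ties share the best place: 1, 2, 2, 4), chosen
over dense ranking so that a block of $k$ flagged devices occupies the last
$k$ places. Metrics are rounded to their reporting precision before ranking
(PE to 2 decimals, TE and LOA width to 1) so ties arise exactly as they
would from a published table; `round_metrics = FALSE` ranks on unrounded
values. Lock-flagged devices cannot be credited for artificially low PE:
they all receive the tied worst block (score = number of unflagged devices
+ 1). Global score is the simple sum of the five domain scores,
competition-ranked ascending with no secondary tie-break.

## The synthetic generator

`simulate_study()` emulates the statistical structure the analysis assumes:

* True baseline BFP is truncated-normal with mean 24.7 %, SD 9.1 %,
  truncated to [3, 55] % — a range spanning plausible adult values without
  pathological tails. The longitudinal change is normal with mean 0.2 %,
  SD 2.9 %, re-truncated so the follow-up value stays inside the bounds.
  Draws use the inverse-CDF method, so zero-variance configurations are
  exactly degenerate and every draw is deterministic under the seed.
* 73 participants with the first 37 returning at follow-up mirror a
  realistic single-site validation cohort.
* 4C components are *back-solved*: fat-free mass is split using fixed
  physiological fractions (hydration 0.73, bone mineral 0.045 of fat-free
  mass) and body volume is solved from the Wang equation, so the criterion
  pipeline reproduces the intended criterion BFP to $10^{-9}$. Only the
  reconstructed BFP matters downstream; the components need only be
  plausible and exactly consistent. Follow-up body mass holds fat-free
  mass constant, attributing mass change to fat.
* A device reading is truth + constant bias + proportional slope ×
  (truth − cohort mean) + Gaussian noise, rounded to the display resolution
  (default 0.1 %) and clamped to the physical range [0, 100] %. For lock
  devices the second duplicate is the first plus a noise draw clamped to
  ±`lock_threshold`, evaluated after rounding so the clamp holds exactly on
  displayed values — reproducing "same estimate on immediate retest"
  without modelling vendor firmware.
* Each (device, session) pair draws from its own RNG substream derived by
  stable string hashing, so adding or removing a device never perturbs the
  other devices' readings.

The default 15-device panel (A–O, five of them locked) is illustrative: it
spans realistic ranges of constant error (−3.5 to +11.7 %), proportional
bias and noise, including one grossly biased outlier device and one
research-grade device. Because the model has a *single* noise term, it
cannot simultaneously produce the very small PE (< 0.5 %) and the large
between-subject disagreement (SEE > 3 %) seen in real panels, where device
error is largely subject-stable; the defaults favour realistic agreement
statistics, so the simulated PE values are larger than a real panel's.
Passing tests on these fixtures demonstrates that the statistics and the
ranking arithmetic are correct and that parameters are recoverable — not
that any particular commercial device behaves like a fixture device.

## Numerical choices and degenerate inputs

* Reading-lock detection and the duplicate clamp use a $10^{-9}$ absolute
  slack for display-resolution floating point.
* Degenerate Bland–Altman inputs: constant differences give a slope of
  exactly 0 with no proportional-bias flag; a degenerate mean axis skips
  the regression and still returns the LOA.
* `constant x` makes the OLS fit an error; a zero device–criterion
  covariance makes the Deming slope an error with a diagnostic.
* Competition ranks are computed with `rank(ties.method = "min")`; scale
  invariance and order invariance are property-tested.
* Test problem sizes: study-scale runs use 73/37 participants; parameter
  recovery uses n = 2000 with Monte-Carlo oracles at n = 100 000;
  distributional calibration (LOA coverage, LSC exceedance) uses
  n = 10 000. These sizes give standard errors comfortably inside the
  asserted tolerances while keeping the suite fast.

## Limitations

Immediate test–retest reliability reflects technical precision only; the
generator does not model day-to-day biological variability, anthropometry,
hydration status or device-specific firmware, and between-day reliability
is out of scope. Real-data analyses should treat the packaged device panel
purely as a demonstration fixture.
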