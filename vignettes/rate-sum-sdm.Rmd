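---
title: "Germination rate sums as species-distribution covariates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Germination rate sums as species-distribution covariates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratesumSDM)
```

This vignette documents the models implemented in `ratesumSDM`, the
assumptions behind them, the tunable parameters that matter, and the design
choices made where the design was genuinely open. It states no empirical
results beyond what the package's tests and analysis scripts themselves
compute.

## 1. The wet-thermal germination model

Cheatgrass germination progress is modeled as accruing only during hours
when shallow soil (2 cm) is simultaneously warm and wet. For hour $t$ with
soil temperature $T_t$ (°C) and water potential $\psi_t$ (MPa),

$$
r(T_t,\psi_t) \;=\;
\begin{cases}
\max\!\big(0,\; c_0 + c_1 T_t + c_2 T_t^2\big), & T_t > 0\,^{\circ}\mathrm{C}
\text{ and } \psi_t > -1.25\ \mathrm{MPa},\\[2pt]
0, & \text{otherwise,}
\end{cases}
$$

with defaults $c_0 = 1.29\times10^{-4}$, $c_1 = 6.16\times10^{-4}$,
$c_2 = -1.25\times10^{-5}$ per hour — the averaged germination curve of the
35% subpopulation of sagebrush-steppe cheatgrass seed lots. A **rate sum**
over a window is $\sum_t r(T_t,\psi_t)$: the number of times conditions in
that window would have carried the 35% subpopulation to germination. Rate
sums accumulate over all qualifying hours with no sequential-wetting reset,
by design: the metric is meant to capture cumulative effects of small,
disparate favorable windows that an annual grass can exploit.

Numerical conventions, all asserted by tests:

* **Strict thresholds.** An hour at exactly $T = 0$ or exactly
  $\psi = -1.25$ contributes 0. (One source sentence reads "soil water
  availability < −1.25 MPa"; since wet means *less negative* potential,
  this is treated as a typo and the `>` condition is used.)
* **Clipping.** The quadratic goes negative above ~49 °C; rates are clipped
  at 0 there.
* **Term structure.** The three printed coefficients admit a degenerate
  "literal linear" reading $c_0 + T(c_1 + c_2)$. The concave-down quadratic
  is the only arrangement giving a biologically plausible wet-thermal curve
  (optimum near 24.6 °C; the 35% subpopulation germinating in ~5–6 days of
  continuously wet 20 °C soil), so it is the default; the linear reading is
  selectable via `rate_params(poly_form = "linear")`. Both agree in the
  $T \to 0^+$ limit.
* **Calendar.** Monthly sums use the civil calendar with leap days;
  timestamps are hourly, local, timezone-free, with no daylight-saving
  discontinuities (the method is insensitive to clock conventions).
  Partial boundary months are dropped with a warning; hourly gaps are an
  error naming the first gap.

Seasonal sums attach to an **observation year** $y$: fall = October +
November + December of $y-1$, spring = March of $y$ — the seedbed conditions
immediately preceding a growing-season field observation.

## 2. The four covariates

Let $s_{iy}$ be a site-year seasonal rate sum. The model uses, per season
(fall, spring):

* **Spatial covariate**: the site's long-term mean $\bar s_i$ z-scored
  across sites, $(\bar s_i - m)/\mathrm{sd}$ — between-site climate. A site
  at 0 has average favorability relative to the reference site set.
* **Temporal covariate**: the site-year value z-scored within the site,
  $(s_{iy} - \bar s_i)/\mathrm{sd}_i$ — the weather anomaly for that year.

Design choices (each with the reasoning):

* **Sample (n−1) SDs** throughout: conventional, and unstated in the
  source; nothing downstream depends on the factor.
* **Leakage-safe scaling.** Spatial constants are computed on *training*
  sites only and frozen (`build_covariates(..., constants = )`) for test
  and hindcast covariates, so no test-set information leaks into the
  covariate scale. Within-site temporal statistics are intrinsic to a site
  and are computed from its own reference-period years.
* **Reference period.** Site means and within-site SDs use the full
  simulated period, not only observed years: the spatial covariate is
  climatology, and the hindcast needs covariates in unobserved years.
* **Zero-SD anomalies map to 0.** Cold sites can have identically zero rate
  sums every year; 0 correctly encodes "average for this site". Single-year
  sites likewise get 0.

`screen_covariates()` reproduces the covariate-selection step: Pearson
correlation of candidate rate-sum groupings with percent cover, ranked by
$|r|$ (ties alphabetical, constant candidates last). The final four
covariates are fixed as above; the package does not re-run a model search.

## 3. Presence and cover GAMs

Both models are additive in the four covariates with univariate smooths:

$$
\mathrm{logit}\,P(\text{presence}) = \alpha + \sum_{j=1}^4 f_j(x_j),
\qquad
\mathbb{E}[\text{cover}] = \alpha + \sum_{j=1}^4 f_j(x_j),
$$

binomial-logit and Gaussian-identity respectively. Presence is defined as
cover > 2% (strict). The cover model is fitted on all observations
including zeros, with raw (untransformed) percent cover — the source
design; a transformation would be a modeling change, not a default.

Fitting choices:

* **Basis**: cubic regression splines, $k = 10$ per term, with knots spread
  evenly through each covariate's observed range (so spline flexibility
  covers all combinations of covariate values, not just dense regions).
* **Smoothness selection**: REML (configurable to GCV); deterministic given
  data and configuration.
* **Shrinkage**: double-penalty selection (`select = TRUE`, Marra–Wood) so
  the penalty can remove a smooth entirely. Without it, a truly null
  covariate retains a spurious wiggle in an appreciable fraction of
  replicates; with it, null smooths shrink to effective degrees of freedom
  near 0. This is the package's own default, validated by the
  null-recovery tests.
* **Classification threshold**: 0.5 on predicted probability, strict `>`
  (a probability exactly at the threshold is labeled absent); configurable.
* **Extrapolation**: predictions outside the training covariate range are
  permitted but flagged per row.

`partial_effects()` returns each smooth on an even grid over its training
range with the fit's own sum-to-zero centering and pointwise standard
errors; `truth_partial_effects()` centers the generative curves the same
way so fitted and true shapes are directly comparable.
`model_diagnostics()` reports per-term EDF against the basis dimension
(flagging EDF > 0.9·(k−1), i.e. a basis near exhaustion), a Pearson
dispersion estimate, and a deviance-residual summary.

## 4. Validation and hindcast

**Watershed-blocked holdout.** Whole watershed units are the sampling unit:
`round(test_fraction × n_watersheds)` units (default 1/3) are sampled into
the test set, so no site — and no spatially contiguous cluster — appears on
both sides. Realized observation fractions therefore vary around the
nominal fraction and are reported in the split record.

**Metrics.** Sensitivity (presence accuracy), specificity (absence
accuracy), their unweighted mean (balanced accuracy), overall accuracy, and
the confusion counts; cover is scored by the squared Pearson correlation of
observed vs predicted (the convention comparable across studies; the
$1-\mathrm{SSE}/\mathrm{SST}$ variant is available). Note the Pearson form
is sign-blind and scale-free: it rewards linear association, not agreement.

**Hindcast.** Sites are stratified into elevation terciles (rank order,
ties by site id, sizes differing by ≤ 1) and aspect classes from azimuth
quarters (N = [315°,360°) ∪ [0°,45°), E, S, W analogous, half-open). The
fitted presence model is applied to every site-year of the window
(missing site-years are an error), per-stratum occupied fractions are the
proportion of sites with probability above the threshold, and trends are
OLS slopes of fraction on year. Relative change over the window is
computed from the *fitted* endpoints, $100(\hat f_{end}-\hat
f_{start})/\hat f_{start}$ — robust to single-year noise; the raw-endpoint
variant is selectable, and the change is reported as undefined when the
fitted start is ≤ 0. The default hindcast window starts the year after the
first simulated year (the first year with a complete preceding fall).

## 5. What the synthetic generator emulates — and what it does not

The generator is a statistical stand-in for a physical soil heat/water
simulator. It reproduces exactly the features the rate-sum chain consumes:

* **Temperature**: annual mean declining with elevation at 6.5 °C/km
  (standard environmental lapse), seasonal cosine (amplitude 11 °C, peak
  day 205 — late July), diurnal cosine (amplitude 7 °C, peak 14:00), a
  south-facing aspect term scaled by sin(slope) (max 5 °C — solar loading
  on steep south slopes), and AR(1) weather noise (SD 2.2 °C, hourly
  autocorrelation 0.97, giving multi-day warm/cold spells).
* **Moisture**: wetting events as hourly Bernoulli draws (0.35/day in the
  October–May wet season, 0.06/day June–September) resetting $\psi$ to
  −0.03 MPa, then exponential dry-down toward a −8 MPa floor with
  e-folding time 9 days at 10 °C, halving per 10 °C warming (faster summer
  dry-down).
* **Optional climate trend**: a linear warming increment confined to
  configurable months and to sites below an elevation cutoff, for
  climate-trend experiments.
* **Observations**: presence drawn Bernoulli with logit = intercept + the
  four true partial effects (concave-down quadratic in fall-spatial,
  saturating increase in spring-spatial, concave increase in
  fall-temporal, linear decrease in spring-temporal); cover for presences
  is Gaussian around a linear-in-effects mean, floored just above the 2%
  presence cutoff and capped at 100. The floor (rather than 0) keeps
  generated presence labels identical to cover-derived labels — otherwise
  a few percent of generated presences would relabel as absences.

Default truth amplitudes were set, as a design choice, so that the
generative signal is strong but not trivial: mean presence probability
near 0.5 (about the presence frequency of regional cheatgrass field
datasets) and a combined linear-predictor SD near 2 logits, which puts the
Bayes-optimal balanced accuracy in the mid-0.8s — comfortably above what a
fitted model must reach for the recovery tests while leaving real
estimation error visible.

Deliberately **not** emulated: energy-balance/Richards-equation soil
physics, snow, vegetation canopy, spatially correlated weather between
sites, repeat within-year visits (at most one observation per site-year),
disturbance and fire, and biotic interactions. Passing tests on this
synthetic world therefore demonstrate that the *chain recovers known
structure from data shaped like its inputs* — not that the fitted
ecological relationships transfer to any real landscape. Soil texture
fields are generated for schema compatibility with real soil-model inputs
but do not enter the emulator's physics.

## 6. Problem sizes and reproducibility

The test suite and analysis scripts run the study at desk scale, chosen as
the package's own working sizes: 200 sites in 20 watersheds over 16
simulated years (~2000 observations) for recovery and validation; 60 sites
over 31 years for the warming experiment; 40 sites over 6 years for
pipeline determinism checks. Every stochastic step takes an explicit seed,
per-stage seeds derive from one master seed (`derive_seeds()`), and each
generator restores the caller's RNG state, so identical configuration
reproduces every numeric artifact bit for bit. Model records are exported
as versioned JSON (family, knots, coefficients, smoothing parameters,
EDFs, training ranges, scaling-constants hash); fitted model objects
themselves live in the R session of a run.

## 7. Known limitations

* The binomial GAM attenuates strongly curved effects in covariate regions
  where the probability saturates near 0 or 1 (little gradient
  information); shape recovery there is qualitative (sign, optimum
  location) rather than pointwise.
* The Gaussian cover model can predict outside [0, 100]; a clamped copy is
  returned alongside the raw prediction, and families better suited to
  proportions (beta, Tweedie) are intentionally out of scope.
* The balanced-accuracy metric is threshold-dependent; 0.5 is the
  symmetric default, not an optimized operating point.
* The emulator's watersheds are planar k-means clusters — contiguous, but
  without drainage topology; they exist to provide spatial blocking
  structure, nothing more.
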