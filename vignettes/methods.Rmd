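---
title: "Evaluating farmland-consolidation effectiveness from NDVI time series: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating farmland-consolidation effectiveness from NDVI time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcndvi)
```

## The problem

Farmland consolidation (FC) — re-parcelling, irrigation and drainage
construction, soil amelioration — is intended to raise agricultural
productivity. Whether a completed project actually did so can be read off
satellite vegetation-index history: this package evaluates parcel-level
16-day NDVI composite series (23 composites per calendar year, the MODIS
MOD13Q1 cadence, over a 2001–2013 record) around each project's completion
year, and for projects completed too recently to have a meaningful
post-completion record, predicts the same outcomes from project-level
covariates with support vector machines.

The full chain is: quality screening → gap filling → Savitzky–Golay
smoothing → four before/after change indicators → a seven-type improvement
typology → per-indicator RBF-SVM prediction → cohort-level rate
aggregation. Every stage is driven by a synthetic cohort generator with
known ground truth, so the chain can be validated end to end.

## The four indicators

For a project completed in year $c$ on a record spanning years
$y_0 \dots y_1$, the *before* window is $y_0..c$ (works finish within the
completion year; that year's crop still reflects the pre-project state)
and the *after* window is $c{+}1..y_1$. With $\mathrm{NDVI}$ the parcel-mean
composite series,

$$\mathrm{MEN}_{change} = \overline{\mathrm{NDVI}}_{after} - \overline{\mathrm{NDVI}}_{before}$$
$$\mathrm{SDN}_{change} = \sigma(\mathrm{NDVI}_{after}) - \sigma(\mathrm{NDVI}_{before})$$
$$\mathrm{MAN}_{change} = \max(\mathrm{NDVI}_{after}) - \max(\mathrm{NDVI}_{before})$$
$$\mathrm{PFN}_{change} = \mathrm{PF}(\mathrm{NDVI}_{after}) - \mathrm{PF}(\mathrm{NDVI}_{before})$$

interpreted as changes in productivity level (PL), productivity variation
(PV), productivity potential (PP) and multi-cropping index (MI). A project
is *effective* on an axis by strict inequality — $\mathrm{MEN}>0$,
$\mathrm{SDN}<0$, $\mathrm{MAN}>0$, $\mathrm{PFN}>0$ — so an exact zero
change is non-effective; ties never count in favour.

Three reading choices are genuinely open and resolved as follows:

* **Mean and maximum** are taken over *all composites* in a window — the
  literal reading of the difference formulas.
* **Standard deviation** defaults to the population SD of *per-year mean*
  NDVI across the window years (`sdn_change(mode = "annual_mean")`):
  productivity variation means inter-annual yield fluctuation, and the
  pooled-composite SD is dominated by the seasonal cycle rather than by
  year-to-year stability. The pooled mode is retained
  (`mode = "pooled"`) for users who prefer the literal pooled statistic.
* **Raw vs smoothed input**: the moment indicators (mean/SD/max) default to
  screened, gap-filled but *unsmoothed* values — smoothing attenuates
  maxima, which biases MAN toward zero — while peak counting always runs on
  the smoothed curves, since prominence-based detection needs denoised
  shapes. `use_smoothed_moments = TRUE` switches the moments to the
  smoothed curves.

## Screening, gap filling, smoothing

A parcel enters the analysis only if its area exceeds 100 ha (strictly;
smaller parcels cover too few 250 m pixels for a stable mean) and, after
masking observations with pixel-reliability flag above 1, no calendar year
has more than 5 missing composites. The missing-value rule is applied
*per parcel-year*: 5 of 23 composites keeps annual statistics meaningful,
whereas 5 of a 13-year record would never bind. Reliability masking
precedes the count, so an unusable flag is a missing value. Both
thresholds and the flag cutoff are configuration keys.

Gaps are filled by linear interpolation along the *concatenated*
multi-year composite index, so a gap at a year boundary borrows from the
adjacent year; leading/trailing gaps take the nearest observed value. The
Savitzky–Golay filter (window 7 composites, polynomial order 2 —
approximating common TIMESAT practice; both configurable) also runs on
the concatenated sequence to avoid year-boundary edge artifacts, then the
record is split back into per-year curves and clipped to the valid NDVI
range $[-0.2, 1]$. The filter is linear and preserves polynomials up to
its order exactly, including at the record ends — the test suite checks
constants and linear ramps to $10^{-9}$.

## Peak counting

The multi-cropping index is the number of crop cycles per year, counted
as seasonal peaks of the smoothed annual curve: local maxima (plateaus
collapsed to their center) that reach an absolute floor of 0.3 NDVI
(off-season and bare-soil values sit below it), have topographic
prominence of at least 0.1 NDVI, and are at least 3 composites (48 days,
shorter than any crop cycle) apart, with the higher of two close peaks
winning. The floor, prominence and separation thresholds are this
package's choices — the multi-cropping literature the method descends
from does not publish parameters — and all three are arguments. The
implementation is verified against an exhaustive brute-force counter on
10,000 random curves.

## Improvement typology

The four effectiveness flags combine into seven improvement types:
elementary (EI = upgraded PL), stability (SI = PL∧PV), potential
(PI = PL∧PP), intensity (II = PL∧MI), stability+potential (SPI),
stability+intensity (SII) and optimal (OI = all four). Two readings of
the published type table exist: the *inclusive* reading ("at least these
indicators effective"), under which the types form a lattice
(OI ⇒ SPI ∧ SII ⇒ SI ∧ PI ∧ II ⇒ EI) and a cohort's EI rate equals its
upgraded-PL rate — an identity the published national rates satisfy — and
the *exclusive* literal reading, under which the seven rows partition the
PL-effective projects except for one combination (PL ∧ PP ∧ MI without
PV) absent from the table. The package defaults to inclusive, keeps the
exclusive label alongside, and reports the missing combination as
`UNMAPPED` rather than silently merging it.

## The prediction stage

Projects completed near the end of the record (2011–2013 in the study
design) cannot be evaluated directly — vegetation needs roughly three
years to re-establish after consolidation earthworks, and the
post-completion record is too short. Their four effectiveness
characteristics are instead predicted from sixteen project-level factors
(terrain, climate, socioeconomic context, land-resource endowment,
project properties) with one soft-margin C-SVC per indicator, labels
$y_i \in \{1, -1\}$, and the RBF kernel
$k(x_i, x_j) = \exp(-g \lVert x_i - x_j \rVert^2)$.

Protocol details, all tested:

* **Split**: training = projects completed 2006–2009, testing = 2010
  (2982 / 1460 at the design scale); later projects are the prediction
  set.
* **Scaling**: per-feature min–max scaling to $[0,1]$ learned on the
  training partition only and applied unchanged elsewhere (no test
  leakage; asserted by recomputation in the tests). Zero-range features
  are dropped with a warning.
* **Grid search**: coarse pass over $C, g \in \{2^{-8}, 2^{-6}, \dots,
  2^{8}\}$, then fine passes over a ±2-octave neighborhood of the
  incumbent at step $2^{0.25}$, re-centred until the stratified 5-fold
  cross-validated accuracy improves by less than 0.1 percentage points —
  i.e. until accuracy is high and stable. Ties break toward the smallest
  $C$, then the smallest $g$. The search is deterministic given its seed.
* **CV subsampling**: within the search, cross-validation runs on a
  stratified subsample of 800 training projects (configurable). The QP
  solver's cost grows quadratically in $n$ and the $(C, g)$ ranking is
  stable at this size; the final model is always fitted on the full
  training partition.
* The $(C, g)$ optima reported for real national data ship as
  `svm_parameter_presets()` for users replaying comparable data; they are
  presets, not defaults.

The quadratic-program solver itself is LIBSVM via `e1071` — the package's
contribution is the protocol around it, which is what defines the method.

## Cohort aggregation

Effectiveness rates are percentages rounded half away from zero to two
decimals *at presentation only*; internal arithmetic is full precision.
Pooled rates are size-weighted means $\sum n_i r_i / \sum n_i$; rate
changes between periods are percentage-point differences. With the
published per-period inputs (4442 former / 3063 later projects) this
arithmetic reproduces all eight published pooled and difference values
exactly, which the test suite asserts. `study_cohort_rates()` ships those
inputs.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions
under which the whole chain is validated.

* **Phenology**: each parcel's within-year curve is a Gaussian-bump
  mixture on the 23-composite grid (base 0.15–0.25, one main peak of
  amplitude 0.40–0.60 centred at composites 11–15, width 2.5–3.5
  composites), with a double-logistic green-up/senescence mode as an
  alternative. Parcel-level inter-annual variability enters as annual
  mean offsets with SD 0.02 NDVI — part of the signal the variance
  indicator measures, not observation noise.
* **Calibrated injection**: intervention effects are injected so that the
  before/after contrasts downstream indicators measure equal the
  configured sizes *exactly* (a constant offset plus a narrow bump at
  each year's seasonal maximum solve the mean and maximum targets
  jointly; annual-mean deviations are rescaled to hit the variance
  target; added crop-cycle peaks carve their inter-peak valley deep
  enough to clear the prominence threshold). This orthogonality is what
  makes the zero-noise recovery test exact: every flag must equal its
  latent label for 100% of parcels.
* **Effect sizes** default to ±0.05 NDVI on the mean and maximum, ×0.5 /
  ×1.5 on the inter-annual SD, and +1 crop cycle — sizes a completed
  consolidation plausibly produces and the stated reference conditions
  for the recovery properties. Effects are fully expressed from the year
  after completion; an optional lag (typically 3 years, reflecting soil
  recovery) ramps them in linearly.
* **Corruption** adds Gaussian observation noise (default SD 0.02),
  missing composites (5%), bad reliability flags (3%) and marginal flags
  (20%), capped at 5 unusable composites per parcel-year: the emulated
  cohort represents the study sample, which by construction passed the
  data-quality screening. Screening rejection paths are exercised by
  constructed fixtures instead.
* **Labels**: each indicator's effectiveness probability is a logistic
  function of four designated factors (standardized, coefficient 2.0),
  with the intercept calibrated by root finding so the former cohort's
  expected rate matches its target (defaults: the published per-period
  rates). The former/later rate difference is realized as a calibrated
  *covariate shift*: the later cohort's factors move along the link
  directions (minimum-norm joint shift across the four links, iterated
  against the factors' physical bounds) until each later rate hits its
  target. A per-period intercept would be invisible to a classifier that
  sees only factors, making the predicted later rates systematically
  wrong; with the covariate shift the prediction stage faces a learnable
  problem, and predicted later rates land within a few points of the
  generating rates.
* **Determinism**: all randomness flows through one seeded generator per
  run (per-parcel corruption seeds are derived from the master seed), so
  identical seeds give bit-identical cohorts and pipeline outputs.

What the generator does *not* emulate: spatial autocorrelation between
parcels, realistic weather forcing, mixed land cover within parcels,
factor cross-correlations (factors are drawn independently within
plausible ranges), or any calibration of the NDVI distributions to a
specific country. Passing tests therefore show the *method* is computed
correctly and recovers known truth under controlled conditions — they do
not certify conclusions about any real consolidation programme.

## Problem sizes and runtime

The analysis scripts and the acceptance run use the study design sizes
(4442 former / 3063 later projects; 13-year, 299-composite records). The
recovery checks use 500-parcel cohorts and the peak-counter oracle
10,000 curves. With the CV subsample of 800 the four-indicator tuning
stage completes in a few minutes on one core; the indicator stage scales
linearly in parcels.

## Degenerate inputs and numerical choices

* A change of exactly zero is non-effective (strict inequalities).
* Population (divisor $N$) SD throughout, matching the descriptive
  $\sigma$; sample SD would only rescale both windows.
* Parcels whose completion year leaves an empty window are skipped and
  reported, not imputed.
* An all-unusable composite yields a missing parcel mean (never zero).
* A fully missing year is an error pointing back at screening.
* Injection warns and clips when an effect would leave the valid NDVI
  range (exactness is then void); the variance axis warns and skips when
  the before-window has zero inter-annual variability to scale.
* Peak plateaus count once, at their centre composite.
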