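# fcndvi

Evaluating and predicting the effectiveness of farmland-consolidation
(FC) projects on agricultural productivity from parcel-level NDVI time
series.

## The problem

Farmland consolidation — re-parcelling, irrigation and drainage works,
soil amelioration — is meant to raise farmland productivity. For projects
with known parcel boundaries, the outcome can be read from satellite
vegetation-index history: 16-day NDVI composites (23 per calendar year,
the MODIS MOD13Q1 cadence) before and after each project's completion
year. `fcndvi` is for researchers and land-administration analysts who
want that evaluation reproducible end to end: data-quality screening,
smoothing, change indicators, an improvement typology, machine-learning
prediction for projects completed too recently to evaluate directly, and
cohort-level reporting — plus a synthetic cohort generator with known
ground truth so every stage can be validated.

## The method

For a project completed in year *c* on a 2001–2013 record, the *before*
window is 2001..*c* and the *after* window *c*+1..2013. Four before/after
differences characterize the change in agricultural productivity:

| indicator | statistic | effective when |
|---|---|---|
| productivity level (PL) | MEN = mean NDVI over the window | MEN_change > 0 |
| productivity variation (PV) | SDN = SD of annual mean NDVI | SDN_change < 0 |
| productivity potential (PP) | MAN = maximum NDVI | MAN_change > 0 |
| multi-cropping index (MI) | PFN = seasonal peaks per year | PFN_change > 0 |

Parcels enter only if larger than 100 ha and, after masking pixels with
reliability flag > 1, no year has more than 5 missing composites; gaps
are interpolated and curves Savitzky–Golay smoothed (window 7, order 2).
The four effectiveness flags combine into seven improvement types
(EI, SI, PI, II, SPI, SII, OI). Projects completed near the record's end
are predicted instead of measured: one C-SVC per indicator with RBF
kernel k(x_i, x_j) = exp(−g‖x_i − x_j‖²) over 16 project factors,
trained on 2006–2009 completions, tuned by coarse-then-fine grid search
over (C, g) with stratified 5-fold cross-validation, evaluated on the
held-out 2010 cohort. Cohort rates are pooled as size-weighted means.

## Worked example

```r
library(fcndvi)

# a 300-project synthetic cohort with known injected effects
co <- generate_cohort(n_former = 300, n_later = 0, seed = 7)
cy <- setNames(co$projects$completion_year, co$projects$project_id)
ev <- evaluate_cohort_series(co$series, cy)
head(ev$indicators[, 1:5], 3)
#>   project_id  men_change   sdn_change  man_change pfn_change
#> 1     P00001 -0.04937231  0.007791059  0.03674235  0.6666667
#> 2     P00002 -0.05459190 -0.005648933  0.04109216  0.0000000
#> 3     P00003 -0.04893354  0.010413725 -0.03478300  0.0000000
```

Project `P00001` lost about 0.05 mean NDVI after consolidation
(ineffective on PL) but raised its seasonal maximum by 0.037 (effective
on PP) and gained two-thirds of a crop cycle per year (effective on MI).
Typing and aggregating the whole cohort:

```r
typed <- assign_types_cohort(ev$indicators)
effectiveness_rates(typed)[c("rate_effective_pl", "rate_EI", "rate_OI")]
#> rate_effective_pl rate_EI rate_OI
#>             63.00   63.00   11.00
```

63% of the projects upgraded their productivity level — identical to the
elementary-improvement (EI) rate, as the inclusive typology guarantees —
and 11% improved on all four axes (OI). Pooling per-period rates uses the
published arithmetic:

```r
pooled_rate(c(4442, 3063), c(62.02, 88.18))
#> [1] 72.7
```

The full chain (simulate → screen → smooth → indicators → typology →
SVM → report) is one call, or six narrated steps:

```r
run_pipeline(config = list(), outdir = "fcndvi_run", seed = 1)
```

```sh
Rscript analysis/01_simulate_cohort.R   # cohort tables -> results/
Rscript analysis/02_screen_and_smooth.R
Rscript analysis/03_indicators.R
Rscript analysis/04_typology.R
Rscript analysis/05_svm_prediction.R
Rscript analysis/06_cohort_report.R
```

See `vignettes/methods.Rmd` for the model, its assumptions, and every
tunable parameter.

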