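#' Seasonal phenology parameters
#'
#' Describes one parcel's within-year NDVI curve as a mixture of seasonal
#' crop-growth peaks on the 23-composite grid. Two shapes are available:
#' a Gaussian bump per crop cycle (default; peak count directly
#' controllable) and a double-logistic green-up/senescence curve per cycle,
#' the form commonly fitted to vegetation-index seasons.
#'
#' @param peaks_per_year number of crop cycles (seasonal peaks) per year.
#' @param base_ndvi off-season background NDVI.
#' @param amplitude peak height above `base_ndvi`; recycled to one value per
#'   peak. `base_ndvi + sum(amplitude)` must not exceed 1.
#' @param peak_center composite index (1-23) of each peak maximum; strictly
#'   increasing, one per peak.
#' @param peak_width peak scale in composites (Gaussian standard deviation,
#'   or half-duration for the double-logistic shape); recycled per peak.
#' @param trend_per_year linear NDVI drift per year, anchored at `ref_year`.
#' @param shape `"gaussian"` or `"double_logistic"`.
#' @param ref_year year at which the trend term is zero.
#' @return an object of class `phenology_params`.
#' @export
phenology_params <- function(peaks_per_year = 1, base_ndvi = 0.2,
                             amplitude = 0.5, peak_center = 13,
                             peak_width = 3, trend_per_year = 0,
                             shape = c("gaussian", "double_logistic"),
                             ref_year = 2001) {
  shape <- match.arg(shape)
  peaks_per_year <- as.integer(peaks_per_year)
  if (peaks_per_year < 1L) stop("`peaks_per_year` must be >= 1")
  amplitude <- rep_len(amplitude, peaks_per_year)
  peak_width <- rep_len(peak_width, peaks_per_year)
  if (length(peak_center) != peaks_per_year)
    stop("`peak_center` must supply one center per peak")
  if (any(diff(peak_center) <= 0))
    stop("peak centers must be strictly increasing within the year")
  if (any(peak_center < 1 | peak_center > 23))
    stop("peak centers must lie in the 1-23 composite range")
  if (any(amplitude < 0) || any(peak_width <= 0))
    stop("amplitudes must be >= 0 and widths > 0")
  if (base_ndvi + sum(amplitude) > NDVI_MAX + 1e-9)
    stop("base_ndvi + sum(amplitude) must not exceed 1.0")
  structure(list(peaks_per_year = peaks_per_year, base_ndvi = base_ndvi,
                 amplitude = amplitude, peak_center = peak_center,
                 peak_width = peak_width, trend_per_year = trend_per_year,
                 shape = shape, ref_year = ref_year),
            class = "phenology_params")
}

#' Deterministic within-year NDVI curve
#'
#' Evaluates the phenology model on the 23-composite grid of one calendar
#' year (no noise, no intervention effects).
#'
#' @param params a [phenology_params()] object.
#' @param year calendar year (enters only through the linear trend term).
#' @return numeric vector of 23 NDVI values in `[-0.2, 1.0]`.
#' @export
seasonal_curve <- function(params, year) {
  stopifnot(inherits(params, "phenology_params"))
  t <- 1:23
  v <- rep(params$base_ndvi + params$trend_per_year * (year - params$ref_year), 23L)
  for (k in seq_len(params$peaks_per_year)) {
    c_k <- params$peak_center[k]; w_k <- params$peak_width[k]
    bump <- if (params$shape == "gaussian") {
      exp(-((t - c_k) / w_k)^2 / 2)
    } else {
      # double-logistic: green-up at c-w, senescence at c+w, slope w/4;
      # rescaled so the maximum equals 1 at the center.
      r <- w_k / 4
      f <- 1 / (1 + exp(-(t - (c_k - w_k)) / r)) - 1 / (1 + exp(-(t - (c_k + w_k)) / r))
      fmax <- 1 / (1 + exp(-w_k / r)) - 1 / (1 + exp(w_k / r))
      f / fmax
    }
    v <- v + params$amplitude[k] * bump
  }
  clip_ndvi(v)
}

#' Intervention effect configuration
#'
#' The four effect axes mirror the four productivity-change indicators:
#' a shift of the post-consolidation mean NDVI (productivity level), a
#' multiplier on inter-annual variability (productivity variation), a shift
#' of the seasonal maximum (productivity potential), and a change in crop
#' cycles per year (multi-cropping). Effects are expressed from the year
#' after project completion; `lag_years` delays full expression, with a
#' linear ramp across the intervening years (soil typically needs about
#' three years to recover from consolidation engineering works).
#'
#' @param delta_level additive change in post-consolidation mean NDVI.
#' @param variance_factor multiplier (> 0) on the inter-annual standard
#'   deviation of annual mean NDVI after consolidation.
#' @param delta_max additive change in the post-consolidation seasonal
#'   NDVI maximum.
#' @param delta_peaks integer change in crop cycles per year (>= 0).
#' @param lag_years years after completion before the effect is fully
#'   expressed (default 0; 3 reflects the usual recovery lag).
#' @param new_peak_amp amplitude of any added crop-cycle peak.
#' @param new_peak_width width (composites) of any added peak.
#' @return an object of class `effect_config`.
#' @export
effect_config <- function(delta_level = 0, variance_factor = 1,
                          delta_max = 0, delta_peaks = 0L, lag_years = 0L,
                          new_peak_amp = 0.35, new_peak_width = 2.5) {
  if (variance_factor <= 0) stop("`variance_factor` must be > 0")
  delta_peaks <- as.integer(delta_peaks)
  if (delta_peaks < 0L)
    stop("peak removal (`delta_peaks` < 0) is not supported")
  lag_years <- as.integer(lag_years)
  if (lag_years < 0L) stop("`lag_years` must be >= 0")
  structure(list(delta_level = delta_level, variance_factor = variance_factor,
                 delta_max = delta_max, delta_peaks = delta_peaks,
                 lag_years = lag_years, new_peak_amp = new_peak_amp,
                 new_peak_width = new_peak_width),
            class = "effect_config")
}

is_neutral_effect <- function(effect) {
  effect$delta_level == 0 && effect$variance_factor == 1 &&
    effect$delta_max == 0 && effect$delta_peaks == 0L
}

#' Observation noise and data-quality corruption configuration
#'
#' Emulates the degradations real MODIS composites carry: additive
#' observation noise, cloud-driven missing composites, and poor pixel
#' reliability (flags 2-3) that the screening rules must reject.
#'
#' @param noise_sd standard deviation of additive Gaussian noise (NDVI).
#' @param missing_rate per-composite probability of a missing value.
#' @param bad_reliability_rate per-composite probability of an unusable
#'   reliability flag (2 or 3).
#' @param marginal_rate probability that a usable observation carries the
#'   marginal flag 1 rather than 0.
#' @param max_missing_per_year cap on unusable composites (missing or badly
#'   flagged) per calendar year; excess corruption is rolled back. `Inf`
#'   disables the cap. The cohort generator uses 5 to emulate a study
#'   sample pre-selected to satisfy the data-quality screening.
#' @param seed integer RNG seed; identical seeds give identical corruption.
#' @return an object of class `noise_config`.
#' @export
noise_config <- function(noise_sd = 0, missing_rate = 0,
                         bad_reliability_rate = 0, marginal_rate = 0.2,
                         max_missing_per_year = Inf, seed = 1L) {
  for (r in c(missing_rate, bad_reliability_rate, marginal_rate))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(list(noise_sd = noise_sd, missing_rate = missing_rate,
                 bad_reliability_rate = bad_reliability_rate,
                 marginal_rate = marginal_rate,
                 max_missing_per_year = max_missing_per_year,
                 seed = as.integer(seed)),
            class = "noise_config")
}
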