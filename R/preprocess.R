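#' Parcel-mean NDVI for one composite window
#'
#' Averages the NDVI of the pixels covering one parcel in one 16-day
#' composite, using only observations whose reliability flag is usable
#' (flag `<= max_reliability`).
#'
#' @param values numeric vector of pixel NDVI values (may contain `NA`).
#' @param flags integer reliability flags, same length (`NULL` = all good).
#' @param max_reliability largest usable flag (default 1: good + marginal).
#' @return the mean of usable pixels, or `NA` if none are usable.
#' @export
composite_parcel_mean <- function(values, flags = NULL, max_reliability = 1) {
  if (is.null(flags)) flags <- rep(0L, length(values))
  ok <- !is.na(values) & !is.na(flags) & flags <= max_reliability
  if (!any(ok)) return(NA_real_)
  mean(values[ok])
}

# Mask observations whose reliability flag exceeds the usable threshold;
# they count as missing from this point on.
mask_unreliable <- function(series, max_reliability = 1) {
  bad <- !is.na(series$reliability) & series$reliability > max_reliability
  series$ndvi[bad] <- NA_real_
  series$reliability[bad] <- NA_integer_
  series
}

#' Screen a parcel against the data-quality rules
#'
#' A parcel is kept only if (a) its area exceeds `min_area_ha` (small
#' parcels cover too few 250 m NDVI pixels for a stable mean) and (b) after
#' masking unreliable observations (flag `> max_reliability`), no year has
#' more than `max_missing` missing composites. The report distinguishes
#' gaps already present in the record (`TOO_MANY_MISSING`) from gaps
#' created by reliability masking (`UNRELIABLE`).
#'
#' @param series an [ndvi_series()].
#' @param min_area_ha area threshold in hectares (strict inequality).
#' @param max_missing largest tolerable number of missing composites in any
#'   single year, counted after reliability masking.
#' @param max_reliability largest usable reliability flag.
#' @return a list of class `screening_report`: `parcel_id`, `kept`,
#'   `reasons` (character vector, empty iff kept), and per-year missing
#'   counts.
#' @export
screen_parcel <- function(series, min_area_ha = 100, max_missing = 5,
                          max_reliability = 1) {
  stopifnot(inherits(series, "ndvi_series"))
  masked <- mask_unreliable(series, max_reliability)
  miss_raw <- rowSums(is.na(series$ndvi))
  miss <- rowSums(is.na(masked$ndvi))
  reasons <- character(0)
  if (series$area_ha <= min_area_ha) reasons <- c(reasons, "AREA_TOO_SMALL")
  if (any(miss_raw > max_missing)) reasons <- c(reasons, "TOO_MANY_MISSING")
  if (any(miss > max_missing & miss_raw <= max_missing))
    reasons <- c(reasons, "UNRELIABLE")
  structure(list(parcel_id = series$parcel_id,
                 kept = length(reasons) == 0,
                 reasons = reasons,
                 missing_per_year = stats::setNames(miss, series$years)),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> parcel %s: %s%s\n", x$parcel_id,
              if (x$kept) "kept" else "rejected",
              if (x$kept) "" else paste0(" (", paste(x$reasons, collapse = ", "), ")")))
  invisible(x)
}

#' Fill missing composites by linear interpolation
#'
#' Interpolates gaps linearly over the concatenated multi-year composite
#' index (so a gap at the year boundary borrows from the adjacent year);
#' leading/trailing gaps take the nearest observed value. Intended for
#' records that already passed [screen_parcel()]; reliability masking is
#' applied first.
#'
#' @param series an [ndvi_series()].
#' @param max_reliability largest usable reliability flag.
#' @return the gap-free [ndvi_series()].
#' @export
fill_missing <- function(series, max_reliability = 1) {
  stopifnot(inherits(series, "ndvi_series"))
  series <- mask_unreliable(series, max_reliability)
  v <- as.vector(t(series$ndvi))
  if (all(is.na(v))) stop("series has no usable observations")
  full_year_gap <- rowSums(!is.na(series$ndvi)) == 0
  if (any(full_year_gap))
    stop("year(s) ", paste(series$years[full_year_gap], collapse = ", "),
         " fully missing; such parcels should be rejected by screen_parcel()")
  if (anyNA(v)) {
    idx <- seq_along(v)
    v <- stats::approx(idx[!is.na(v)], v[!is.na(v)], xout = idx, rule = 2)$y
  }
  series$ndvi <- matrix(v, nrow = length(series$years), ncol = 23L,
                        byrow = TRUE, dimnames = dimnames(series$ndvi))
  series$reliability[is.na(series$reliability)] <- 0L
  series
}

#' Savitzky-Golay smoothing of a parcel record
#'
#' Applies a Savitzky-Golay least-squares polynomial filter along the
#' concatenated multi-year composite sequence (avoiding year-boundary edge
#' artifacts), then splits the result back into per-year 23-composite
#' curves. The filter preserves polynomials up to `polyorder` exactly,
#' including at the record ends.
#'
#' @param series a gap-free [ndvi_series()] (run [fill_missing()] first).
#' @param window odd filter window length in composites.
#' @param polyorder polynomial order (`< window`).
#' @return numeric matrix of smoothed annual curves, years by 23
#'   composites, clipped to `[-0.2, 1.0]`.
#' @export
sg_smooth <- function(series, window = 7, polyorder = 2) {
  stopifnot(inherits(series, "ndvi_series"))
  if (window %% 2 != 1) stop("`window` must be odd")
  if (polyorder >= window) stop("`polyorder` must be smaller than `window`")
  v <- as.vector(t(series$ndvi))
  if (anyNA(v)) stop("sg_smooth() requires a gap-free series; run fill_missing() first")
  if (window >= length(v)) stop("`window` must be shorter than the series")
  sm <- signal::sgolayfilt(v, p = polyorder, n = window)
  matrix(clip_ndvi(sm), nrow = length(series$years), ncol = 23L, byrow = TRUE,
         dimnames = list(series$years, 1:23))
}

#' Smoothed annual curves of a parcel collection, in long format
#'
#' Gap-fills and Savitzky-Golay smooths every (already screened) parcel
#' and stacks the per-year curves into one long table, ready for CSV
#' export or downstream indicator extraction outside R.
#'
#' @param series_list named list of [ndvi_series()] objects.
#' @param window,polyorder smoothing parameters, see [sg_smooth()].
#' @param max_reliability largest usable reliability flag.
#' @return data.frame with columns `parcel_id`, `year`, `composite`,
#'   `ndvi_smooth`.
#' @export
smooth_curves_long <- function(series_list, window = 7, polyorder = 2,
                               max_reliability = 1) {
  if (inherits(series_list, "ndvi_series")) series_list <- list(series_list)
  do.call(rbind, lapply(series_list, function(s) {
    sm <- sg_smooth(fill_missing(s, max_reliability), window, polyorder)
    data.frame(parcel_id = s$parcel_id,
               year = rep(as.integer(rownames(sm)), each = 23L),
               composite = rep(1:23, times = nrow(sm)),
               ndvi_smooth = as.vector(t(sm)))
  }))
}

#' Full preprocessing of one parcel
#'
#' Convenience wrapper: reliability masking, screening, gap filling and
#' Savitzky-Golay smoothing in one call.
#'
#' @param series an [ndvi_series()].
#' @param min_area_ha,max_missing,max_reliability screening thresholds, see
#'   [screen_parcel()].
#' @param window,polyorder smoothing parameters, see [sg_smooth()].
#' @return list with `report` (the [screen_parcel()] result) and, when the
#'   parcel is kept, `raw` (gap-filled annual-curve matrix) and `smooth`
#'   (Savitzky-Golay smoothed matrix); rejected parcels carry `NULL`
#'   curves.
#' @export
preprocess_parcel <- function(series, min_area_ha = 100, max_missing = 5,
                              max_reliability = 1, window = 7, polyorder = 2) {
  report <- screen_parcel(series, min_area_ha, max_missing, max_reliability)
  if (!report$kept)
    return(list(report = report, raw = NULL, smooth = NULL))
  filled <- fill_missing(series, max_reliability)
  list(report = report,
       raw = filled$ndvi,
       smooth = sg_smooth(filled, window, polyorder))
}
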