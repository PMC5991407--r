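#' Before/after analysis windows for a project
#'
#' Splits the available record at the project completion year: the "before"
#' window runs from the first year through the completion year inclusive
#' (consolidation works finish within the completion year, so that year's
#' crop still reflects the pre-project state), the "after" window from the
#' following year to the end of the record. A project completed in 2007 on
#' a 2001-2013 record thus compares 2001-2007 against 2008-2013.
#'
#' @param years integer vector of available record years (contiguous).
#' @param completion_year project completion year; must leave both windows
#'   non-empty.
#' @return object of class `window_pair`: list with integer vectors
#'   `before` and `after`.
#' @export
split_windows <- function(years, completion_year) {
  years <- sort(as.integer(years))
  completion_year <- as.integer(completion_year)
  if (completion_year < min(years) || completion_year >= max(years))
    stop("completion year ", completion_year, " leaves an empty window on a ",
         min(years), "-", max(years), " record")
  structure(list(before = years[years <= completion_year],
                 after = years[years > completion_year]),
            class = "window_pair")
}

# Extract window rows from an annual-curve matrix (years x 23), by rowname.
window_rows <- function(curves, yrs) {
  if (length(yrs) == 0) stop("empty analysis window")
  i <- match(as.character(yrs), rownames(curves))
  if (anyNA(i)) stop("curves do not cover years ",
                     paste(yrs[is.na(i)], collapse = ", "))
  curves[i, , drop = FALSE]
}

#' Change in mean NDVI (productivity level)
#'
#' Mean NDVI over all composites of the after window minus the same over
#' the before window. A positive value marks an effective project on
#' upgrading the productivity level.
#'
#' @param curves numeric matrix of annual curves, years (rownames) by 23
#'   composites.
#' @param windows a [split_windows()] result.
#' @return the mean-NDVI change (NDVI units).
#' @export
men_change <- function(curves, windows) {
  mean(window_rows(curves, windows$after)) -
    mean(window_rows(curves, windows$before))
}

#' Change in NDVI standard deviation (productivity variation)
#'
#' Population standard deviation of NDVI in the after window minus the
#' before window; a negative value marks reduced year-to-year productivity
#' fluctuation. The default `"annual_mean"` mode takes the SD of per-year
#' mean NDVI across the window years (inter-annual yield fluctuation);
#' `"pooled"` takes the SD over all composites in the window.
#'
#' @inheritParams men_change
#' @param mode `"annual_mean"` (default) or `"pooled"`.
#' @return the SD change (NDVI units).
#' @export
sdn_change <- function(curves, windows, mode = c("annual_mean", "pooled")) {
  mode <- match.arg(mode)
  b <- window_rows(curves, windows$before)
  a <- window_rows(curves, windows$after)
  if (mode == "annual_mean") {
    if (nrow(b) < 2 || nrow(a) < 2)
      stop("annual_mean mode needs at least 2 years per window")
    sd_pop(rowMeans(a)) - sd_pop(rowMeans(b))
  } else {
    sd_pop(as.vector(a)) - sd_pop(as.vector(b))
  }
}

#' Change in maximum NDVI (productivity potential)
#'
#' Maximum NDVI over all composites of the after window minus the before
#' window; a positive value marks improved productivity potential.
#'
#' @inheritParams men_change
#' @return the maximum-NDVI change (NDVI units).
#' @export
man_change <- function(curves, windows) {
  max(window_rows(curves, windows$after)) -
    max(window_rows(curves, windows$before))
}

#' Change in NDVI peak frequency (multi-cropping index)
#'
#' Mean annual seasonal-peak count over the after window minus the before
#' window; a positive value marks an increased multi-cropping index.
#'
#' @inheritParams men_change
#' @param min_ndvi,min_prominence,min_separation peak-detection thresholds,
#'   see [find_seasonal_peaks()].
#' @return the peak-frequency change (crop cycles per year).
#' @export
pfn_change <- function(curves, windows, min_ndvi = 0.3, min_prominence = 0.1,
                       min_separation = 3) {
  count_rows <- function(m) vapply(seq_len(nrow(m)), function(i)
    peak_frequency(m[i, ], min_ndvi, min_prominence, min_separation),
    numeric(1))
  mean(count_rows(window_rows(curves, windows$after))) -
    mean(count_rows(window_rows(curves, windows$before)))
}

#' Four productivity-change indicators and effectiveness flags
#'
#' Computes the full indicator set for one project on a common before/after
#' split: mean, standard-deviation, maximum and peak-frequency changes of
#' NDVI, and the four strict-inequality effectiveness flags (a change of
#' exactly zero is non-effective). Peak counting runs on the smoothed
#' curves (peak detection needs denoised shapes); the moment indicators
#' default to the screened-but-unsmoothed curves.
#'
#' @param raw_curves gap-filled annual-curve matrix (years x 23).
#' @param smooth_curves Savitzky-Golay smoothed matrix; defaults to
#'   `raw_curves`.
#' @param completion_year project completion year.
#' @param sdn_mode see [sdn_change()].
#' @param use_smoothed_moments if `TRUE`, compute the mean/SD/max
#'   indicators on the smoothed curves as well.
#' @param min_ndvi,min_prominence,min_separation peak-detection thresholds.
#' @return one-row data.frame: `men_change`, `sdn_change`, `man_change`,
#'   `pfn_change`, `effective_pl`, `effective_pv`, `effective_pp`,
#'   `effective_mi`.
#' @export
evaluate_project <- function(raw_curves, smooth_curves = raw_curves,
                             completion_year,
                             sdn_mode = c("annual_mean", "pooled"),
                             use_smoothed_moments = FALSE,
                             min_ndvi = 0.3, min_prominence = 0.1,
                             min_separation = 3) {
  sdn_mode <- match.arg(sdn_mode)
  years <- as.integer(rownames(raw_curves))
  w <- split_windows(years, completion_year)
  mom <- if (use_smoothed_moments) smooth_curves else raw_curves
  men <- men_change(mom, w)
  sdn <- sdn_change(mom, w, mode = sdn_mode)
  man <- man_change(mom, w)
  pfn <- pfn_change(smooth_curves, w, min_ndvi, min_prominence, min_separation)
  data.frame(men_change = men, sdn_change = sdn, man_change = man,
             pfn_change = pfn,
             effective_pl = men > 0, effective_pv = sdn < 0,
             effective_pp = man > 0, effective_mi = pfn > 0)
}

#' Evaluate every parcel of a cohort
#'
#' Runs screening, gap filling, smoothing and indicator extraction over a
#' collection of parcel series. Parcels rejected by screening, or whose
#' completion year leaves an empty window, are skipped and reported.
#'
#' @param series_list named list of [ndvi_series()] objects.
#' @param completion_years named integer vector (or single value) of
#'   completion years, keyed by parcel id.
#' @param min_area_ha,max_missing,max_reliability screening thresholds.
#' @param window,polyorder Savitzky-Golay parameters.
#' @param ... indicator options passed to [evaluate_project()].
#' @return list with `indicators` (data.frame, one row per evaluated
#'   parcel, keyed by `project_id`) and `screening` (data.frame with
#'   `project_id`, `kept`, `reasons`).
#' @export
evaluate_cohort_series <- function(series_list, completion_years,
                                   min_area_ha = 100, max_missing = 5,
                                   max_reliability = 1, window = 7,
                                   polyorder = 2, ...) {
  if (length(completion_years) == 1 && is.null(names(completion_years)))
    completion_years <- stats::setNames(rep(completion_years, length(series_list)),
                                        names(series_list))
  rows <- vector("list", length(series_list))
  screen <- vector("list", length(series_list))
  for (i in seq_along(series_list)) {
    s <- series_list[[i]]
    id <- s$parcel_id
    pp <- preprocess_parcel(s, min_area_ha, max_missing, max_reliability,
                            window, polyorder)
    screen[[i]] <- data.frame(project_id = id, kept = pp$report$kept,
                              reasons = paste(pp$report$reasons, collapse = ";"))
    if (!pp$report$kept) next
    cy <- completion_years[[id]]
    if (is.null(cy) || is.na(cy)) next
    if (cy >= max(s$years)) next  # no post-completion record to evaluate
    ind <- evaluate_project(pp$raw, pp$smooth, cy, ...)
    rows[[i]] <- cbind(data.frame(project_id = id), ind)
  }
  list(indicators = do.call(rbind, rows[!vapply(rows, is.null, logical(1))]),
       screening = do.call(rbind, screen))
}
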