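#' Parcel NDVI composite series
#'
#' Container for one parcel's 16-day NDVI composite record: a year-by-23
#' matrix of NDVI values (23 composites per calendar year, MOD13Q1-style)
#' plus a matching matrix of pixel-reliability flags. Missing observations
#' are `NA` in both matrices. Reliability follows the MODIS convention:
#' 0 = good, 1 = marginal, 2 = snow/ice, 3 = cloudy; flags above the
#' usability threshold (default 1) are masked out before analysis.
#'
#' @param parcel_id character scalar identifying the parcel.
#' @param area_ha parcel area in hectares (must be positive).
#' @param years integer vector of contiguous calendar years covered.
#' @param ndvi numeric matrix, `length(years)` rows by 23 columns, values in
#'   `[-0.2, 1.0]` or `NA`.
#' @param reliability integer matrix of the same shape; `NA` where the
#'   observation is missing.
#' @return an object of class `ndvi_series`.
#' @export
ndvi_series <- function(parcel_id, area_ha, years, ndvi,
                        reliability = NULL) {
  years <- as.integer(years)
  if (length(years) == 0 || any(diff(years) != 1L))
    stop("`years` must be a contiguous sequence of calendar years")
  if (!is.matrix(ndvi)) ndvi <- matrix(ndvi, nrow = length(years), byrow = TRUE)
  if (nrow(ndvi) != length(years) || ncol(ndvi) != 23L)
    stop("`ndvi` must be a length(years) x 23 matrix")
  if (!is.numeric(area_ha) || length(area_ha) != 1 || area_ha <= 0)
    stop("`area_ha` must be a positive scalar")
  rng <- range(ndvi, na.rm = TRUE)
  if (any(is.finite(rng)) && (rng[1] < NDVI_MIN - 1e-9 || rng[2] > NDVI_MAX + 1e-9))
    stop("NDVI values outside [-0.2, 1.0]")
  if (is.null(reliability)) {
    reliability <- matrix(0L, nrow(ndvi), 23L)
    reliability[is.na(ndvi)] <- NA_integer_
  }
  if (!all(dim(reliability) == dim(ndvi)))
    stop("`reliability` must have the same shape as `ndvi`")
  dimnames(ndvi) <- dimnames(reliability) <- list(years, 1:23)
  structure(
    list(parcel_id = as.character(parcel_id), area_ha = area_ha,
         years = years, ndvi = ndvi,
         reliability = matrix(as.integer(reliability), nrow(ndvi), 23L,
                              dimnames = dimnames(ndvi))),
    class = "ndvi_series")
}

#' @export
print.ndvi_series <- function(x, ...) {
  n_miss <- sum(is.na(x$ndvi))
  cat(sprintf("<ndvi_series> parcel %s, %.1f ha, years %d-%d, %d/%d missing\n",
              x$parcel_id, x$area_ha, min(x$years), max(x$years),
              n_miss, length(x$ndvi)))
  invisible(x)
}

#' Convert a parcel series to the long table dialect
#'
#' @param series an [ndvi_series()].
#' @return data.frame with columns `parcel_id`, `year`, `composite`, `ndvi`,
#'   `reliability` (one row per year-composite slot, missing values as `NA`).
#' @export
series_to_long <- function(series) {
  stopifnot(inherits(series, "ndvi_series"))
  data.frame(
    parcel_id = series$parcel_id,
    year = rep(series$years, each = 23L),
    composite = rep(1:23, times = length(series$years)),
    ndvi = as.vector(t(series$ndvi)),
    reliability = as.vector(t(series$reliability)))
}

#' Build parcel series from a long NDVI table
#'
#' Accepts the long dialect written by [write_series_csv()] and also raw
#' MOD13Q1 integer NDVI (scale factor 0.0001), auto-detected whenever values
#' fall outside `[-1.5, 1.5]` and rescaled.
#'
#' @param df data.frame with columns `parcel_id`, `year`, `composite`,
#'   `ndvi`, and optionally `reliability`.
#' @param areas named numeric vector of parcel areas (ha) keyed by parcel id;
#'   parcels absent from `areas` get `default_area_ha`.
#' @param default_area_ha fallback area.
#' @return named list of [ndvi_series()] objects.
#' @export
long_to_series <- function(df, areas = NULL, default_area_ha = 1000) {
  need <- c("parcel_id", "year", "composite", "ndvi")
  if (!all(need %in% names(df)))
    stop("long table must have columns ", paste(need, collapse = ", "))
  if (is.null(df$reliability)) df$reliability <- ifelse(is.na(df$ndvi), NA, 0L)
  mx <- suppressWarnings(max(abs(df$ndvi), na.rm = TRUE))
  if (is.finite(mx) && mx > 1.5) df$ndvi <- df$ndvi * 1e-4
  out <- lapply(split(df, df$parcel_id), function(d) {
    years <- sort(unique(d$year))
    ndvi <- matrix(NA_real_, length(years), 23L)
    rel <- matrix(NA_integer_, length(years), 23L)
    i <- cbind(match(d$year, years), d$composite)
    ndvi[i] <- d$ndvi
    rel[i] <- d$reliability
    id <- d$parcel_id[1]
    area <- if (!is.null(areas) && id %in% names(areas)) areas[[id]] else default_area_ha
    ndvi_series(id, area, years, ndvi, rel)
  })
  out[order(names(out))]
}

#' Write / read parcel series as long-format CSV
#'
#' @param series_list list of [ndvi_series()] objects.
#' @param path CSV path.
#' @return `read_series_csv` returns a named list of series.
#' @export
write_series_csv <- function(series_list, path) {
  if (inherits(series_list, "ndvi_series")) series_list <- list(series_list)
  long <- do.call(rbind, lapply(series_list, series_to_long))
  utils::write.csv(long, path, row.names = FALSE)
  areas <- vapply(series_list, `[[`, numeric(1), "area_ha")
  names(areas) <- vapply(series_list, `[[`, character(1), "parcel_id")
  utils::write.csv(data.frame(parcel_id = names(areas), area_ha = areas),
                   sub("\\.csv$", "_areas.csv", path), row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @param path CSV path written by `write_series_csv`.
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path)
  areas_path <- sub("\\.csv$", "_areas.csv", path)
  areas <- NULL
  if (file.exists(areas_path)) {
    a <- utils::read.csv(areas_path)
    areas <- stats::setNames(a$area_ha, a$parcel_id)
  }
  long_to_series(df, areas = areas)
}
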