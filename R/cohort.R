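#' Factor-to-effectiveness model for synthetic cohorts
#'
#' Declares how the sixteen project-level factors drive the probability
#' that a project is effective on each of the four productivity indicators
#' (productivity level PL, productivity variation PV, productivity
#' potential PP, multi-cropping index MI), and the effect sizes injected
#' into parcel NDVI once the latent label is drawn.
#'
#' Each indicator has a monotone-logistic link over four designated
#' factors (standardized over the cohort, signed coefficients), with the
#' intercept calibrated per period so that the expected effectiveness rate
#' matches `target_former` / `target_later`. The default targets are the
#' per-period rates of the reference national study (former cohort
#' 62.02/55.02/53.53/33.30%, later cohort 88.18/66.41/81.55/3.59%).
#'
#' @param coef coefficient magnitude on the standardized-factor scale.
#' @param target_former,target_later named vectors of target effectiveness
#'   rates (proportions in `[0, 1]`) for the two cohorts, names
#'   `pl, pv, pp, mi`.
#' @param constant_prob optional named vector; indicators listed here get a
#'   constant effectiveness probability instead of the factor link (useful
#'   for degenerate ground-truth checks).
#' @param delta_level_mag,delta_max_mag NDVI effect magnitudes injected for
#'   the PL and PP axes (sign follows the label).
#' @param variance_effective,variance_ineffective inter-annual variance
#'   multipliers injected for effective / ineffective PV labels.
#' @param peaks_effective extra crop cycles injected for an effective MI
#'   label (ineffective projects get no peak change).
#' @param lag_years effect expression lag passed to [effect_config()].
#' @return an object of class `fc_effect_model`.
#' @export
effect_model <- function(coef = 2.0,
                         target_former = c(pl = 0.6202, pv = 0.5502,
                                           pp = 0.5353, mi = 0.3330),
                         target_later = c(pl = 0.8818, pv = 0.6641,
                                          pp = 0.8155, mi = 0.0359),
                         constant_prob = NULL,
                         delta_level_mag = 0.05, delta_max_mag = 0.05,
                         variance_effective = 0.5,
                         variance_ineffective = 1.5,
                         peaks_effective = 1L, lag_years = 0L) {
  links <- list(
    pl = c(investment_intensity = 1, precipitation = 1,
           gdp_per_capita = 1, slope = -1),
    pv = c(precipitation = 1, crop_disaster_rate = -1,
           investment_intensity = 1, road_density = 1),
    pp = c(investment_intensity = 1, elevation = -1,
           precipitation = 1, plot_size = 1),
    mi = c(regional_mci = 1, precipitation = 1,
           urbanization_rate = -1, dist_county_center = -1))
  links <- lapply(links, function(s) s * coef)
  structure(list(links = links,
                 target_former = target_former, target_later = target_later,
                 constant_prob = constant_prob,
                 delta_level_mag = delta_level_mag,
                 delta_max_mag = delta_max_mag,
                 variance_effective = variance_effective,
                 variance_ineffective = variance_ineffective,
                 peaks_effective = as.integer(peaks_effective),
                 lag_years = as.integer(lag_years)),
            class = "fc_effect_model")
}

# Independent draws within plausible ranges for the sixteen project-level
# factors (units follow the national-study factor table).
draw_factors <- function(n) {
  data.frame(
    elevation = exp(stats::rnorm(n, 5.5, 1.0)),              # m
    slope = stats::runif(n, 0, 15),                          # degrees
    precipitation = stats::runif(n, 400, 1800),              # mm/yr
    crop_disaster_rate = stats::runif(n, 0, 40),             # %
    gdp_per_capita = exp(stats::rnorm(n, 8.3, 0.6)),         # USD/person
    urbanization_rate = stats::runif(n, 20, 80),             # %
    population_density = exp(stats::rnorm(n, 5.8, 0.8)),     # person/km2
    road_density = stats::runif(n, 0.2, 3),                  # km/km2
    farmland_per_capita = stats::runif(n, 0.03, 0.5),        # ha
    farmland_quality_grade = sample(1:15, n, replace = TRUE),# grade
    regional_mci = stats::runif(n, 100, 250),                # %
    farmland_reserve_area = exp(stats::rnorm(n, 7.5, 1.0)),  # ha
    plot_size = pmax(110, exp(stats::rnorm(n, 6.2, 0.7))),   # ha
    shape_index = stats::runif(n, 1, 3),                     # -
    investment_intensity = exp(stats::rnorm(n, 8.5, 0.5)),   # USD/ha
    dist_county_center = stats::runif(n, 1, 80))             # km
}

#' Names of the sixteen project factor columns
#' @return character vector of factor column names.
#' @export
factor_names <- function() names(draw_factors(1))

# Re-impose physical bounds after covariate shifts.
clamp_factors <- function(projects) {
  nonneg <- c("elevation", "slope", "precipitation", "gdp_per_capita",
              "population_density", "road_density", "farmland_per_capita",
              "regional_mci", "farmland_reserve_area", "investment_intensity",
              "dist_county_center")
  for (f in nonneg) projects[[f]] <- pmax(projects[[f]], 0)
  for (f in c("crop_disaster_rate", "urbanization_rate"))
    projects[[f]] <- pmin(pmax(projects[[f]], 0), 100)
  projects$plot_size <- pmax(projects$plot_size, 101)
  projects$shape_index <- pmax(projects$shape_index, 1)
  projects
}

# Allocate completion years deterministically: the former cohort keeps the
# study's 2982:1460 split between 2006-2009 and 2010, the later cohort is
# spread evenly over 2011-2013.
allocate_completion_years <- function(n_former, n_later) {
  former <- integer(0)
  if (n_former > 0) {
    n2010 <- round(n_former * 1460 / 4442)
    n_rest <- n_former - n2010
    per <- rep(n_rest %/% 4, 4)
    per[seq_len(n_rest %% 4)] <- per[seq_len(n_rest %% 4)] + 1
    former <- sample(rep(c(2006:2009, 2010), c(per, n2010)))
  }
  later <- integer(0)
  if (n_later > 0) {
    per <- rep(n_later %/% 3, 3)
    per[seq_len(n_later %% 3)] <- per[seq_len(n_later %% 3)] + 1
    later <- sample(rep(2011:2013, per))
  }
  c(former, later)
}

# Calibrate the logistic intercept so that mean(plogis(b0 + s)) hits the
# target rate on the realized linear predictors.
calibrate_intercept <- function(s, target) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  stats::uniroot(function(b0) mean(stats::plogis(b0 + s)) - target,
                 lower = -50, upper = 50, tol = 1e-10)$root
}

#' Generate a synthetic farmland-consolidation cohort
#'
#' Builds a full study cohort with known ground truth: a project table
#' (completion years, areas, group codes, sixteen factors), parcel NDVI
#' composite series with exactly calibrated injected effects, and the
#' latent per-indicator effectiveness labels the effects realize. The
#' default sizes reproduce the reference study design: 4442 "former"
#' projects completed 2006-2010 (with the 2982/1460 split between
#' 2006-2009 and 2010) and 3063 "later" projects completed 2011-2013.
#'
#' @param n_former,n_later cohort sizes for the two periods.
#' @param model an [effect_model()].
#' @param noise a [noise_config()] applied to every generated series
#'   (per-parcel seeds are derived from `seed`).
#' @param seed master RNG seed; identical seeds give identical cohorts.
#' @param years calendar years covered by each parcel record.
#' @param series which parcels get NDVI series: `"former"` (default; later
#'   projects have too little post-completion record to evaluate),
#'   `"all"`, or `"none"`.
#' @param year_sd standard deviation (NDVI) of parcel-level inter-annual
#'   fluctuations of the annual mean; these are part of the signal the
#'   variance indicator measures, not observation noise.
#' @return an object of class `fc_cohort`: list with elements `projects`
#'   (data.frame), `series` (named list of [ndvi_series()]), and `truth`
#'   (data.frame of latent labels `eff_pl`, `eff_pv`, `eff_pp`, `eff_mi`).
#' @export
generate_cohort <- function(n_former = 4442, n_later = 3063,
                            model = effect_model(),
                            noise = noise_config(noise_sd = 0.02,
                                                 missing_rate = 0.05,
                                                 bad_reliability_rate = 0.03,
                                                 marginal_rate = 0.2,
                                                 max_missing_per_year = 5),
                            seed = 1L, years = 2001:2013,
                            series = c("former", "all", "none"),
                            year_sd = 0.02) {
  series <- match.arg(series)
  stopifnot(n_former >= 0, n_later >= 0, inherits(model, "fc_effect_model"))
  n <- n_former + n_later
  if (n == 0) stop("empty cohort")
  with_seed(seed, {
    projects <- data.frame(
      project_id = sprintf("P%05d", seq_len(n)),
      period = rep(c("former", "later"), c(n_former, n_later)),
      completion_year = allocate_completion_years(n_former, n_later),
      group = sample(1:30, n, replace = TRUE))
    projects <- cbind(projects, draw_factors(n))

    # Latent effectiveness labels from the factor links. The probability of
    # each label is a logistic function of the factors only -- no hidden
    # period term -- so the prediction stage faces a learnable problem.
    # Period differences in effectiveness rates are realized by shifting
    # the later cohort's factor distribution along the link directions
    # (minimum-norm joint shift over the four links), calibrated so each
    # indicator's expected later rate hits its target.
    fn <- factor_names()
    inds <- c("pl", "pv", "pp", "mi")
    cp <- model$constant_prob
    link_inds <- inds[!inds %in% names(cp)]
    f_idx <- projects$period == "former"
    l_idx <- !f_idx
    ref_idx <- if (any(f_idx)) f_idx else l_idx
    mu <- colMeans(projects[ref_idx, fn])
    sdv <- apply(projects[ref_idx, fn], 2, stats::sd)
    sdv[sdv == 0] <- 1
    L <- t(vapply(link_inds, function(ind) {
      row <- stats::setNames(numeric(length(fn)), fn)
      row[names(model$links[[ind]])] <- model$links[[ind]]
      row
    }, numeric(length(fn))))
    zmat <- function() sweep(sweep(as.matrix(projects[fn]), 2, mu), 2, sdv, "/")
    S <- zmat() %*% t(L)
    b0 <- vapply(link_inds, function(ind) {
      tgt <- if (any(f_idx)) model$target_former[[ind]]
             else model$target_later[[ind]]
      calibrate_intercept(S[ref_idx, ind], tgt)
    }, numeric(1))
    if (any(f_idx) && any(l_idx) && length(link_inds)) {
      # iterate because clamping shifted factors to their physical bounds
      # (slope >= 0, rates in [0, 100], ...) perturbs the calibration
      for (it in 1:3) {
        delta <- vapply(link_inds, function(ind)
          stats::uniroot(function(d)
            mean(stats::plogis(b0[ind] + S[l_idx, ind] + d)) -
              model$target_later[[ind]],
            lower = -60, upper = 60, tol = 1e-10)$root, numeric(1))
        if (max(abs(delta)) < 1e-4) break
        u <- drop(t(L) %*% solve(L %*% t(L), delta)) # z-scale factor shift
        projects[l_idx, fn] <- sweep(projects[l_idx, fn], 2, u * sdv, "+")
        projects <- clamp_factors(projects)
        S <- zmat() %*% t(L)
      }
    }
    projects$area_ha <- pmax(projects$plot_size, 101)
    truth <- data.frame(project_id = projects$project_id,
                        period = projects$period,
                        completion_year = projects$completion_year)
    for (ind in inds) {
      p <- if (ind %in% names(cp)) rep(cp[[ind]], n)
           else stats::plogis(b0[ind] + S[, ind])
      truth[[paste0("prob_", ind)]] <- p
      truth[[paste0("eff_", ind)]] <- stats::runif(n) < p
    }

    make_series <- series != "none"
    which_series <- if (series == "former") which(projects$period == "former")
                    else if (series == "all") seq_len(n) else integer(0)
    ser <- list()
    if (make_series && length(which_series)) {
      # per-parcel phenology and inter-annual offsets drawn up-front so the
      # RNG stream is independent of the injection arithmetic
      ny <- length(years)
      base <- stats::runif(n, 0.15, 0.25)
      amp <- stats::runif(n, 0.40, 0.60)
      ctr <- sample(11:15, n, replace = TRUE)
      wid <- stats::runif(n, 2.5, 3.5)
      offs <- matrix(stats::rnorm(n * ny, 0, year_sd), n, ny)
      ser <- vector("list", length(which_series))
      for (k in seq_along(which_series)) {
        i <- which_series[k]
        ph <- phenology_params(peaks_per_year = 1, base_ndvi = base[i],
                               amplitude = amp[i], peak_center = ctr[i],
                               peak_width = wid[i])
        M <- t(vapply(seq_len(ny),
                      function(j) clip_ndvi(seasonal_curve(ph, years[j]) + offs[i, j]),
                      numeric(23)))
        s_i <- ndvi_series(projects$project_id[i], projects$area_ha[i], years, M)
        eff <- effect_config(
          delta_level = ifelse(truth$eff_pl[i], 1, -1) * model$delta_level_mag,
          variance_factor = ifelse(truth$eff_pv[i], model$variance_effective,
                                   model$variance_ineffective),
          delta_max = ifelse(truth$eff_pp[i], 1, -1) * model$delta_max_mag,
          delta_peaks = ifelse(truth$eff_mi[i], model$peaks_effective, 0L),
          lag_years = model$lag_years)
        if (projects$completion_year[i] < max(years))
          s_i <- inject_effect(s_i, projects$completion_year[i], eff)
        pn <- noise
        pn$seed <- derive_seed(noise$seed, i)
        ser[[k]] <- corrupt_series(s_i, pn)
      }
      names(ser) <- projects$project_id[which_series]
    }
    structure(list(projects = projects, series = ser, truth = truth),
              class = "fc_cohort")
  })
}

#' @export
print.fc_cohort <- function(x, ...) {
  cat(sprintf("<fc_cohort> %d projects (%d former, %d later), %d parcel series\n",
              nrow(x$projects), sum(x$projects$period == "former"),
              sum(x$projects$period == "later"), length(x$series)))
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' Writes `projects.csv`, `ground_truth.csv` and (optionally) the parcel
#' series in long format as `series.csv` (+ `series_areas.csv`).
#'
#' @param cohort an [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param write_series whether to write the (large) long-format series.
#' @return invisibly, the directory.
#' @export
write_cohort_csv <- function(cohort, dir, write_series = FALSE) {
  stopifnot(inherits(cohort, "fc_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$projects, file.path(dir, "projects.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  if (write_series && length(cohort$series))
    write_series_csv(cohort$series, file.path(dir, "series.csv"))
  invisible(dir)
}
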