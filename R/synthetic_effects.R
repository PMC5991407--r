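#' Inject a calibrated consolidation effect into a parcel series
#'
#' Modifies the years after `completion_year` so that the before/after
#' contrasts a downstream indicator computation will measure equal the
#' configured effect sizes exactly (before any clipping). Concretely, on the
#' fully-affected years the injector guarantees:
#' \itemize{
#'   \item mean NDVI (all composites) shifts by `delta_level`,
#'   \item the inter-annual standard deviation of annual mean NDVI becomes
#'     `variance_factor` times its before-window value,
#'   \item the window maximum shifts by `delta_max`,
#'   \item each affected year carries `delta_peaks` additional seasonal
#'     peaks.
#' }
#' The mean and maximum targets are met jointly by solving for a constant
#' offset plus a narrow bump at each year's seasonal maximum (the bump moves
#' the maximum, the constant moves the rest of the mean), iterated to
#' convergence, so the four effect axes stay orthogonal: e.g. adding a
#' second crop peak does not leak into the mean-level contrast. With
#' `lag_years > 0`, intermediate years receive a linearly ramped fraction of
#' the effect and calibration targets the fully-expressed years.
#'
#' @param series an [ndvi_series()].
#' @param completion_year project completion year; years up to and including
#'   it are left untouched.
#' @param effect an [effect_config()].
#' @return the modified [ndvi_series()]. Values pushed outside
#'   `[-0.2, 1.0]` are clipped with a warning (clipping voids exactness).
#' @export
inject_effect <- function(series, completion_year, effect) {
  stopifnot(inherits(series, "ndvi_series"), inherits(effect, "effect_config"))
  completion_year <- as.integer(completion_year)
  if (completion_year < min(series$years) || completion_year > max(series$years))
    stop("`completion_year` must lie within the series years")
  if (is_neutral_effect(effect)) return(series)
  after <- series$years[series$years > completion_year]
  if (length(after) == 0) return(series)

  M <- series$ndvi
  if (anyNA(M))
    stop("inject_effect() requires a gap-free series; corrupt afterwards")
  yrs <- series$years
  frac <- pmin(1, (after - completion_year) / (effect$lag_years + 1))
  full <- after[frac >= 1]
  before_idx <- which(yrs <= completion_year)
  after_idx <- match(after, yrs)
  full_idx <- match(full, yrs)
  t <- 1:23

  # 1. extra crop cycles: Gaussian bumps placed away from the existing
  # peaks. Wide main peaks can leave the inter-peak valley too shallow for
  # a prominence-based detector, so after adding each bump the valley is
  # deepened (a smooth notch at its lowest point) until the new peak
  # stands at least `prom_margin` above it -- with headroom for the
  # smoothing filter, which flattens narrow features.
  prom_margin <- 0.18
  if (effect$delta_peaks > 0L) {
    for (j in seq_along(after_idx)) {
      row <- after_idx[j]
      centers <- which.max(M[row, ])
      for (k in seq_len(effect$delta_peaks)) {
        cand <- 4:20
        d <- vapply(cand, function(p) min(abs(p - centers)), numeric(1))
        ctr <- cand[which.max(d)]
        M[row, ] <- M[row, ] + frac[j] * effect$new_peak_amp *
          exp(-((t - ctr) / effect$new_peak_width)^2 / 2)
        for (m0 in centers) {
          span <- (min(ctr, m0) + 1):(max(ctr, m0) - 1)
          if (length(span) < 2) next
          for (rep in 1:4) {
            vmin_at <- span[which.min(M[row, span])]
            deficit <- prom_margin * frac[j] -
              (M[row, ctr] - min(M[row, span]))
            if (deficit <= 0) break
            M[row, ] <- M[row, ] -
              deficit * exp(-((t - vmin_at) / 2)^2 / 2)
          }
        }
        centers <- c(centers, ctr)
      }
    }
  }

  # 2. inter-annual variability: rescale annual-mean deviations on the
  # fully-affected years so their population SD is variance_factor times
  # the before-window SD.
  if (effect$variance_factor != 1) {
    sigma_b <- sd_pop(rowMeans(M[before_idx, , drop = FALSE]))
    if (length(full_idx) < 2L) {
      warning("fewer than 2 fully-affected years; variance effect skipped")
    } else if (sigma_b < 1e-12) {
      warning("before-window inter-annual variability is zero; ",
              "variance effect has no reference scale and was skipped")
    } else {
      m_f <- rowMeans(M[full_idx, , drop = FALSE])
      dev <- m_f - mean(m_f)
      target <- effect$variance_factor * sigma_b
      cur <- sd_pop(m_f)
      if (cur > 1e-12) {
        M[full_idx, ] <- M[full_idx, ] + (target / cur - 1) * dev
      } else {
        p <- rep_len(c(1, -1), length(full_idx))
        p <- p - mean(p)
        M[full_idx, ] <- M[full_idx, ] + (target / sd_pop(p)) * p
      }
    }
  }

  # 3. joint mean/max calibration: constant offset + bump at each year's
  # seasonal maximum, iterated until both contrasts hit their targets.
  bump_w <- 1.5
  converged <- FALSE
  for (it in 1:40) {
    cur_men <- mean(M[full_idx, ]) - mean(M[before_idx, ])
    cur_man <- max(M[full_idx, ]) - max(M[before_idx, ])
    err_l <- effect$delta_level - cur_men
    err_x <- effect$delta_max - cur_man
    if (max(abs(err_l), abs(err_x)) < 1e-10) { converged <- TRUE; break }
    bumps <- lapply(after_idx, function(row)
      exp(-((t - which.max(M[row, ])) / bump_w)^2 / 2))
    wbar <- mean(vapply(bumps, sum, numeric(1))) / 23
    da <- (err_x - err_l) / (1 - wbar)
    dc <- err_l - da * wbar
    for (j in seq_along(after_idx))
      M[after_idx[j], ] <- M[after_idx[j], ] + frac[j] * (dc + da * bumps[[j]])
  }
  if (!converged)
    warning("mean/max calibration did not fully converge")

  if (any(M < NDVI_MIN - 1e-12 | M > NDVI_MAX + 1e-12)) {
    warning("injected effect pushed NDVI outside [-0.2, 1.0]; values clipped")
    M <- clip_ndvi(M)
  }
  series$ndvi <- M
  series
}

#' Corrupt a parcel series with noise, gaps and bad reliability flags
#'
#' Applies, in order: additive Gaussian observation noise (clipped to the
#' valid NDVI range), missing composites drawn per-slot at `missing_rate`,
#' marginal-quality flags (1) at `marginal_rate`, and unusable flags (2 or
#' 3) at `bad_reliability_rate`. Fully deterministic given the seed in the
#' config; with an all-zero config the series is returned unchanged.
#'
#' @param series an [ndvi_series()].
#' @param noise a [noise_config()].
#' @return the corrupted [ndvi_series()].
#' @export
corrupt_series <- function(series, noise) {
  stopifnot(inherits(series, "ndvi_series"), inherits(noise, "noise_config"))
  if (noise$noise_sd == 0 && noise$missing_rate == 0 &&
      noise$bad_reliability_rate == 0 && noise$marginal_rate == 0)
    return(series)
  with_seed(noise$seed, {
    M <- series$ndvi
    R <- series$reliability
    n <- length(M)
    if (noise$noise_sd > 0)
      M[] <- clip_ndvi(M + stats::rnorm(n, 0, noise$noise_sd))
    marg <- if (noise$marginal_rate > 0) stats::runif(n) < noise$marginal_rate
            else rep(FALSE, n)
    bad <- if (noise$bad_reliability_rate > 0)
      matrix(stats::runif(n) < noise$bad_reliability_rate, nrow(M))
      else matrix(FALSE, nrow(M), ncol(M))
    bad_flag <- sample(c(2L, 3L), n, replace = TRUE)
    miss <- if (noise$missing_rate > 0)
      matrix(stats::runif(n) < noise$missing_rate, nrow(M))
      else matrix(FALSE, nrow(M), ncol(M))
    if (is.finite(noise$max_missing_per_year)) {
      # roll back excess corruption so every year stays screenable
      for (r in seq_len(nrow(M))) {
        unusable <- which(miss[r, ] | bad[r, ])
        if (length(unusable) > noise$max_missing_per_year) {
          excess <- unusable[-seq_len(noise$max_missing_per_year)]
          miss[r, excess] <- FALSE
          bad[r, excess] <- FALSE
        }
      }
    }
    R[marg & R == 0L] <- 1L
    R[bad & !is.na(R)] <- bad_flag[bad & !is.na(R)]
    M[miss] <- NA_real_
    R[miss] <- NA_integer_
    series$ndvi <- M
    series$reliability <- R
    series
  })
}
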