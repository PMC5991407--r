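test_that("a pure level effect shifts every post-completion annual mean exactly", {
  s <- make_series()
  out <- inject_effect(s, 2007, effect_config(delta_level = 0.1))
  pre <- as.character(2001:2007)
  post <- as.character(2008:2013)
  expect_identical(out$ndvi[pre, ], s$ndvi[pre, ])
  expect_equal(rowMeans(out$ndvi[post, ]) - rowMeans(s$ndvi[post, ]),
               setNames(rep(0.1, 6), post), tolerance = 1e-9)
})

test_that("an all-neutral effect is the identity", {
  s <- make_series()
  expect_identical(inject_effect(s, 2007, effect_config()), s)
})

test_that("delta_peaks adds detectable crop cycles to every post year", {
  s <- make_series()
  out <- inject_effect(s, 2007, effect_config(delta_peaks = 1))
  for (y in as.character(2008:2013))
    expect_equal(brute_force_peak_count(out$ndvi[y, ]), 2)
  for (y in as.character(2001:2007))
    expect_equal(brute_force_peak_count(out$ndvi[y, ]), 1)
})

test_that("injected effects are exactly calibrated and mutually orthogonal", {
  set.seed(31)
  offs <- rnorm(13, 0, 0.02)
  s <- make_series(offsets = offs)
  w <- split_windows(2001:2013, 2007)
  eff <- effect_config(delta_level = -0.05, variance_factor = 1.5,
                       delta_max = 0.05, delta_peaks = 1)
  out <- inject_effect(s, 2007, eff)
  expect_equal(men_change(out$ndvi, w), -0.05, tolerance = 1e-8)
  expect_equal(man_change(out$ndvi, w), 0.05, tolerance = 1e-8)
  sigma_b <- sd(rowMeans(s$ndvi[1:7, ])) * sqrt(6 / 7)  # population SD
  expect_equal(sdn_change(out$ndvi, w), 0.5 * sigma_b, tolerance = 1e-8)
  expect_equal(pfn_change(out$ndvi, w), 1)
})

test_that("variance reduction hits the configured factor of the before SD", {
  set.seed(8)
  s <- make_series(offsets = rnorm(13, 0, 0.03))
  w <- split_windows(2001:2013, 2006)
  out <- inject_effect(s, 2006, effect_config(variance_factor = 0.25,
                                              delta_level = 0.02))
  m_b <- rowMeans(s$ndvi[as.character(w$before), ])
  sigma_b <- sqrt(mean((m_b - mean(m_b))^2))
  m_a <- rowMeans(out$ndvi[as.character(w$after), ])
  expect_equal(sqrt(mean((m_a - mean(m_a))^2)), 0.25 * sigma_b,
               tolerance = 1e-8)
})

test_that("effects that overflow the NDVI range warn and clip", {
  s <- make_series(params = phenology_params(base_ndvi = 0.4, amplitude = 0.55))
  expect_warning(out <- inject_effect(s, 2007, effect_config(delta_max = 0.2)),
                 "clip")
  expect_true(all(out$ndvi <= 1 + 1e-12))
})

test_that("lagged effects ramp in and reach full size after the lag", {
  s <- make_series()
  out <- inject_effect(s, 2005, effect_config(delta_level = 0.09, lag_years = 2))
  shift <- rowMeans(out$ndvi) - rowMeans(s$ndvi)
  expect_equal(unname(shift[as.character(2006:2007)]), c(0.03, 0.06),
               tolerance = 1e-3)
  expect_gt(shift[["2013"]], 0.08)
})

test_that("corruption with an all-zero config is the identity", {
  s <- make_series()
  expect_identical(corrupt_series(s, noise_config(marginal_rate = 0)), s)
})

test_that("corruption is reproducible under a fixed seed", {
  s <- make_series()
  nc <- noise_config(noise_sd = 0.05, missing_rate = 0.2,
                     bad_reliability_rate = 0.1, seed = 99)
  expect_identical(corrupt_series(s, nc), corrupt_series(s, nc))
  nc2 <- nc; nc2$seed <- 100L
  expect_false(identical(corrupt_series(s, nc), corrupt_series(s, nc2)))
})

test_that("realized missing fraction matches the binomial expectation", {
  s <- make_series()
  n_slots <- length(s$ndvi)
  fracs <- vapply(1:300, function(sd) {
    out <- corrupt_series(s, noise_config(missing_rate = 0.5, seed = sd))
    mean(is.na(out$ndvi))
  }, numeric(1))
  se <- sqrt(0.25 / n_slots) / sqrt(300)
  expect_lt(abs(mean(fracs) - 0.5), 3 * se)
})

test_that("corrupted flags stay in the MODIS reliability domain", {
  s <- make_series()
  out <- corrupt_series(s, noise_config(noise_sd = 0.05, missing_rate = 0.1,
                                        bad_reliability_rate = 0.2,
                                        marginal_rate = 0.3, seed = 5))
  r <- out$reliability
  expect_true(all(r[!is.na(r)] %in% 0:3))
  expect_true(all(is.na(r[is.na(out$ndvi)])))
  expect_true(all(out$ndvi >= -0.2 & out$ndvi <= 1, na.rm = TRUE))
})
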