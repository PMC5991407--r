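mk_curves <- function(values_by_year) {
  yrs <- as.integer(names(values_by_year))
  m <- t(vapply(values_by_year, function(v) rep_len(v, 23), numeric(23)))
  rownames(m) <- yrs
  m
}

test_that("window splitting follows the completion-year convention", {
  w <- split_windows(2001:2013, 2007)
  expect_equal(w$before, 2001:2007)
  expect_equal(w$after, 2008:2013)
  expect_equal(split_windows(2001:2013, 2012)$after, 2013L)
  expect_equal(split_windows(2001:2013, 2001)$before, 2001L)
  expect_error(split_windows(2001:2013, 2013), "empty window")
  expect_error(split_windows(2001:2013, 2000), "empty window")
})

test_that("mean-NDVI change matches hand-computed constants", {
  cur <- mk_curves(list(`2001` = 0.4, `2002` = 0.4, `2003` = 0.5, `2004` = 0.5))
  w <- split_windows(2001:2004, 2002)
  expect_equal(men_change(cur, w), 0.1)
  expect_equal(men_change(cur, split_windows(2001:2004, 2002)), 0.1)
  same <- mk_curves(list(`2001` = 0.4, `2002` = 0.4, `2003` = 0.4, `2004` = 0.4))
  expect_equal(men_change(same, w), 0)
  cur3 <- mk_curves(list(`2001` = 0.3, `2002` = 0.5, `2003` = 0.6))
  expect_equal(men_change(cur3, split_windows(2001:2003, 2002)), 0.2)
})

test_that("SD change uses the population SD of annual means", {
  cur <- mk_curves(list(`2001` = 0.3, `2002` = 0.5,
                        `2003` = 0.4, `2004` = 0.4, `2005` = 0.4))
  w <- split_windows(2001:2005, 2002)
  expect_equal(sdn_change(cur, w), -0.1)
  same <- mk_curves(list(`2001` = 0.4, `2002` = 0.6, `2003` = 0.4, `2004` = 0.6))
  expect_equal(sdn_change(same, split_windows(2001:2004, 2002)), 0)
  expect_error(sdn_change(cur, split_windows(2001:2005, 2004)), "2 years")
})

test_that("pooled-mode SD change uses every composite in the window", {
  set.seed(1)
  m <- matrix(runif(4 * 23, 0.2, 0.8), 4, 23, dimnames = list(2001:2004, NULL))
  w <- split_windows(2001:2004, 2002)
  expected <- sd(as.vector(m[3:4, ])) * sqrt(45 / 46) -
    sd(as.vector(m[1:2, ])) * sqrt(45 / 46)
  expect_equal(sdn_change(m, w, mode = "pooled"), expected, tolerance = 1e-12)
})

test_that("maximum-NDVI change scans all composites of each window", {
  m <- matrix(0.3, 4, 23, dimnames = list(2001:2004, NULL))
  m[1, 5] <- 0.7; m[3, 20] <- 0.8
  w <- split_windows(2001:2004, 2002)
  expect_equal(man_change(m, w), 0.1)
  m[4, 7] <- 0.95
  expect_equal(man_change(m, w), 0.25)
  expect_equal(man_change(m, w) * 0 + man_change(m[c(1, 2, 3, 4), ], w),
               man_change(m, w))
})

test_that("peak-frequency change averages annual counts per window", {
  one <- seasonal_curve(phenology_params(), 2001)
  two <- seasonal_curve(phenology_params(peaks_per_year = 2, amplitude = 0.35,
                                         peak_center = c(7, 16),
                                         peak_width = 2), 2001)
  m <- rbind(matrix(rep(one, 7), 7, 23, byrow = TRUE),
             matrix(rep(two, 6), 6, 23, byrow = TRUE))
  rownames(m) <- 2001:2013
  w <- split_windows(2001:2013, 2007)
  expect_equal(pfn_change(m, w), 1)
  m2 <- m
  m2[8, ] <- one  # first after-year still single-cropped
  expect_equal(pfn_change(m2, w), 11 / 6 - 1, tolerance = 1e-12)
  flat <- matrix(rep(one, 13), 13, 23, byrow = TRUE,
                 dimnames = list(2001:2013, NULL))
  expect_equal(pfn_change(flat, w), 0)
})

test_that("translation leaves all four change indicators invariant", {
  set.seed(12)
  m <- matrix(runif(13 * 23, 0.1, 0.6), 13, 23, dimnames = list(2001:2013, NULL))
  w <- split_windows(2001:2013, 2006)
  shifted <- m + 0.15
  expect_equal(men_change(shifted, w), men_change(m, w), tolerance = 1e-12)
  expect_equal(man_change(shifted, w), man_change(m, w), tolerance = 1e-12)
  expect_equal(sdn_change(shifted, w), sdn_change(m, w), tolerance = 1e-12)
  # peak counting has an absolute NDVI floor, so translation invariance of
  # PFN holds via the prominence structure when peaks stay above the floor
  base <- t(vapply(1:13, function(i) seasonal_curve(phenology_params(), 2000 + i),
                   numeric(23)))
  rownames(base) <- 2001:2013
  expect_equal(pfn_change(base + 0.1, w), pfn_change(base, w))
})

test_that("swapping the windows negates every change indicator", {
  set.seed(13)
  m <- matrix(runif(10 * 23, 0.1, 0.7), 10, 23, dimnames = list(2001:2010, NULL))
  w <- split_windows(2001:2010, 2005)
  swapped <- structure(list(before = w$after, after = w$before),
                       class = "window_pair")
  expect_equal(men_change(m, swapped), -men_change(m, w), tolerance = 1e-12)
  expect_equal(sdn_change(m, swapped), -sdn_change(m, w), tolerance = 1e-12)
  expect_equal(man_change(m, swapped), -man_change(m, w), tolerance = 1e-12)
  expect_equal(pfn_change(m, swapped), -pfn_change(m, w), tolerance = 1e-12)
})

test_that("evaluate_project sets flags by strict inequalities", {
  s <- make_series()
  out <- inject_effect(s, 2007, effect_config(delta_level = 0.1))
  ind <- evaluate_project(out$ndvi, out$ndvi, 2007)
  expect_true(ind$effective_pl)
  expect_false(ind$effective_pp)  # max calibrated to exactly zero change

  still <- evaluate_project(s$ndvi, s$ndvi, 2007)
  expect_equal(still$men_change, 0)
  expect_equal(still$sdn_change, 0)
  expect_equal(still$man_change, 0)
  expect_equal(still$pfn_change, 0)
  expect_false(any(unlist(still[paste0("effective_",
                                       c("pl", "pv", "pp", "mi"))])))
})

test_that("an injected variance reduction is recovered as effective PV", {
  set.seed(44)
  s <- make_series(offsets = rnorm(13, 0, 0.02))
  out <- inject_effect(s, 2007, effect_config(variance_factor = 0.25,
                                              delta_level = 0.05))
  ind <- evaluate_project(out$ndvi, out$ndvi, 2007)
  expect_lt(ind$sdn_change, 0)
  expect_true(ind$effective_pv)
})
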