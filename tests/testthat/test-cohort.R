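test_that("cohort sizes and the training/testing year split match the design", {
  co <- generate_cohort(n_former = 4442, n_later = 3063, seed = 3,
                        series = "none")
  expect_equal(nrow(co$projects), 7505)
  cy <- co$projects$completion_year
  expect_equal(sum(cy %in% 2006:2009), 2982)
  expect_equal(sum(cy == 2010), 1460)
  expect_equal(sum(cy %in% 2011:2013), 3063)
  expect_equal(ncol(co$projects[factor_names()]), 16)
})

test_that("an empty former cohort yields a later-only table", {
  co <- generate_cohort(n_former = 0, n_later = 50, seed = 4, series = "none")
  expect_equal(nrow(co$projects), 50)
  expect_true(all(co$projects$period == "later"))
  expect_true(all(co$projects$completion_year %in% 2011:2013))
})

test_that("a constant effect model forces every ground-truth label", {
  co <- generate_cohort(n_former = 80, n_later = 0, seed = 5, series = "none",
                        model = effect_model(constant_prob = c(pl = 1.0)))
  expect_true(all(co$truth$eff_pl))
})

test_that("identical seeds reproduce the cohort bit-for-bit", {
  a <- generate_cohort(n_former = 30, n_later = 10, seed = 77)
  b <- generate_cohort(n_former = 30, n_later = 10, seed = 77)
  expect_identical(a, b)
  tmp <- tempfile(); tmp2 <- tempfile()
  saveRDS(a, tmp); saveRDS(b, tmp2)
  expect_identical(readLines(tmp, warn = FALSE), readLines(tmp2, warn = FALSE))
  d <- generate_cohort(n_former = 30, n_later = 10, seed = 78)
  expect_false(identical(a$projects, d$projects))
})

test_that("generated series respect the NDVI and reliability domains", {
  co <- generate_cohort(n_former = 25, n_later = 0, seed = 9)
  for (s in co$series) {
    expect_true(all(s$ndvi >= -0.2 & s$ndvi <= 1, na.rm = TRUE))
    r <- s$reliability
    expect_true(all(r[!is.na(r)] %in% 0:3))
  }
})

test_that("per-period effectiveness rates land on the calibrated targets", {
  co <- generate_cohort(n_former = 3000, n_later = 2000, seed = 21,
                        series = "none")
  tr <- co$truth
  tgt_f <- c(pl = 62.02, pv = 55.02, pp = 53.53, mi = 33.30)
  tgt_l <- c(pl = 88.18, pv = 66.41, pp = 81.55, mi = 3.59)
  for (ind in names(tgt_f)) {
    f <- 100 * mean(tr[[paste0("eff_", ind)]][tr$period == "former"])
    l <- 100 * mean(tr[[paste0("eff_", ind)]][tr$period == "later"])
    expect_lt(abs(f - tgt_f[ind]), 3)
    expect_lt(abs(l - tgt_l[ind]), 3)
  }
})

test_that("factor draws respect their physical bounds", {
  co <- generate_cohort(n_former = 500, n_later = 500, seed = 13,
                        series = "none")
  p <- co$projects
  expect_true(all(p$slope >= 0))
  expect_true(all(p$urbanization_rate >= 0 & p$urbanization_rate <= 100))
  expect_true(all(p$crop_disaster_rate >= 0 & p$crop_disaster_rate <= 100))
  expect_true(all(p$area_ha > 100))
})

test_that("cohort CSV round trip preserves the project table", {
  co <- generate_cohort(n_former = 12, n_later = 5, seed = 2)
  d <- tempfile()
  write_cohort_csv(co, d, write_series = TRUE)
  expect_true(all(file.exists(file.path(d, c("projects.csv", "ground_truth.csv",
                                             "series.csv")))))
  p2 <- read.csv(file.path(d, "projects.csv"))
  expect_equal(p2$project_id, co$projects$project_id)
  ser <- read_series_csv(file.path(d, "series.csv"))
  id <- names(co$series)[1]
  expect_equal(ser[[id]]$ndvi, co$series[[id]]$ndvi, tolerance = 1e-12)
  expect_equal(ser[[id]]$area_ha, co$series[[id]]$area_ha)
  unlink(d, recursive = TRUE)
})
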