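test_that("parcel-mean compositing averages only usable pixels", {
  expect_equal(composite_parcel_mean(c(0.4, 0.6)), 0.5)
  expect_equal(composite_parcel_mean(0.4), 0.4)
  expect_equal(composite_parcel_mean(c(0.4, 0.9), flags = c(0, 2)), 0.4)
  expect_true(is.na(composite_parcel_mean(c(0.4, 0.9), flags = c(2, 3))))
  expect_true(is.na(composite_parcel_mean(c(NA, NA))))
})

test_that("screening keeps clean large parcels and rejects rule violations", {
  ok <- make_series(area = 250)
  expect_true(screen_parcel(ok)$kept)

  small <- make_series(area = 50)
  r <- screen_parcel(small)
  expect_false(r$kept)
  expect_equal(r$reasons, "AREA_TOO_SMALL")

  gappy <- make_series(area = 250)
  gappy$ndvi[3, 1:6] <- NA
  gappy$reliability[3, 1:6] <- NA
  r <- screen_parcel(gappy)
  expect_false(r$kept)
  expect_true("TOO_MANY_MISSING" %in% r$reasons)

  # five missing in a year is still acceptable
  gappy5 <- make_series(area = 250)
  gappy5$ndvi[3, 1:5] <- NA
  expect_true(screen_parcel(gappy5)$kept)

  unreliable <- make_series(area = 250)
  unreliable$reliability[2, 1:6] <- 3L
  r <- screen_parcel(unreliable)
  expect_false(r$kept)
  expect_equal(r$reasons, "UNRELIABLE")

  # boundary: exactly 100 ha does not pass a strict threshold
  expect_false(screen_parcel(make_series(area = 100))$kept)
})

test_that("screening is idempotent and order-independent", {
  s <- make_series(area = 250)
  s$ndvi[4, 2:7] <- NA
  r1 <- screen_parcel(s)
  r2 <- screen_parcel(s)
  expect_identical(r1, r2)
})

test_that("gap filling interpolates linearly and extends ends", {
  s <- make_series()
  s$ndvi[1, 1:3] <- c(0.2, NA, 0.4)
  filled <- fill_missing(s)
  expect_equal(filled$ndvi[1, 2], 0.3)

  # no gaps: identity on the values
  s2 <- make_series()
  expect_equal(fill_missing(s2)$ndvi, s2$ndvi)

  # trailing gap copies the nearest observed value
  s3 <- make_series()
  s3$ndvi[13, 23] <- NA
  expect_equal(fill_missing(s3)$ndvi[13, 23], s3$ndvi[13, 22])

  # an entirely missing year must have been screened out earlier
  s4 <- make_series()
  s4$ndvi[5, ] <- NA
  expect_error(fill_missing(s4), "screen_parcel")
})

test_that("gap filling bridges year boundaries through the concatenated record", {
  s <- make_series()
  s$ndvi[2, 23] <- NA
  filled <- fill_missing(s)
  expect_equal(filled$ndvi[2, 23], (s$ndvi[2, 22] + s$ndvi[3, 1]) / 2)
})

test_that("Savitzky-Golay smoothing preserves constants and linear ramps", {
  yrs <- 2001:2003
  const <- ndvi_series("c", 200, yrs, matrix(0.5, 3, 23))
  expect_equal(sg_smooth(const), matrix(0.5, 3, 23, dimnames = list(yrs, 1:23)),
               tolerance = 1e-12)

  ramp_vals <- seq(0, 0.69, length.out = 69)
  ramp <- ndvi_series("r", 200, yrs, matrix(ramp_vals, 3, 23, byrow = TRUE))
  sm <- sg_smooth(ramp)
  expect_equal(as.vector(t(sm)), ramp_vals, tolerance = 1e-9)
})

test_that("Savitzky-Golay smoothing strictly reduces an isolated spike", {
  yrs <- 2001:2002
  M <- matrix(0.3, 2, 23)
  M[1, 12] <- 0.9
  s <- ndvi_series("spk", 200, yrs, M)
  sm <- sg_smooth(s, window = 7, polyorder = 2)
  expect_lt(max(sm), 0.9)
  expect_gt(max(sm), 0.3)
})

test_that("Savitzky-Golay smoothing is linear in its input", {
  set.seed(42)
  yrs <- 2001:2004
  mk <- function(M) ndvi_series("l", 200, yrs, M)
  A <- matrix(runif(4 * 23, 0, 0.5), 4, 23)
  B <- matrix(runif(4 * 23, 0, 0.4), 4, 23)
  lhs <- sg_smooth(mk(0.6 * A + 0.4 * B))
  rhs <- 0.6 * sg_smooth(mk(A)) + 0.4 * sg_smooth(mk(B))
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("smoothing rejects invalid windows", {
  s <- make_series(years = 2001:2002)
  expect_error(sg_smooth(s, window = 6), "odd")
  expect_error(sg_smooth(s, window = 7, polyorder = 7), "smaller")
  expect_error(sg_smooth(s, window = 47), "shorter")
})

test_that("preprocessing a clean synthetic parcel barely changes the curves", {
  s <- make_series(params = phenology_params(peak_width = 3))
  pp <- preprocess_parcel(s)
  expect_true(pp$report$kept)
  expect_lt(max(abs(pp$smooth - s$ndvi)), 0.01)
})

test_that("raw MOD13Q1 integer scaling is auto-detected on read", {
  s <- make_series(years = 2001:2002)
  long <- series_to_long(s)
  long$ndvi <- round(long$ndvi * 1e4)
  back <- long_to_series(long)
  expect_equal(back[[1]]$ndvi, s$ndvi, tolerance = 1e-3)
})
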