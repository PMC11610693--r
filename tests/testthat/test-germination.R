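test_that("hourly rate follows the wet-thermal polynomial under wet, warm conditions", {
  p <- rate_params()
  # 0.000129 + 0.00616*2 - 0.0000125*400, verified by hand
  expect_equal(germination_rate(20, -0.1, p), 0.007449, tolerance = 1e-12)
  # intercept in the T -> 0+ wet limit
  expect_equal(germination_rate(1e-9, -0.1, p), 1.29e-4, tolerance = 1e-6)
  # vectorized over both arguments
  expect_equal(germination_rate(c(20, 20), c(-0.1, -5), p),
               c(0.007449, 0))
})

test_that("rate is exactly zero outside the wet-thermal conditions, with strict thresholds", {
  p <- rate_params()
  expect_identical(germination_rate(-2, -0.5, p), 0)     # cold
  expect_identical(germination_rate(15, -2.0, p), 0)     # dry
  expect_identical(germination_rate(0, -0.1, p), 0)      # exactly at base temp
  expect_identical(germination_rate(25, -1.25, p), 0)    # exactly at wet threshold
  # negative polynomial values (supra-optimal temperature) are clipped
  expect_identical(germination_rate(55, -0.1, p), 0)
})

test_that("linear and quadratic readings of the coefficients agree only near T = 0", {
  pq <- rate_params(poly_form = "quadratic")
  pl <- rate_params(poly_form = "linear")
  expect_equal(germination_rate(1e-9, -0.1, pq),
               germination_rate(1e-9, -0.1, pl), tolerance = 1e-6)
  expect_equal(germination_rate(10, -0.1, pl),
               1.29e-4 + (6.16e-4 - 1.25e-5) * 10)
  # away from 0 the quadratic bends below the literal linear reading
  expect_lt(germination_rate(10, -0.1, pq), germination_rate(10, -0.1, pl))
})

test_that("rate parameters are validated", {
  expect_error(rate_params(poly_coeffs = c(1, 2)), "three finite")
  expect_error(rate_params(wet_threshold_mpa = 1), "negative")
  expect_error(germination_rate(NA, -0.1), "non-finite")
})

test_that("hourly_rates applies the rate elementwise and validates hourly spacing", {
  dry <- make_series(48, temp = 20, psi = -5)
  expect_identical(hourly_rates(dry), rep(0, 48))
  const <- make_series(48, temp = 20, psi = -0.1)
  expect_equal(hourly_rates(const), rep(0.007449, 48))
  gappy <- const[-10, ]
  expect_error(hourly_rates(gappy), "gap after 2001-01-01 08:00")
})

test_that("rate sums match the constant-series arithmetic and add over disjoint windows", {
  s <- make_series(24, temp = 20, psi = -0.1)
  w <- c(s$timestamp[1], s$timestamp[24] + 3600)
  expect_equal(rate_sum(s, w), 0.178776, tolerance = 1e-12)  # 24 x 0.007449
  s2 <- random_series(5, 400)
  mid <- s2$timestamp[200]
  whole <- rate_sum(s2, c(s2$timestamp[1], s2$timestamp[400] + 3600))
  left <- rate_sum(s2, c(s2$timestamp[1], mid))
  right <- rate_sum(s2, c(mid, s2$timestamp[400] + 3600))
  expect_equal(left + right, whole, tolerance = 1e-12)
  # empty intersection: zero, with a coverage warning
  far <- as.POSIXct(c("2010-01-01", "2010-02-01"), tz = "UTC")
  expect_warning(z <- rate_sum(s2, far), "coverage")
  expect_identical(z, 0)
  expect_error(rate_sum(s2, c(mid, mid)), "non-empty")
})

test_that("monthly sums partition the annual sum and respect the calendar", {
  # wet and warm only during March 2001
  s <- make_series(24 * 365, temp = 10, psi = -5)
  lt <- as.POSIXlt(s$timestamp, tz = "UTC")
  s$soil_wp_mpa[lt$mon == 2L] <- -0.2
  m <- monthly_rate_sums(s)
  expect_equal(nrow(m), 12L)
  expect_true(all(m$rate_sum[m$month != 3] == 0))
  expect_gt(m$rate_sum[m$month == 3], 0)
  # partition property on a random full year
  r <- random_series(11, 24 * 365, start = "2003-01-01 00:00:00")
  m2 <- monthly_rate_sums(r)
  annual <- rate_sum(r, c(r$timestamp[1], r$timestamp[nrow(r)] + 3600))
  expect_equal(sum(m2$rate_sum), annual, tolerance = 1e-9)
  # leap-year February has 29 x 24 contributing hours
  leap <- make_series(24 * (31 + 29), temp = 20, psi = -0.1,
                      start = "2000-01-01 00:00:00")
  mf <- monthly_rate_sums(leap)
  expect_equal(mf$rate_sum[mf$month == 2], 29 * 24 * 0.007449, tolerance = 1e-9)
  # partial boundary months are dropped with a warning
  expect_warning(mp <- monthly_rate_sums(make_series(24 * 40)), "partial")
  expect_equal(nrow(mp), 1L)
})

test_that("seasonal sums attach fall of year y-1 and spring of year y to observation year y", {
  monthly <- data.frame(site_id = "A",
                        year = c(2000, 2000, 2000, 2001),
                        month = c(10, 11, 12, 3),
                        rate_sum = c(1.0, 2.0, 0.5, 0.8))
  s <- seasonal_rate_sums(monthly, 2001)
  expect_equal(s$fall_rate_sum, 3.5)
  expect_equal(s$spring_rate_sum, 0.8)
  expect_equal(s$obs_year, 2001L)
  # missing October: the observation year is omitted with a warning
  expect_warning(s2 <- seasonal_rate_sums(monthly[-1, ], 2001), "incomplete")
  expect_equal(nrow(s2), 0L)
})

test_that("rate sums are nonnegative and never decrease when a dry hour turns wet", {
  for (seed in 1:10) {
    s <- random_series(seed, 300)
    w <- c(s$timestamp[1], s$timestamp[300] + 3600)
    base <- rate_sum(s, w)
    expect_gte(base, 0)
    dry_warm <- which(s$soil_wp_mpa <= -1.25 & s$soil_temp_c > 0)
    if (length(dry_warm)) {
      s$soil_wp_mpa[dry_warm[1]] <- -0.1
      expect_gte(rate_sum(s, w), base)
    }
  }
})

test_that("vectorized accumulation equals the hour-by-hour loop oracle", {
  for (seed in 1:25) {
    s <- random_series(seed, 400)
    expect_equal(rate_sum(s, c(s$timestamp[1], s$timestamp[400] + 3600)),
                 loop_rate_sum(s$soil_temp_c, s$soil_wp_mpa),
                 tolerance = 1e-13)
  }
})
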