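test_that("spatial scaling gives across-site z-scores and freezes constants", {
  z <- spatial_scale(c(a = 1, b = 2, c = 3))
  expect_equal(unname(z$z), c(-1, 0, 1))          # sample SD = 1
  expect_equal(z$constants$mean, 2)
  # a site equal to the mean scores 0
  expect_equal(unname(z$z["b"]), 0)
  # frozen constants are applied unchanged: training z-scores do not move
  z2 <- spatial_scale(c(a = 1, b = 2, c = 3, d = 10), constants = z$constants)
  expect_equal(unname(z2$z[c("a", "b", "c")]), c(-1, 0, 1))
  expect_error(spatial_scale(c(a = 2, b = 2, c = 2)), "degenerate")
  expect_error(spatial_scale(c(a = 1)), ">= 2 sites")
})

test_that("temporal scaling gives within-site anomalies with zero-SD and single-year rules", {
  d <- data.frame(site_id = rep(c("A", "B", "C"), times = c(3, 3, 1)),
                  year = c(1:3, 1:3, 1),
                  value = c(2, 4, 6, 5, 5, 5, 9))
  suppressMessages(out <- temporal_scale(d))
  expect_equal(out$anomaly[out$site_id == "A"], c(-1, 0, 1))
  expect_equal(out$anomaly[out$site_id == "B"], c(0, 0, 0))  # constant across years
  expect_equal(out$anomaly[out$site_id == "C"], 0)           # single year
})

test_that("build_covariates produces normalized covariates with exact joins", {
  set.seed(20)
  seasonal <- expand.grid(site_id = sprintf("S%02d", 1:12), obs_year = 2001:2008)
  seasonal$fall_rate_sum <- stats::rgamma(nrow(seasonal), 3, 1)
  seasonal$spring_rate_sum <- stats::rgamma(nrow(seasonal), 2, 1)
  cb <- build_covariates(seasonal, quiet = TRUE)
  cov <- cb$covariates
  expect_equal(nrow(cov), nrow(seasonal))
  # spatial covariates: mean 0, sample SD 1 across sites (site means)
  sm <- cov[!duplicated(cov$site_id), ]
  expect_lt(abs(mean(sm$fall_spatial)), 1e-9)
  expect_equal(stats::sd(sm$fall_spatial), 1, tolerance = 1e-9)
  expect_lt(abs(mean(sm$spring_spatial)), 1e-9)
  expect_equal(stats::sd(sm$spring_spatial), 1, tolerance = 1e-9)
  # temporal anomalies: mean 0 within every site
  for (sid in unique(cov$site_id)) {
    expect_lt(abs(mean(cov$fall_temporal[cov$site_id == sid])), 1e-9)
    expect_lt(abs(mean(cov$spring_temporal[cov$site_id == sid])), 1e-9)
  }
  # two-site z-scores: means {4, 6} -> -1/sqrt(2), +1/sqrt(2)
  two <- data.frame(site_id = rep(c("A", "B"), each = 2), obs_year = rep(1:2, 2),
                    fall_rate_sum = c(3, 5, 5, 7), spring_rate_sum = c(1, 1, 2, 2))
  cb2 <- build_covariates(two, quiet = TRUE)
  expect_equal(sort(unique(cb2$covariates$fall_spatial)),
               c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # requesting a missing site-year errors and names it
  expect_error(build_covariates(seasonal,
                                site_years = data.frame(site_id = "S01", obs_year = 1999)),
               "S01 1999")
})

test_that("covariates are invariant to a common positive rescaling of rate sums", {
  set.seed(21)
  seasonal <- expand.grid(site_id = sprintf("S%02d", 1:8), obs_year = 2001:2006)
  seasonal$fall_rate_sum <- stats::rgamma(nrow(seasonal), 3, 1)
  seasonal$spring_rate_sum <- stats::rgamma(nrow(seasonal), 2, 1)
  a <- build_covariates(seasonal, quiet = TRUE)$covariates
  seasonal2 <- seasonal
  seasonal2$fall_rate_sum <- seasonal2$fall_rate_sum * 7.3
  seasonal2$spring_rate_sum <- seasonal2$spring_rate_sum * 7.3
  b <- build_covariates(seasonal2, quiet = TRUE)$covariates
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("frozen training constants reproduce training z-scores on reapplication", {
  set.seed(22)
  seasonal <- expand.grid(site_id = sprintf("S%02d", 1:10), obs_year = 2001:2005)
  seasonal$fall_rate_sum <- stats::rgamma(nrow(seasonal), 3, 1)
  seasonal$spring_rate_sum <- stats::rgamma(nrow(seasonal), 2, 1)
  cb <- build_covariates(seasonal, quiet = TRUE)
  again <- build_covariates(seasonal, constants = cb$constants, quiet = TRUE)
  expect_equal(cb$covariates, again$covariates, tolerance = 1e-12)
})

test_that("covariate screening ranks by |r| with alphabetical ties and constants last", {
  set.seed(23)
  n <- 1000
  cover <- data.frame(site_id = sprintf("S%04d", 1:n), obs_year = 2000L,
                      cover_percent = stats::runif(n, 0, 40))
  cand <- function(v) data.frame(site_id = cover$site_id, obs_year = 2000L, value = v)
  ranked <- screen_covariates(cover, list(
    self = cand(cover$cover_percent),
    anti = cand(-cover$cover_percent),
    noise = cand(stats::rnorm(n)),
    flat = cand(rep(2, n))))
  expect_equal(ranked$name[ranked$rank == 1], "anti")  # |r| = 1 tie, alphabetical
  expect_equal(ranked$name[ranked$rank == 2], "self")
  expect_equal(ranked$r[ranked$name == "self"], 1)
  expect_equal(abs(ranked$r[ranked$name == "anti"]), 1)
  expect_lt(ranked$abs_r[ranked$name == "noise"], 0.1)
  expect_true(is.na(ranked$r[ranked$name == "flat"]))
  expect_equal(ranked$rank[ranked$name == "flat"], 4L)
  expect_error(screen_covariates(cover, list(tiny = cand(1:n)[1:2, ])), "fewer than 3")
})
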