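# Builders for small in-code fixtures shared across test files.

# Constant-condition hourly series starting 2001-01-01 00:00.
make_series <- function(n_hours, temp = 20, psi = -0.1,
                        start = "2001-01-01 00:00:00", site_id = NULL) {
  ts <- seq(as.POSIXct(start, tz = "UTC"), by = 3600, length.out = n_hours)
  d <- data.frame(timestamp = ts,
                  soil_temp_c = rep_len(temp, n_hours),
                  soil_wp_mpa = rep_len(psi, n_hours))
  if (!is.null(site_id)) d <- cbind(data.frame(site_id = site_id), d)
  d
}

# Random hourly series with wet and dry spells and sub- and supra-zero
# temperatures, for oracle-equivalence checks.
random_series <- function(seed, n_hours = 500, start = "2003-01-01 00:00:00") {
  set.seed(seed)
  make_series(n_hours,
              temp = stats::runif(n_hours, -10, 50),
              psi = -stats::rexp(n_hours, rate = 1 / 1.2),
              start = start)
}

# Hour-by-hour loop oracle for rate sums, written independently of the
# package's vectorized path.
loop_rate_sum <- function(temp, psi, c0 = 1.29e-4, c1 = 6.16e-4, c2 = -1.25e-5,
                          thr = -1.25) {
  total <- 0
  for (i in seq_along(temp)) {
    if (temp[i] > 0 && psi[i] > thr) {
      r <- c0 + c1 * temp[i] + c2 * temp[i]^2
      if (r > 0) total <- total + r
    }
  }
  total
}

# Synthetic covariate table drawn directly on the covariate scale (bypassing
# the microclimate chain) for fast model-fitting tests.
make_cov_table <- function(n, seed = 1) {
  set.seed(seed)
  d <- data.frame(site_id = sprintf("S%04d", seq_len(n)),
                  obs_year = 2000L,
                  fall_spatial = pmax(-3, pmin(3, stats::rnorm(n))),
                  spring_spatial = pmax(-3, pmin(3, stats::rnorm(n))),
                  fall_temporal = pmax(-3, pmin(3, stats::rnorm(n))),
                  spring_temporal = pmax(-3, pmin(3, stats::rnorm(n))))
  d
}

# A null generative truth: every partial effect identically zero.
null_truth <- function(beta0 = 0) {
  synth_truth(beta0 = beta0, fall_spatial_curv = 0, spring_spatial_scale = 0,
              fall_temporal_scale = 0, spring_temporal_slope = 0)
}
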