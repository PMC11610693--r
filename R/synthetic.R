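#' Configuration for the synthetic site generator
#'
#' @param elevation_range_m numeric length-2, site elevation range (default
#'   800-2500 m, the elevation span typical of sagebrush-steppe monitoring
#'   networks).
#' @param slope_range_deg numeric length-2, slope range in degrees.
#' @param domain_km side length of the square planar study domain.
#' @return a list of generator settings.
#' @export
site_config <- function(elevation_range_m = c(800, 2500),
                        slope_range_deg = c(0, 30),
                        domain_km = 100) {
  list(elevation_range_m = elevation_range_m,
       slope_range_deg = slope_range_deg,
       domain_km = domain_km)
}

#' Generate synthetic field sites grouped into watersheds
#'
#' Sites get planar coordinates, elevation, aspect, slope, a soil-texture
#' triple, and a watershed label assigned by spatial (k-means) clustering of
#' their coordinates, so watersheds are contiguous groups usable as spatial
#' blocking units for train/test splits.
#'
#' @param n_sites number of sites (>= `n_watersheds`).
#' @param n_watersheds number of watershed units (>= 2).
#' @param seed integer seed; identical seed gives identical output.
#' @param config a [site_config()] list.
#' @return data frame with columns `site_id`, `x_km`, `y_km`, `elevation_m`,
#'   `aspect_deg`, `slope_deg`, `watershed_id`, `sand_frac`, `silt_frac`,
#'   `clay_frac`.
#' @export
generate_sites <- function(n_sites, n_watersheds, seed = 1L, config = site_config()) {
  if (!is_count(n_sites) || !is_count(n_watersheds) || n_sites < 1 || n_watersheds < 1)
    stop("`n_sites` and `n_watersheds` must be positive counts", call. = FALSE)
  if (n_sites < n_watersheds)
    stop("`n_sites` must be >= `n_watersheds`", call. = FALSE)
  if (n_watersheds < 2)
    stop("`n_watersheds` must be >= 2", call. = FALSE)
  with_seed(seed, {
    x <- stats::runif(n_sites, 0, config$domain_km)
    y <- stats::runif(n_sites, 0, config$domain_km)
    elev <- stats::runif(n_sites, config$elevation_range_m[1], config$elevation_range_m[2])
    aspect <- stats::runif(n_sites, 0, 360) %% 360
    slope <- stats::runif(n_sites, config$slope_range_deg[1], config$slope_range_deg[2])
    tex <- matrix(stats::rgamma(3L * n_sites, shape = 2), ncol = 3L)
    tex <- tex / rowSums(tex)
    ws <- if (n_watersheds == n_sites) seq_len(n_sites) else
      stats::kmeans(cbind(x, y), centers = n_watersheds, nstart = 5L,
                    iter.max = 50L)$cluster
    data.frame(
      site_id = sprintf("S%04d", seq_len(n_sites)),
      x_km = x, y_km = y,
      elevation_m = elev, aspect_deg = aspect, slope_deg = slope,
      watershed_id = sprintf("W%03d", ws),
      sand_frac = tex[, 1], silt_frac = tex[, 2], clay_frac = tex[, 3])
  })
}

#' Configuration for the soil-microclimate emulator
#'
#' The emulator is a statistical stand-in for a physical soil heat/water
#' simulator: it reproduces only the features the rate-sum method consumes.
#' Soil temperature at 2 cm = elevation-lapsed annual mean + seasonal cosine
#' (peak late July) + diurnal cosine (peak 14:00) + a south-facing aspect
#' term scaled by slope + AR(1) weather noise. Soil water potential follows
#' episodic wetting events (more frequent October-May) to a wet value with
#' exponential dry-down toward a dry floor, faster in warm months.
#'
#' @param mean_temp_sea_level_c annual-mean soil temperature extrapolated to
#'   sea level (degrees C).
#' @param lapse_rate_c_per_km decline of annual mean with elevation.
#' @param seasonal_amp_c amplitude of the annual temperature cycle.
#' @param seasonal_peak_doy day-of-year of the warmest soil (late July).
#' @param diurnal_amp_c amplitude of the diurnal cycle at 2 cm.
#' @param diurnal_peak_hour local hour of the daily maximum.
#' @param aspect_amp_c maximum aspect effect (south minus flat) for a
#'   90-degree slope; actual effect scales with `sin(slope)`.
#' @param ar1_sd_c stationary SD of the autocorrelated weather noise.
#' @param ar1_rho hourly lag-1 autocorrelation of the noise.
#' @param wet_psi_mpa water potential right after a wetting event (MPa).
#' @param dry_floor_mpa asymptotic dry-down floor (MPa).
#' @param wet_event_rate_per_day_wet wetting-event rate in the wet season
#'   (events/day, October-May).
#' @param wet_event_rate_per_day_dry wetting-event rate June-September.
#' @param wet_season_months months of the wet season.
#' @param drydown_tau_days e-folding dry-down time at 10 C (days).
#' @param drydown_q10 factor by which dry-down speeds up per 10 C warming.
#' @param trend_c_per_decade linear soil-warming trend applied within
#'   `trend_months` at sites below `trend_below_elevation_m` (default 0:
#'   stationary climate).
#' @param trend_months months receiving the warming trend.
#' @param trend_below_elevation_m elevation cutoff for the trend.
#' @return a list of emulator settings.
#' @export
microclimate_config <- function(mean_temp_sea_level_c = 16,
                                lapse_rate_c_per_km = 6.5,
                                seasonal_amp_c = 11,
                                seasonal_peak_doy = 205,
                                diurnal_amp_c = 7,
                                diurnal_peak_hour = 14,
                                aspect_amp_c = 5,
                                ar1_sd_c = 2.2,
                                ar1_rho = 0.97,
                                wet_psi_mpa = -0.03,
                                dry_floor_mpa = -8,
                                wet_event_rate_per_day_wet = 0.35,
                                wet_event_rate_per_day_dry = 0.06,
                                wet_season_months = c(10:12, 1:5),
                                drydown_tau_days = 9,
                                drydown_q10 = 2,
                                trend_c_per_decade = 0,
                                trend_months = 9:12,
                                trend_below_elevation_m = Inf) {
  cfg <- as.list(environment())
  if (cfg$wet_psi_mpa >= 0 || cfg$dry_floor_mpa >= cfg$wet_psi_mpa)
    stop("need dry_floor_mpa < wet_psi_mpa < 0", call. = FALSE)
  if (cfg$ar1_rho < 0 || cfg$ar1_rho >= 1) stop("`ar1_rho` must be in [0,1)", call. = FALSE)
  cfg
}

#' Simulate an hourly soil-microclimate series for one site
#'
#' Produces one record per hour over all full calendar years from
#' `start_year` to `end_year` (leap days included; timestamps are local,
#' timezone-free, with no daylight-saving discontinuities). See
#' [microclimate_config()] for the generative structure.
#'
#' @param site a single-row site record (as from [generate_sites()]).
#' @param start_year,end_year first and last calendar year (inclusive).
#' @param seed integer seed; identical seed gives an identical series.
#' @param config a [microclimate_config()] list.
#' @return data frame with columns `site_id`, `timestamp` (POSIXct, UTC
#'   convention), `soil_temp_c`, `soil_wp_mpa`.
#' @export
simulate_microclimate <- function(site, start_year, end_year, seed = 1L,
                                  config = microclimate_config()) {
  if (start_year > end_year) stop("`start_year` must be <= `end_year`", call. = FALSE)
  stopifnot(nrow(site) == 1L)
  t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", start_year), tz = "UTC")
  t1 <- as.POSIXct(sprintf("%d-12-31 23:00:00", end_year), tz = "UTC")
  ts <- seq(t0, t1, by = 3600)
  lt <- as.POSIXlt(ts, tz = "UTC")
  doy <- lt$yday + 1L
  hod <- lt$hour
  mon <- lt$mon + 1L
  yr <- lt$year + 1900L
  n <- length(ts)

  mean_t <- config$mean_temp_sea_level_c -
    config$lapse_rate_c_per_km * site$elevation_m / 1000
  seas <- config$seasonal_amp_c * cos(2 * pi * (doy - config$seasonal_peak_doy) / 365.25)
  diur <- config$diurnal_amp_c * cos(2 * pi * (hod - config$diurnal_peak_hour) / 24)
  aspect_term <- config$aspect_amp_c * sin(site$slope_deg * pi / 180) *
    cos((site$aspect_deg - 180) * pi / 180)
  trend <- if (config$trend_c_per_decade != 0 &&
               site$elevation_m < config$trend_below_elevation_m) {
    ifelse(mon %in% config$trend_months,
           config$trend_c_per_decade * (yr - start_year) / 10, 0)
  } else 0

  with_seed(seed, {
    innov_sd <- config$ar1_sd_c * sqrt(1 - config$ar1_rho^2)
    noise <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd),
                                      config$ar1_rho, method = "recursive"))
    temp <- mean_t + seas + diur + aspect_term + trend + noise

    # wetting events: hourly Bernoulli at a season-dependent daily rate
    wet_season <- mon %in% config$wet_season_months
    p_event <- ifelse(wet_season,
                      config$wet_event_rate_per_day_wet,
                      config$wet_event_rate_per_day_dry) / 24
    event <- stats::runif(n) < p_event
    event[1] <- TRUE  # initialize wet; dry-down proceeds from there

    # dry-down rate (per hour) speeds up with the seasonal temperature
    tau_h <- config$drydown_tau_days * 24 *
      config$drydown_q10^(-(mean_t + seas - 10) / 10)
    k <- 1 / tau_h
    S <- cumsum(k)
    ev_idx <- which(event)
    last_ev <- ev_idx[findInterval(seq_len(n), ev_idx)]
    psi <- config$dry_floor_mpa + (config$wet_psi_mpa - config$dry_floor_mpa) *
      exp(-(S - S[last_ev]))
    psi <- pmin(pmax(psi, config$dry_floor_mpa), config$wet_psi_mpa)

    data.frame(site_id = site$site_id, timestamp = ts,
               soil_temp_c = temp, soil_wp_mpa = psi)
  })
}

#' Generative truth for synthetic presence/cover observations
#'
#' Encodes the qualitative partial-effect shapes the presence and cover
#' models should recover from the four rate-sum covariates: a concave-down
#' quadratic in the fall spatial covariate, an increasing saturating effect
#' of the spring spatial covariate, an increasing concave-down effect of the
#' fall anomaly, and a decreasing linear effect of the spring anomaly.
#'
#' Defaults put the mean presence probability near 0.5 (about the presence
#' frequency of regional cheatgrass field datasets) with a combined
#' linear-predictor SD near 2 on the logit scale.
#'
#' @param beta0 intercept on the logit scale.
#' @param fall_spatial_peak,fall_spatial_curv peak location and curvature of
#'   the fall spatial quadratic `-curv * (x - peak)^2`.
#' @param spring_spatial_scale,spring_spatial_rate saturating effect
#'   `scale * tanh(rate * x)`.
#' @param fall_temporal_scale,fall_temporal_shift concave increasing effect
#'   `scale * sqrt(x + shift)` (shift > 3 keeps it defined on [-3, 3]).
#' @param spring_temporal_slope slope of the decreasing linear effect.
#' @param cover_intercept,cover_gain,cover_sd mean percent cover at null
#'   effects, gain applied to the summed effects, and Gaussian noise SD of
#'   the cover model.
#' @param min_presence_cover floor applied to generated presence-site cover
#'   (just above the 2 percent presence cutoff), so generated presences stay
#'   presences when relabeled from cover.
#' @return an object of class `synth_truth`.
#' @export
synth_truth <- function(beta0 = -1.3,
                        fall_spatial_peak = 0.5, fall_spatial_curv = 1.1,
                        spring_spatial_scale = 1.6, spring_spatial_rate = 1,
                        fall_temporal_scale = 1.5, fall_temporal_shift = 3.5,
                        spring_temporal_slope = -0.9,
                        cover_intercept = 12, cover_gain = 4, cover_sd = 6,
                        min_presence_cover = 2.05) {
  if (cover_sd <= 0) stop("`cover_sd` must be > 0", call. = FALSE)
  if (fall_temporal_shift <= 3) stop("`fall_temporal_shift` must exceed 3", call. = FALSE)
  tr <- as.list(environment())
  structure(tr, class = "synth_truth")
}

# Evaluate the four uncentered true effect functions at covariate values x.
truth_effect <- function(truth, term, x) {
  switch(term,
    fall_spatial = -truth$fall_spatial_curv * (x - truth$fall_spatial_peak)^2,
    spring_spatial = truth$spring_spatial_scale * tanh(truth$spring_spatial_rate * x),
    fall_temporal = truth$fall_temporal_scale * sqrt(pmax(x + truth$fall_temporal_shift, 0)),
    spring_temporal = truth$spring_temporal_slope * x,
    stop("unknown term: ", term, call. = FALSE))
}

covariate_terms <- c("fall_spatial", "spring_spatial", "fall_temporal", "spring_temporal")

#' True partial-effect curves on a grid
#'
#' Evaluates each generative effect function on a grid and centers it to
#' mean zero over the grid, matching the sum-to-zero centering of fitted
#' smooth terms so fitted and true curves are directly comparable.
#'
#' @param truth a [synth_truth()] object.
#' @param grid numeric vector of covariate values within [-3, 3].
#' @return data frame with columns `term`, `x`, `effect`.
#' @export
truth_partial_effects <- function(truth, grid) {
  if (any(grid < -3 | grid > 3)) stop("`grid` must lie within [-3, 3]", call. = FALSE)
  out <- lapply(covariate_terms, function(tm) {
    f <- truth_effect(truth, tm, grid)
    data.frame(term = tm, x = grid, effect = f - mean(f))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate presence/cover observations from covariates and a known truth
#'
#' Presence is drawn Bernoulli with logit equal to `beta0` plus the four
#' true effects evaluated at the row's covariates. Absences get zero cover;
#' presences get Gaussian cover around a linear-plus-smooth mean, floored at
#' 0 and capped at 100. The final `presence` flag is relabeled from the
#' realized cover (> 2 percent), mirroring how field presence is derived
#' from cover.
#'
#' @param covariates data frame with `site_id`, `obs_year` and the four
#'   covariate columns (see [build_covariates()]).
#' @param truth a [synth_truth()] object.
#' @param seed integer seed.
#' @return data frame `site_id`, `obs_year`, `cover_percent`, `presence`.
#' @export
simulate_observations <- function(covariates, truth = synth_truth(), seed = 1L) {
  miss <- setdiff(covariate_terms, names(covariates))
  if (length(miss)) stop("covariates lack fields: ", paste(miss, collapse = ", "), call. = FALSE)
  X <- covariates[, covariate_terms]
  if (any(!is.finite(as.matrix(X)))) stop("non-finite covariate values", call. = FALSE)
  effmat <- vapply(covariate_terms, function(tm) truth_effect(truth, tm, X[[tm]]),
                   numeric(nrow(covariates)))
  if (is.null(dim(effmat))) effmat <- matrix(effmat, nrow = 1L)
  eff <- rowSums(effmat)
  lp <- truth$beta0 + eff
  with_seed(seed, {
    n <- nrow(covariates)
    pres <- stats::rbinom(n, 1L, stats::plogis(lp)) == 1L
    cover <- numeric(n)
    if (any(pres)) {
      mu <- truth$cover_intercept + truth$cover_gain * (eff[pres] - mean(eff))
      cover[pres] <- pmin(100, pmax(truth$min_presence_cover,
                                    stats::rnorm(sum(pres), mu, truth$cover_sd)))
    }
    data.frame(site_id = covariates$site_id, obs_year = covariates$obs_year,
               cover_percent = cover, presence = cover > 2)
  })
}
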