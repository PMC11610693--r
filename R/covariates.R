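#' Spatially scale site-level means to across-site z-scores
#'
#' Converts site climatology (long-term mean seasonal rate sums) to z-scores
#' across sites: a site at 0 has average seedbed favorability relative to
#' the reference site set. When `constants` are supplied (e.g., frozen from
#' a training set) they are applied unchanged, so new sites are scored on
#' the training scale with no re-centering.
#'
#' @param site_means named numeric vector of per-site values.
#' @param constants optional list with `mean` and `sd` to apply; when NULL
#'   they are computed from `site_means` (sample SD, n-1).
#' @return list with `z` (named numeric) and `constants`.
#' @export
spatial_scale <- function(site_means, constants = NULL) {
  if (is.null(constants)) {
    if (length(site_means) < 2L)
      stop("need >= 2 sites to compute spatial scaling constants", call. = FALSE)
    constants <- list(mean = mean(site_means), sd = stats::sd(site_means))
  }
  if (!is.finite(constants$sd) || constants$sd <= 0)
    stop("degenerate spatial covariate: across-site SD is zero", call. = FALSE)
  list(z = (site_means - constants$mean) / constants$sd, constants = constants)
}

#' Temporally scale site-year values to within-site anomalies
#'
#' z-scores each site's yearly values against that site's own across-year
#' mean and sample SD: an anomaly of 0 means average conditions for that
#' site. Sites with a single year or zero across-year SD (e.g., identically
#' zero rate sums at cold sites) get anomaly 0 for all years, which encodes
#' "average for this site".
#'
#' @param site_year_values data frame with columns `site_id`, `year`,
#'   `value`.
#' @param quiet suppress the message listing zero-SD sites.
#' @return the input with an added `anomaly` column.
#' @export
temporal_scale <- function(site_year_values, quiet = FALSE) {
  need <- c("site_id", "year", "value")
  if (!all(need %in% names(site_year_values)))
    stop("`site_year_values` must have site_id, year, value", call. = FALSE)
  df <- site_year_values
  mu <- tapply(df$value, df$site_id, mean)
  sdv <- tapply(df$value, df$site_id, stats::sd)  # NA for single-year sites
  sid <- as.character(df$site_id)
  anom <- (df$value - mu[sid]) / sdv[sid]
  flat <- !is.finite(anom)
  anom[flat] <- 0
  if (any(flat) && !quiet) {
    degen <- unique(sid[flat])
    message("temporal anomalies set to 0 for ", length(degen),
            " site(s) with a single year or zero across-year SD")
  }
  df$anomaly <- as.numeric(anom)
  df
}

#' Build the four rate-sum model covariates
#'
#' From per site-year seasonal rate sums, builds the covariate table used by
#' the presence and cover models: `fall_spatial` and `spring_spatial` are
#' across-site z-scores of the site-mean fall and spring rate sums (between-
#' site climate), and `fall_temporal` and `spring_temporal` are within-site
#' z-scores of the site-year values (weather anomalies). Site means and
#' within-site statistics are computed over the full reference period
#' present in `seasonal`, not only observed years.
#'
#' @param seasonal data frame from [seasonal_rate_sums()] covering the full
#'   reference period for every site.
#' @param site_years optional data frame with `site_id`, `obs_year` naming
#'   the rows to return (default: every site-year in `seasonal`). A
#'   requested site-year absent from `seasonal` is an error.
#' @param constants optional [scaling constants][build_covariates] returned
#'   by a previous call (e.g., on training sites); applied frozen. Sites
#'   absent from frozen per-site statistics get them computed from
#'   `seasonal` (within-site statistics are intrinsic to a site).
#' @param quiet passed to [temporal_scale()].
#' @return list with `covariates` (data frame: `site_id`, `obs_year`, the
#'   four covariate columns) and `constants` (list with `spatial`, a
#'   per-season mean/sd pair; `temporal`, a per-site statistics table; and
#'   `site_set`, the sites that defined the spatial constants).
#' @export
build_covariates <- function(seasonal, site_years = NULL, constants = NULL,
                             quiet = FALSE) {
  need <- c("site_id", "obs_year", "fall_rate_sum", "spring_rate_sum")
  if (!all(need %in% names(seasonal)))
    stop("`seasonal` must have ", paste(need, collapse = ", "), call. = FALSE)
  seasonal$site_id <- as.character(seasonal$site_id)

  site_mean_fall <- tapply(seasonal$fall_rate_sum, seasonal$site_id, mean)
  site_mean_spring <- tapply(seasonal$spring_rate_sum, seasonal$site_id, mean)

  if (is.null(constants)) {
    sf <- spatial_scale(site_mean_fall)
    ss <- spatial_scale(site_mean_spring)
    spatial <- list(fall = sf$constants, spring = ss$constants)
    site_set <- names(site_mean_fall)
  } else {
    spatial <- constants$spatial
    site_set <- constants$site_set
  }
  z_fall <- spatial_scale(site_mean_fall, spatial$fall)$z
  z_spring <- spatial_scale(site_mean_spring, spatial$spring)$z

  tf <- temporal_scale(data.frame(site_id = seasonal$site_id,
                                  year = seasonal$obs_year,
                                  value = seasonal$fall_rate_sum), quiet = quiet)
  tsp <- temporal_scale(data.frame(site_id = seasonal$site_id,
                                   year = seasonal$obs_year,
                                   value = seasonal$spring_rate_sum), quiet = TRUE)

  all_rows <- data.frame(
    site_id = seasonal$site_id, obs_year = seasonal$obs_year,
    fall_spatial = as.numeric(z_fall[seasonal$site_id]),
    spring_spatial = as.numeric(z_spring[seasonal$site_id]),
    fall_temporal = tf$anomaly, spring_temporal = tsp$anomaly)

  if (!is.null(site_years)) {
    key <- paste(all_rows$site_id, all_rows$obs_year)
    want <- paste(as.character(site_years$site_id), site_years$obs_year)
    miss <- setdiff(want, key)
    if (length(miss))
      stop("requested site-years missing from seasonal table: ",
           paste(utils::head(miss, 10L), collapse = ", "),
           if (length(miss) > 10L) " ..." else "", call. = FALSE)
    all_rows <- all_rows[match(want, key), ]
    rownames(all_rows) <- NULL
  }

  temporal_stats <- data.frame(
    site_id = names(site_mean_fall),
    fall_mean = as.numeric(site_mean_fall),
    spring_mean = as.numeric(site_mean_spring),
    fall_sd = as.numeric(tapply(seasonal$fall_rate_sum, seasonal$site_id, stats::sd)),
    spring_sd = as.numeric(tapply(seasonal$spring_rate_sum, seasonal$site_id, stats::sd)))

  list(covariates = all_rows,
       constants = list(spatial = spatial, temporal = temporal_stats,
                        site_set = site_set))
}

#' Rank candidate covariates by correlation with cover
#'
#' The screening step used to choose which monthly/seasonal rate-sum
#' groupings enter the model: Pearson correlation of each candidate with
#' percent cover, ranked by absolute value (ties broken alphabetically by
#' candidate name). Constant candidates have undefined correlation and rank
#' last.
#'
#' @param cover data frame with `site_id`, `obs_year`, `cover_percent`.
#' @param candidates named list of data frames, each with `site_id`,
#'   `obs_year`, `value`.
#' @return data frame `name`, `r`, `abs_r`, `n`, `rank`, sorted by rank.
#' @export
screen_covariates <- function(cover, candidates) {
  if (!length(candidates) || is.null(names(candidates)))
    stop("`candidates` must be a non-empty named list", call. = FALSE)
  rows <- lapply(names(candidates), function(nm) {
    cand <- candidates[[nm]]
    m <- merge(cover[, c("site_id", "obs_year", "cover_percent")],
               cand[, c("site_id", "obs_year", "value")],
               by = c("site_id", "obs_year"))
    m <- m[stats::complete.cases(m), ]
    if (nrow(m) < 3L)
      stop("candidate '", nm, "' has fewer than 3 complete pairs", call. = FALSE)
    r <- if (stats::sd(m$value) == 0 || stats::sd(m$cover_percent) == 0) NA_real_
         else stats::cor(m$cover_percent, m$value)
    data.frame(name = nm, r = r, n = nrow(m))
  })
  out <- do.call(rbind, rows)
  out$abs_r <- abs(out$r)
  ord <- order(-ifelse(is.na(out$abs_r), -Inf, out$abs_r), out$name)
  out <- out[ord, c("name", "r", "abs_r", "n")]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
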