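#' Stratify sites by elevation tercile and aspect class
#'
#' Elevation terciles (low/mid/high) are assigned by elevation rank over
#' the dataset, ties broken by `site_id`, with group sizes differing by at
#' most one (extra sites go to the lower strata first). Aspect classes use
#' azimuth quarters: N = [315,360) u [0,45), E = [45,135), S = [135,225),
#' W = [225,315).
#'
#' @param sites data frame with `site_id`, `elevation_m`, `aspect_deg`.
#' @return data frame `site_id`, `elevation_tercile` (factor low/mid/high),
#'   `aspect_class` (factor N/E/S/W).
#' @export
stratify_sites <- function(sites) {
  if (nrow(sites) < 3L) stop("need >= 3 sites to form terciles", call. = FALSE)
  ord <- order(sites$elevation_m, sites$site_id)
  n <- nrow(sites)
  base <- n %/% 3L; extra <- n %% 3L
  sizes <- rep(base, 3L) + (seq_len(3L) <= extra)
  terc <- rep(c("low", "mid", "high"), times = sizes)
  tercile <- character(n)
  tercile[ord] <- terc
  a <- sites$aspect_deg %% 360
  aspect <- ifelse(a >= 315 | a < 45, "N",
            ifelse(a < 135, "E", ifelse(a < 225, "S", "W")))
  data.frame(site_id = sites$site_id,
             elevation_tercile = factor(tercile, levels = c("low", "mid", "high")),
             aspect_class = factor(aspect, levels = c("N", "E", "S", "W")))
}

#' Annual predicted-occupancy fractions by stratum
#'
#' Applies the fitted presence model to every site-year of the hindcast
#' window and reports, per stratum and year, the fraction of its sites
#' predicted present (probability strictly above the threshold).
#'
#' @param model a fitted binomial `rs_gam`.
#' @param covariates covariate data frame covering every (site, year) of
#'   the window; missing site-years are an error.
#' @param strata data frame from [stratify_sites()].
#' @param threshold probability threshold (default 0.5).
#' @param by_aspect if TRUE strata are tercile x aspect; otherwise
#'   tercile only.
#' @return data frame `stratum`, `elevation_tercile`, `aspect_class` (NA
#'   when `by_aspect = FALSE`), `year`, `n_sites`, `fraction_occupied`.
#' @export
annual_occupancy <- function(model, covariates, strata, threshold = 0.5,
                             by_aspect = TRUE) {
  stopifnot(inherits(model, "rs_gam"))
  if (model$family != "binomial") stop("occupancy requires the presence model", call. = FALSE)
  d <- merge(covariates, strata, by = "site_id")
  if (nrow(d) < nrow(covariates))
    stop("covariate rows reference sites missing from `strata`", call. = FALSE)
  years <- sort(unique(d$obs_year))
  tab <- table(d$site_id)
  bad <- names(tab)[tab != length(years)]
  if (length(bad))
    stop("missing site-years in hindcast window for: ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "", call. = FALSE)
  pred <- predict(model, d, threshold = threshold)
  d$occ <- pred$probability > threshold
  group <- if (by_aspect)
    interaction(d$elevation_tercile, d$aspect_class, d$obs_year, drop = TRUE, sep = "|")
  else
    interaction(d$elevation_tercile, d$obs_year, drop = TRUE, sep = "|")
  agg <- tapply(d$occ, group, mean)
  cnt <- tapply(d$occ, group, length)
  parts <- strsplit(names(agg), "|", fixed = TRUE)
  out <- data.frame(
    elevation_tercile = vapply(parts, `[`, "", 1L),
    aspect_class = if (by_aspect) vapply(parts, `[`, "", 2L) else NA_character_,
    year = as.integer(vapply(parts, function(p) p[length(p)], "")),
    n_sites = as.integer(cnt),
    fraction_occupied = as.numeric(agg))
  out$stratum <- if (by_aspect)
    paste(out$elevation_tercile, out$aspect_class, sep = "-")
  else out$elevation_tercile
  out <- out[order(out$stratum, out$year),
             c("stratum", "elevation_tercile", "aspect_class", "year",
               "n_sites", "fraction_occupied")]
  rownames(out) <- NULL
  out
}

#' Linear occupancy trend per stratum
#'
#' Ordinary least-squares slope of the occupancy fraction on year, per
#' stratum, with the relative change over the window computed from the
#' fitted line's endpoints: `100 * (fit_end - fit_start) / fit_start`
#' (undefined when the fitted start is <= 0). The raw-endpoint variant is
#' selectable.
#'
#' @param series data frame from [annual_occupancy()].
#' @param endpoints `"fitted"` (default) or `"raw"` first/last years.
#' @return data frame `stratum`, `n_years`, `slope_per_year`,
#'   `fit_start`, `fit_end`, `relative_change_pct`.
#' @export
trend_estimate <- function(series, endpoints = c("fitted", "raw")) {
  endpoints <- match.arg(endpoints)
  rows <- lapply(split(series, series$stratum), function(s) {
    if (nrow(s) < 3L) stop("need >= 3 years per stratum", call. = FALSE)
    fit <- stats::lm(fraction_occupied ~ year, data = s)
    yr <- range(s$year)
    ends <- if (endpoints == "fitted")
      as.numeric(stats::predict(fit, data.frame(year = yr)))
    else
      c(s$fraction_occupied[which.min(s$year)], s$fraction_occupied[which.max(s$year)])
    rel <- if (ends[1] > 0) 100 * (ends[2] - ends[1]) / ends[1] else NA_real_
    data.frame(stratum = s$stratum[1], n_years = nrow(s),
               slope_per_year = unname(stats::coef(fit)[2]),
               fit_start = ends[1], fit_end = ends[2],
               relative_change_pct = rel)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
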