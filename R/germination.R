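#' Wet-thermal germination rate parameters
#'
#' Parameters of the hourly wet-thermal germination-rate curve for the 35%
#' subpopulation of a cheatgrass seed lot. Germination progress accrues as a
#' polynomial function of soil temperature, but only during hours when the
#' soil is both above a base temperature and wetter than a water-potential
#' threshold; outside those conditions the rate is zero.
#'
#' The default coefficients give the concave-down quadratic
#' \deqn{rate(T) = 1.29\times10^{-4} + 6.16\times10^{-4} T - 1.25\times10^{-5} T^2,}
#' per hour, with an optimum near 24.6 C. A literal linear reading of the
#' same three printed coefficients, \eqn{c_0 + T (c_1 + c_2)}, is selectable
#' via `poly_form = "linear"`; both agree in the limit T -> 0+.
#'
#' @param poly_coeffs numeric length-3 vector `(c0, c1, c2)`: intercept,
#'   linear, and quadratic temperature coefficients (per hour).
#' @param wet_threshold_mpa water-potential wetness threshold in MPa
#'   (default -1.25); hours at or below it contribute nothing.
#' @param base_temp_c base temperature in degrees C (default 0); hours at or
#'   below it contribute nothing.
#' @param poly_form `"quadratic"` (default) or `"linear"` term structure.
#' @param subpopulation_frac seed-lot fraction the curve indexes (metadata
#'   only; default 0.35).
#' @return an object of class `rate_params`.
#' @examples
#' p <- rate_params()
#' germination_rate(20, -0.1, p)   # 0.007449
#' @export
rate_params <- function(poly_coeffs = c(1.29e-4, 6.16e-4, -1.25e-5),
                        wet_threshold_mpa = -1.25,
                        base_temp_c = 0,
                        poly_form = c("quadratic", "linear"),
                        subpopulation_frac = 0.35) {
  poly_form <- match.arg(poly_form)
  if (length(poly_coeffs) != 3L || !is.numeric(poly_coeffs) || any(!is.finite(poly_coeffs)))
    stop("`poly_coeffs` must be three finite numbers (c0, c1, c2)", call. = FALSE)
  if (!is.numeric(wet_threshold_mpa) || wet_threshold_mpa >= 0)
    stop("`wet_threshold_mpa` must be negative (MPa; wet = less negative)", call. = FALSE)
  structure(
    list(poly_coeffs = as.numeric(poly_coeffs),
         wet_threshold_mpa = wet_threshold_mpa,
         base_temp_c = base_temp_c,
         poly_form = poly_form,
         subpopulation_frac = subpopulation_frac),
    class = "rate_params")
}

#' Hourly wet-thermal germination rate
#'
#' Evaluates the germination-rate curve at given soil temperature and water
#' potential. The rate is strictly zero unless `soil_temp_c > base_temp_c`
#' and `soil_wp_mpa > wet_threshold_mpa` (both strict); a negative polynomial
#' value (possible at supra-optimal temperatures) is clipped to zero.
#'
#' @param soil_temp_c soil temperature at 2 cm, degrees C (vectorized).
#' @param soil_wp_mpa soil water potential at 2 cm, MPa (vectorized).
#' @param params a [rate_params()] object.
#' @return numeric vector of per-hour germination rates (>= 0).
#' @export
germination_rate <- function(soil_temp_c, soil_wp_mpa, params = rate_params()) {
  if (!inherits(params, "rate_params")) stop("`params` must be a rate_params object", call. = FALSE)
  if (any(!is.finite(soil_temp_c)) || any(!is.finite(soil_wp_mpa)))
    stop("non-finite soil temperature or water potential", call. = FALSE)
  n <- max(length(soil_temp_c), length(soil_wp_mpa))
  Tt <- rep_len(soil_temp_c, n)
  psi <- rep_len(soil_wp_mpa, n)
  cf <- params$poly_coeffs
  r <- if (params$poly_form == "quadratic")
    cf[1] + cf[2] * Tt + cf[3] * Tt^2
  else
    cf[1] + (cf[2] + cf[3]) * Tt
  r <- pmax(r, 0)
  r[Tt <= params$base_temp_c | psi <= params$wet_threshold_mpa] <- 0
  r
}

# Validate an hourly microclimate series: required columns, strictly
# increasing hourly timestamps with no gaps, non-positive water potential.
check_microclimate <- function(series) {
  need <- c("timestamp", "soil_temp_c", "soil_wp_mpa")
  miss <- setdiff(need, names(series))
  if (length(miss)) stop("microclimate series lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  ts <- series$timestamp
  if (!inherits(ts, "POSIXct")) stop("`timestamp` must be POSIXct", call. = FALSE)
  if (nrow(series) > 1L) {
    d <- diff(as.numeric(ts))
    bad <- which(d != 3600)
    if (length(bad)) {
      stop(sprintf("non-hourly spacing in series: first gap after %s (%.0f s)",
                   format(ts[bad[1]], tz = "UTC", usetz = FALSE), d[bad[1]]),
           call. = FALSE)
    }
  }
  if (any(!is.finite(series$soil_temp_c)))
    stop("non-finite soil temperature in series", call. = FALSE)
  if (any(series$soil_wp_mpa > 0))
    stop("positive soil water potential in series (psi must be <= 0 MPa)", call. = FALSE)
  invisible(series)
}

#' Hourly germination rates for a microclimate series
#'
#' Elementwise application of [germination_rate()] to an hourly series. The
#' series must have strictly increasing, gap-free hourly timestamps.
#'
#' @param series data frame with columns `timestamp` (POSIXct, hourly),
#'   `soil_temp_c`, `soil_wp_mpa` (and optionally `site_id`).
#' @param params a [rate_params()] object.
#' @return numeric vector of per-hour rates aligned to `series$timestamp`.
#' @export
hourly_rates <- function(series, params = rate_params()) {
  check_microclimate(series)
  germination_rate(series$soil_temp_c, series$soil_wp_mpa, params)
}

#' Germination rate sum over a time window
#'
#' Sums hourly germination rates over the half-open window
#' `[start, end)`. The rate sum is a dimensionless index of seedbed
#' favorability: how many times over the window conditions would have carried
#' the indexed subpopulation to germination. Rate sums over disjoint windows
#' add; hours failing the wet-thermal conditions contribute zero, so no
#' sequential-wetting reset is applied.
#'
#' @param series hourly microclimate data frame (see [hourly_rates()]).
#' @param window length-2 POSIXct (or coercible) vector `(start, end)`,
#'   half-open on the right.
#' @param params a [rate_params()] object.
#' @return a single non-negative number; 0 if no hours fall in the window
#'   (with a warning when the window is not fully covered by the series).
#' @export
rate_sum <- function(series, window, params = rate_params()) {
  check_microclimate(series)
  if (length(window) != 2L) stop("`window` must be (start, end)", call. = FALSE)
  window <- as.POSIXct(window, tz = "UTC")
  if (!(window[1] < window[2])) stop("`window` must be non-empty (start < end)", call. = FALSE)
  ts <- series$timestamp
  if (window[1] < ts[1] || window[2] > ts[length(ts)] + 3600)
    warning("window extends beyond the series' coverage; only covered hours are summed",
            call. = FALSE)
  keep <- ts >= window[1] & ts < window[2]
  if (!any(keep)) return(0)
  sum(germination_rate(series$soil_temp_c[keep], series$soil_wp_mpa[keep], params))
}

#' Monthly germination rate sums
#'
#' Accumulates hourly rates into calendar-month rate sums. Partial months at
#' the series boundaries are dropped with a warning; leap-year Februaries
#' contribute all 29 x 24 hours. The monthly sums partition the annual sum.
#'
#' @param series hourly microclimate data frame; may carry a `site_id`
#'   column (constant), propagated to the output.
#' @param params a [rate_params()] object.
#' @return data frame with columns `site_id` (if present), `year`, `month`,
#'   `rate_sum`, one row per complete calendar month covered.
#' @export
monthly_rate_sums <- function(series, params = rate_params()) {
  check_microclimate(series)
  lt <- as.POSIXlt(series$timestamp, tz = "UTC")
  yr <- lt$year + 1900L
  mo <- lt$mon + 1L
  ym <- yr * 12L + mo
  rates <- germination_rate(series$soil_temp_c, series$soil_wp_mpa, params)
  cnt <- tapply(rates, ym, length)
  sums <- tapply(rates, ym, sum)
  ymu <- as.integer(names(sums))
  y <- (ymu - 1L) %/% 12L
  m <- ymu - y * 12L
  full <- as.integer(cnt) == days_in_month(y, m) * 24L
  if (any(!full))
    warning(sprintf("dropping %d partial boundary month(s): %s", sum(!full),
                    paste(sprintf("%d-%02d", y[!full], m[!full]), collapse = ", ")),
            call. = FALSE)
  out <- data.frame(year = y[full], month = m[full],
                    rate_sum = as.numeric(sums)[full])
  if (!is.null(series$site_id)) {
    sid <- unique(series$site_id)
    if (length(sid) != 1L) stop("series must contain a single site_id", call. = FALSE)
    out <- cbind(data.frame(site_id = sid), out)
  }
  rownames(out) <- NULL
  out
}

#' Seasonal (fall and spring) rate sums per observation year
#'
#' Attaches to each observation year the late-fall (October-December of the
#' preceding calendar year) and spring (March of the observation year) rate
#' sums: the seedbed conditions immediately preceding a growing-season field
#' observation. Observation years whose constituent months are missing are
#' omitted with a warning.
#'
#' @param monthly data frame from [monthly_rate_sums()], with `site_id`,
#'   `year`, `month`, `rate_sum` (possibly several sites stacked).
#' @param obs_years integer vector of observation years to attach sums to.
#' @return data frame with columns `site_id`, `obs_year`, `fall_rate_sum`,
#'   `spring_rate_sum`.
#' @export
seasonal_rate_sums <- function(monthly, obs_years) {
  need <- c("year", "month", "rate_sum")
  if (!all(need %in% names(monthly))) stop("`monthly` must have year, month, rate_sum", call. = FALSE)
  if (is.null(monthly$site_id)) monthly$site_id <- "site"
  obs_years <- sort(unique(as.integer(obs_years)))
  out <- vector("list", 0L)
  dropped <- character(0)
  for (sid in unique(monthly$site_id)) {
    ms <- monthly[monthly$site_id == sid, ]
    key <- paste(ms$year, ms$month)
    val <- stats::setNames(ms$rate_sum, key)
    for (y in obs_years) {
      fall_keys <- paste(y - 1L, 10:12)
      spring_key <- paste(y, 3L)
      if (all(fall_keys %in% key) && spring_key %in% key) {
        out[[length(out) + 1L]] <- data.frame(
          site_id = sid, obs_year = y,
          fall_rate_sum = sum(val[fall_keys]),
          spring_rate_sum = as.numeric(val[spring_key]))
      } else {
        dropped <- c(dropped, sprintf("%s:%d", sid, y))
      }
    }
  }
  if (length(dropped))
    warning("omitting site-years with incomplete seasonal months: ",
            paste(utils::head(dropped, 10L), collapse = ", "),
            if (length(dropped) > 10L) " ..." else "", call. = FALSE)
  if (!length(out))
    return(data.frame(site_id = character(0), obs_year = integer(0),
                      fall_rate_sum = numeric(0), spring_rate_sum = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
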