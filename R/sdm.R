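#' GAM fitting settings
#'
#' @param k basis dimension per smooth term (default 10).
#' @param criterion smoothness-selection criterion: `"REML"` (default) or
#'   `"GCV.Cp"`.
#' @param threshold classification probability threshold for presence
#'   labels (default 0.5; labels use a strict `>`).
#' @param select apply double-penalty shrinkage (Marra & Wood) so smooths of
#'   uninformative covariates can be penalized to flat (default TRUE).
#' @return a list of settings.
#' @export
gam_config <- function(k = 10, criterion = c("REML", "GCV.Cp"), threshold = 0.5,
                       select = TRUE) {
  criterion <- match.arg(criterion)
  if (!is_count(k) || k < 3) stop("`k` must be an integer >= 3", call. = FALSE)
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0,1)", call. = FALSE)
  list(k = k, criterion = criterion, threshold = threshold, select = isTRUE(select))
}

rs_formula <- function(response, k) {
  stats::as.formula(paste(
    response, "~",
    paste(sprintf("s(%s, bs = 'cr', k = %d)", covariate_terms, k), collapse = " + ")))
}

# Even knot placement through each covariate's observed range, so spline
# flexibility is spread across all covariate values rather than concentrated
# where data are dense.
even_knots <- function(data, k) {
  kn <- lapply(covariate_terms, function(tm)
    seq(min(data[[tm]]), max(data[[tm]]), length.out = k))
  names(kn) <- covariate_terms
  kn
}

fit_rs_gam <- function(data, response, family, config) {
  fit <- mgcv::gam(rs_formula(response, config$k), family = family,
                   data = data, method = config$criterion,
                   select = config$select,
                   knots = even_knots(data, config$k))
  if (!fit$converged)
    stop("GAM fit did not converge (", family$family, "); check data and basis dimension",
         call. = FALSE)
  ranges <- lapply(data[covariate_terms], range)
  structure(
    list(fit = fit, family = family$family, config = config,
         terms = covariate_terms, ranges = ranges, n = nrow(data)),
    class = "rs_gam")
}

check_cov_input <- function(covariates) {
  miss <- setdiff(covariate_terms, names(covariates))
  if (length(miss)) stop("unknown/missing covariate terms; need: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(as.matrix(covariates[, covariate_terms]))))
    stop("non-finite covariate values", call. = FALSE)
  invisible(covariates)
}

#' Fit the binomial presence model
#'
#' Penalized-likelihood fit of
#' `logit P(presence) = a + s(fall_spatial) + s(spring_spatial) +
#' s(fall_temporal) + s(spring_temporal)`, each `s` a cubic regression
#' spline with `k` evenly spread knots. Deterministic given data and
#' config.
#'
#' @param covariates covariate data frame (four covariate columns).
#' @param presence logical (or 0/1) presence labels.
#' @param config a [gam_config()] list.
#' @return an object of class `rs_gam`.
#' @export
fit_presence <- function(covariates, presence, config = gam_config()) {
  check_cov_input(covariates)
  presence <- as.logical(presence)
  if (length(presence) != nrow(covariates))
    stop("`presence` length must match covariate rows", call. = FALSE)
  tab <- table(presence)
  if (length(tab) < 2L) stop("presence labels contain a single class", call. = FALSE)
  if (any(tab < 20L)) stop("need >= 20 rows per class to fit the presence model", call. = FALSE)
  d <- covariates[, covariate_terms]
  d$presence <- as.integer(presence)
  fit_rs_gam(d, "presence", stats::binomial(), config)
}

#' Fit the Gaussian cover (abundance) model
#'
#' Same additive structure as [fit_presence()] with an identity link and
#' Gaussian errors; the response is raw percent cover, fitted on all
#' observations including zeros.
#'
#' @param covariates covariate data frame.
#' @param cover_percent numeric percent cover in [0, 100].
#' @param config a [gam_config()] list.
#' @return an object of class `rs_gam`.
#' @export
fit_abundance <- function(covariates, cover_percent, config = gam_config()) {
  check_cov_input(covariates)
  if (length(cover_percent) != nrow(covariates))
    stop("`cover_percent` length must match covariate rows", call. = FALSE)
  if (nrow(covariates) < 50L) stop("need >= 50 rows to fit the cover model", call. = FALSE)
  d <- covariates[, covariate_terms]
  d$cover_percent <- as.numeric(cover_percent)
  fit_rs_gam(d, "cover_percent", stats::gaussian(), config)
}

#' Predict from a fitted presence or cover model
#'
#' Presence models return the predicted probability and a label
#' (`probability > threshold`, strict, so a probability exactly at the
#' threshold is labeled absent). Cover models return the unclamped
#' prediction plus a copy clamped to [0, 100]. Rows with any covariate
#' outside the training range are predicted anyway but flagged as
#' extrapolation.
#'
#' @param object an `rs_gam` model.
#' @param newdata covariate data frame.
#' @param threshold probability threshold (default from the model config).
#' @param ... unused.
#' @return data frame with, for binomial models, `probability`, `label`,
#'   `extrapolation`; for Gaussian models `cover_pred`,
#'   `cover_pred_clamped`, `extrapolation`.
#' @export
predict.rs_gam <- function(object, newdata, threshold = NULL, ...) {
  check_cov_input(newdata)
  threshold <- threshold %||% object$config$threshold
  extra <- Reduce(`|`, lapply(object$terms, function(tm)
    newdata[[tm]] < object$ranges[[tm]][1] | newdata[[tm]] > object$ranges[[tm]][2]))
  if (object$family == "binomial") {
    p <- as.numeric(stats::predict(object$fit, newdata = newdata, type = "response"))
    data.frame(probability = p, label = p > threshold, extrapolation = extra)
  } else {
    mu <- as.numeric(stats::predict(object$fit, newdata = newdata, type = "response"))
    data.frame(cover_pred = mu, cover_pred_clamped = pmin(100, pmax(0, mu)),
               extrapolation = extra)
  }
}

#' Centered partial-effect curves of a fitted model
#'
#' Evaluates each smooth term on an even grid spanning that covariate's
#' training range, with the other terms at their centered (zero)
#' contribution. Effects are on the linear-predictor scale (log-odds for
#' presence, percent-cover units for abundance) and are centered by the
#' fit's own sum-to-zero constraint over the training data; pointwise
#' standard errors are included.
#'
#' @param model an `rs_gam` model.
#' @param n_grid grid points per term (default 100).
#' @return data frame `term`, `x`, `effect`, `se`.
#' @export
partial_effects <- function(model, n_grid = 100) {
  stopifnot(inherits(model, "rs_gam"))
  out <- lapply(model$terms, function(tm) {
    grid <- seq(model$ranges[[tm]][1], model$ranges[[tm]][2], length.out = n_grid)
    nd <- as.data.frame(stats::setNames(rep(list(0), length(model$terms)), model$terms))
    nd <- nd[rep(1L, n_grid), , drop = FALSE]
    nd[[tm]] <- grid
    pr <- stats::predict(object = model$fit, newdata = nd, type = "terms", se.fit = TRUE)
    col <- paste0("s(", tm, ")")
    data.frame(term = tm, x = grid,
               effect = as.numeric(pr$fit[, col]),
               se = as.numeric(pr$se.fit[, col]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Smoothness and dispersion diagnostics for a fitted model
#'
#' Reports, per smooth term, the effective degrees of freedom against the
#' basis dimension (flagging terms with EDF > 0.9 (k - 1), i.e. close to
#' exhausting their basis and so possibly over-smoothed by a too-small k),
#' a Pearson dispersion estimate, and a residual summary.
#'
#' @param model an `rs_gam` model.
#' @return list of class `rs_diagnostics` with elements `family`, `terms`
#'   (data frame: term, edf, k_prime, flag_basis), `dispersion`,
#'   `residual_summary`, `n`.
#' @export
model_diagnostics <- function(model) {
  stopifnot(inherits(model, "rs_gam"))
  fit <- model$fit
  edf <- vapply(seq_along(fit$smooth), function(i) {
    sm <- fit$smooth[[i]]
    sum(fit$edf[sm$first.para:sm$last.para])
  }, numeric(1))
  kprime <- vapply(fit$smooth, function(sm) sm$bs.dim - 1, numeric(1))
  terms <- data.frame(
    term = vapply(fit$smooth, function(sm) sm$term, character(1)),
    edf = edf, k_prime = kprime,
    flag_basis = edf > 0.9 * kprime)
  disp <- sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
  rq <- stats::quantile(stats::residuals(fit, type = "deviance"),
                        c(0, 0.25, 0.5, 0.75, 1))
  structure(list(family = model$family, terms = terms, dispersion = disp,
                 residual_summary = rq, n = model$n),
            class = "rs_diagnostics")
}

#' @export
print.rs_diagnostics <- function(x, ...) {
  cat("GAM diagnostics (", x$family, ", n = ", x$n, ")\n", sep = "")
  print(x$terms, row.names = FALSE)
  cat(sprintf("Pearson dispersion: %.3f\n", x$dispersion))
  invisible(x)
}

#' Export a fitted model as a JSON run record
#'
#' Writes the quantities that define and document the fit — family, basis
#' dimension, per-term knots, coefficient vector, smoothing parameters,
#' EDFs, training ranges and size, and an optional scaling-constants hash —
#' to a versioned JSON file, as a human- and machine-readable record of a
#' model run.
#'
#' @param model an `rs_gam` model.
#' @param path output file path.
#' @param constants optional scaling constants (hashed into the record).
#' @return `path`, invisibly.
#' @export
model_to_json <- function(model, path, constants = NULL) {
  stopifnot(inherits(model, "rs_gam"))
  fit <- model$fit
  knots <- lapply(fit$smooth, function(sm) as.numeric(sm$xp))
  names(knots) <- vapply(fit$smooth, function(sm) sm$term, character(1))
  rec <- list(
    format = "rs_gam-record", version = 1L,
    family = model$family,
    k = model$config$k, criterion = model$config$criterion,
    threshold = model$config$threshold,
    terms = model$terms, knots = knots,
    coefficients = as.list(stats::coef(fit)),
    smoothing_parameters = as.numeric(fit$sp),
    edf = as.numeric(vapply(seq_along(fit$smooth), function(i) {
      sm <- fit$smooth[[i]]; sum(fit$edf[sm$first.para:sm$last.para])
    }, numeric(1))),
    n_train = model$n,
    training_ranges = model$ranges,
    scaling_constants_hash = if (!is.null(constants)) hash_obj(constants) else NA)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
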