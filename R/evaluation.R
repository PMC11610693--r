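#' Watershed-blocked train/test split
#'
#' Samples `round(test_fraction * n_watersheds)` whole watershed units into
#' the test set, so no site (and no spatially adjacent group of sites)
#' appears on both sides of the split. Because watersheds, not
#' observations, are the sampling unit, the realized observation fraction
#' varies around the nominal one.
#'
#' @param observations data frame with a `site_id` column (one row per
#'   observation).
#' @param watershed_map data frame with `site_id`, `watershed_id`.
#' @param test_fraction fraction of watershed units held out (in (0,1)).
#' @param seed integer seed.
#' @return list of class `split_spec`: `train_watersheds`,
#'   `test_watersheds`, `test_fraction_watersheds`, `test_fraction_obs`,
#'   `seed`, plus `train_idx`/`test_idx` row indices into `observations`.
#' @export
split_by_watershed <- function(observations, watershed_map, test_fraction = 1/3,
                               seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("`test_fraction` must be in (0, 1)", call. = FALSE)
  ws <- sort(unique(as.character(watershed_map$watershed_id)))
  if (length(ws) < 3L) stop("need >= 3 watersheds to split", call. = FALSE)
  n_test <- round(test_fraction * length(ws))
  n_test <- max(1L, min(length(ws) - 1L, n_test))
  test_ws <- with_seed(seed, sort(sample(ws, n_test)))
  site_ws <- stats::setNames(as.character(watershed_map$watershed_id),
                             as.character(watershed_map$site_id))
  obs_ws <- site_ws[as.character(observations$site_id)]
  if (any(is.na(obs_ws)))
    stop("observations reference sites missing from `watershed_map`", call. = FALSE)
  test_idx <- which(obs_ws %in% test_ws)
  structure(list(
    train_watersheds = setdiff(ws, test_ws), test_watersheds = test_ws,
    test_fraction_watersheds = n_test / length(ws),
    test_fraction_obs = length(test_idx) / nrow(observations),
    seed = seed,
    train_idx = setdiff(seq_len(nrow(observations)), test_idx),
    test_idx = test_idx), class = "split_spec")
}

#' Classification accuracy metrics for presence predictions
#'
#' Class-wise accuracies (sensitivity: fraction of true presences predicted
#' present; specificity: fraction of true absences predicted absent), their
#' unweighted mean (balanced accuracy), overall accuracy, and the confusion
#' counts. If a class is absent from the truth, its class-wise rate and the
#' balanced accuracy are `NA`.
#'
#' @param true_presence logical vector of observed presence.
#' @param predicted_labels logical vector of predicted presence.
#' @return list of class `metrics_report`: `n_test`, `tp`, `fp`, `tn`,
#'   `fn`, `presence_accuracy`, `absence_accuracy`, `balanced_accuracy`,
#'   `overall_accuracy`.
#' @export
classification_metrics <- function(true_presence, predicted_labels) {
  if (length(true_presence) != length(predicted_labels) || !length(true_presence))
    stop("inputs must be equal-length and nonempty", call. = FALSE)
  y <- as.logical(true_presence); p <- as.logical(predicted_labels)
  tp <- sum(y & p); fn <- sum(y & !p); tn <- sum(!y & !p); fp <- sum(!y & p)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(list(
    n_test = length(y), tp = tp, fp = fp, tn = tn, fn = fn,
    presence_accuracy = sens, absence_accuracy = spec,
    balanced_accuracy = (sens + spec) / 2,
    overall_accuracy = (tp + tn) / length(y)), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0(
    "n = %d  (TP %d, FP %d, TN %d, FN %d)\n",
    "presence accuracy (sensitivity): %.3f\n",
    "absence accuracy (specificity):  %.3f\n",
    "balanced accuracy:               %.3f\n",
    "overall accuracy:                %.3f\n"),
    x$n_test, x$tp, x$fp, x$tn, x$fn, x$presence_accuracy,
    x$absence_accuracy, x$balanced_accuracy, x$overall_accuracy))
  invisible(x)
}

#' Observed-versus-predicted R-squared for cover
#'
#' Squared Pearson correlation between observed and predicted percent
#' cover (the convention that permits comparison across studies). The
#' `"ssr"` variant `1 - SSE/SST` is also available.
#'
#' @param observed_cover numeric observed cover.
#' @param predicted_cover numeric predicted cover.
#' @param method `"pearson"` (default) or `"ssr"`.
#' @return a single number (for `"pearson"`, in [0, 1]).
#' @export
r_squared <- function(observed_cover, predicted_cover,
                      method = c("pearson", "ssr")) {
  method <- match.arg(method)
  if (length(observed_cover) != length(predicted_cover) || length(observed_cover) < 3L)
    stop("need >= 3 observed/predicted pairs", call. = FALSE)
  if (stats::sd(observed_cover) == 0)
    stop("observed cover is constant; R-squared undefined", call. = FALSE)
  if (method == "pearson") {
    if (stats::sd(predicted_cover) == 0)
      stop("predicted cover is constant; R-squared undefined", call. = FALSE)
    stats::cor(observed_cover, predicted_cover)^2
  } else {
    1 - sum((observed_cover - predicted_cover)^2) /
      sum((observed_cover - mean(observed_cover))^2)
  }
}
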