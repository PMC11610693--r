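#' Default end-to-end run configuration
#'
#' The defaults encode the study conditions the synthetic analysis is run
#' under at desk scale: 200 sites in 20 watershed units, hourly
#' microclimate over 1989-2004, about 2000 presence/cover observations over
#' observation years 1990-2004, the default generative truth, k = 10 cubic
#' regression splines selected by REML, a 1/3 watershed holdout, and a
#' hindcast over the full simulated window.
#'
#' @return nested list of settings (YAML-serializable).
#' @export
default_config <- function() {
  list(
    seed = 42L,
    sites = c(list(n_sites = 200L, n_watersheds = 20L), site_config()),
    years = list(sim_start = 1989L, sim_end = 2004L),
    microclimate = microclimate_config(),
    rate = list(poly_coeffs = c(1.29e-4, 6.16e-4, -1.25e-5),
                wet_threshold_mpa = -1.25, base_temp_c = 0,
                poly_form = "quadratic", subpopulation_frac = 0.35),
    observations = c(list(n_obs = 2000L), unclass(synth_truth())),
    gam = gam_config(),
    split = list(test_fraction = 1/3),
    hindcast = list(start = NULL, end = NULL, by_aspect = TRUE,
                    endpoints = "fitted"),
    inputs = list(sites_csv = NULL, microclimate_csv = NULL),
    output = list(write_microclimate = FALSE))
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults))
      stop("unknown config key: ", full, call. = FALSE)
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(user[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], full)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Validate and normalize a run configuration
#'
#' Accepts a YAML file path or a nested list, fills documented defaults,
#' rejects unknown keys by name, and checks units/ranges of the settings
#' that have them.
#'
#' @param config NULL (all defaults), a YAML file path, or a nested list of
#'   overrides.
#' @return the normalized full configuration list.
#' @export
validate_config <- function(config = NULL) {
  user <- if (is.null(config)) list()
  else if (is.character(config)) yaml::read_yaml(config) %||% list()
  else if (is.list(config)) config
  else stop("`config` must be NULL, a file path, or a list", call. = FALSE)
  cfg <- merge_config(default_config(), user)

  if (cfg$rate$wet_threshold_mpa >= 0)
    stop("rate.wet_threshold_mpa must be negative (MPa)", call. = FALSE)
  if (cfg$years$sim_start > cfg$years$sim_end)
    stop("years.sim_start must be <= years.sim_end", call. = FALSE)
  if (cfg$sites$n_sites < cfg$sites$n_watersheds || cfg$sites$n_watersheds < 2)
    stop("need sites.n_sites >= sites.n_watersheds >= 2", call. = FALSE)
  if (cfg$split$test_fraction <= 0 || cfg$split$test_fraction >= 1)
    stop("split.test_fraction must be in (0,1)", call. = FALSE)
  if (cfg$observations$cover_sd <= 0)
    stop("observations.cover_sd must be > 0", call. = FALSE)
  # exercise the constructors so their own checks run
  do.call(rate_params, cfg$rate[setdiff(names(cfg$rate), character(0))])
  do.call(gam_config, cfg$gam)
  cfg$hindcast$start <- cfg$hindcast$start %||% (cfg$years$sim_start + 1L)
  cfg$hindcast$end <- cfg$hindcast$end %||% cfg$years$sim_end
  cfg
}

read_microclimate_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$timestamp <- as.POSIXct(d$timestamp, tz = "UTC",
                            tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  d
}

write_microclimate_csv <- function(series, path, append = FALSE) {
  out <- series
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = !append, append = append, quote = FALSE)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the six stages — simulate (sites + hourly microclimate), rate
#' sums (monthly and seasonal), covariates (watershed split, training-set
#' scaling constants, covariate table, simulated observations), fit
#' (presence and cover GAMs), validate (out-of-sample metrics), and
#' hindcast (occupancy by stratum and trends) — writing every tabular
#' artifact under `out_dir` plus a JSON run manifest. Rerunning with the
#' same config reproduces all numeric outputs; per-stage seeds derive from
#' the single top-level seed.
#'
#' When `inputs$sites_csv` and `inputs$microclimate_csv` are set, the
#' simulation stage is skipped and the supplied files (the ingestion
#' contract for real soil-model output) are used instead.
#'
#' @param config see [validate_config()].
#' @param out_dir output directory (created if needed).
#' @return the run manifest, invisibly.
#' @export
run_pipeline <- function(config = NULL, out_dir) {
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- do.call(rate_params, cfg$rate)
  truth_keys <- names(formals(synth_truth))
  truth <- do.call(synth_truth, cfg$observations[intersect(names(cfg$observations), truth_keys)])
  seeds <- derive_seeds(cfg$seed, 6L)
  manifest <- list()
  log_stage <- function(stage, t0, outputs, extra = list(), skipped = FALSE) {
    entry <- c(list(stage = stage, skipped = skipped,
                    elapsed_s = round(as.numeric(Sys.time()) - t0, 3),
                    outputs = outputs), extra)
    manifest[[length(manifest) + 1L]] <<- entry
    message(sprintf("[%s] %s (%.1fs)", stage,
                    if (skipped) "skipped (inputs supplied)" else "done",
                    entry$elapsed_s))
  }

  # -- stage 1: simulate sites and hourly microclimate ----------------------
  t0 <- as.numeric(Sys.time())
  use_files <- !is.null(cfg$inputs$microclimate_csv)
  mc_path <- file.path(out_dir, "microclimate.csv")
  monthly_list <- list()
  if (use_files) {
    sites <- utils::read.csv(cfg$inputs$sites_csv, stringsAsFactors = FALSE)
    mc <- read_microclimate_csv(cfg$inputs$microclimate_csv)
    for (sid in unique(mc$site_id))
      monthly_list[[sid]] <- monthly_rate_sums(mc[mc$site_id == sid, ], params)
    utils::write.csv(sites, file.path(out_dir, "sites.csv"), row.names = FALSE)
    log_stage("simulate", t0, "sites.csv", skipped = TRUE,
              extra = list(inputs_hash = hash_obj(list(cfg$inputs))))
  } else {
    scfg <- do.call(site_config, cfg$sites[setdiff(names(cfg$sites),
                                                   c("n_sites", "n_watersheds"))])
    sites <- generate_sites(cfg$sites$n_sites, cfg$sites$n_watersheds,
                            seed = seeds[1], config = scfg)
    mcfg <- do.call(microclimate_config, cfg$microclimate)
    site_seeds <- derive_seeds(seeds[1] + 1L, nrow(sites))
    if (cfg$output$write_microclimate && file.exists(mc_path)) file.remove(mc_path)
    for (i in seq_len(nrow(sites))) {
      ser <- simulate_microclimate(sites[i, ], cfg$years$sim_start,
                                   cfg$years$sim_end, seed = site_seeds[i],
                                   config = mcfg)
      monthly_list[[sites$site_id[i]]] <- monthly_rate_sums(ser, params)
      if (cfg$output$write_microclimate)
        write_microclimate_csv(ser, mc_path, append = i > 1L)
    }
    utils::write.csv(sites, file.path(out_dir, "sites.csv"), row.names = FALSE)
    log_stage("simulate", t0, "sites.csv",
              extra = list(inputs_hash = hash_obj(cfg[c("seed", "sites",
                                                        "years", "microclimate")])))
  }

  # -- stage 2: monthly and seasonal rate sums ------------------------------
  t0 <- as.numeric(Sys.time())
  monthly <- do.call(rbind, monthly_list)
  rownames(monthly) <- NULL
  obs_years <- (cfg$years$sim_start + 1L):cfg$years$sim_end
  seasonal <- seasonal_rate_sums(monthly, obs_years)
  utils::write.csv(monthly, file.path(out_dir, "monthly_rate_sums.csv"), row.names = FALSE)
  utils::write.csv(seasonal, file.path(out_dir, "seasonal_rate_sums.csv"), row.names = FALSE)
  log_stage("ratesums", t0, c("monthly_rate_sums.csv", "seasonal_rate_sums.csv"),
            extra = list(inputs_hash = hash_obj(cfg$rate)))

  # -- stage 3: split, scaling constants, covariates, observations ----------
  t0 <- as.numeric(Sys.time())
  split <- split_by_watershed(
    data.frame(site_id = sites$site_id), sites[, c("site_id", "watershed_id")],
    test_fraction = cfg$split$test_fraction, seed = seeds[3])
  train_sites <- sites$site_id[split$train_idx]
  cb_train <- build_covariates(seasonal[seasonal$site_id %in% train_sites, ],
                               quiet = TRUE)
  cb_all <- build_covariates(seasonal, constants = cb_train$constants, quiet = TRUE)
  covariates <- cb_all$covariates
  n_obs <- min(cfg$observations$n_obs, nrow(covariates))
  obs_rows <- with_seed(seeds[3] + 1L, sort(sample(nrow(covariates), n_obs)))
  observations <- simulate_observations(covariates[obs_rows, ], truth,
                                        seed = seeds[3] + 2L)
  utils::write.csv(covariates, file.path(out_dir, "covariates.csv"), row.names = FALSE)
  utils::write.csv(observations, file.path(out_dir, "observations.csv"), row.names = FALSE)
  yaml::write_yaml(list(
    spatial = cb_train$constants$spatial,
    site_set = cb_train$constants$site_set),
    file.path(out_dir, "scaling_constants.yaml"))
  utils::write.csv(
    data.frame(watershed_id = c(split$train_watersheds, split$test_watersheds),
               partition = rep(c("train", "test"),
                               c(length(split$train_watersheds),
                                 length(split$test_watersheds)))),
    file.path(out_dir, "split.csv"), row.names = FALSE)
  log_stage("covariates", t0,
            c("covariates.csv", "observations.csv", "scaling_constants.yaml", "split.csv"),
            extra = list(inputs_hash = hash_obj(list(cfg$observations, cfg$split))))

  # -- stage 4: fit presence and cover models -------------------------------
  t0 <- as.numeric(Sys.time())
  site_of <- stats::setNames(as.character(sites$watershed_id), sites$site_id)
  obs_ws <- site_of[as.character(observations$site_id)]
  is_train <- obs_ws %in% split$train_watersheds
  obs_cov <- covariates[obs_rows, ]
  presence_model <- fit_presence(obs_cov[is_train, ], observations$presence[is_train],
                                 cfg$gam)
  abundance_model <- fit_abundance(obs_cov[is_train, ],
                                   observations$cover_percent[is_train], cfg$gam)
  model_to_json(presence_model, file.path(out_dir, "model_presence.json"),
                constants = cb_train$constants)
  model_to_json(abundance_model, file.path(out_dir, "model_abundance.json"),
                constants = cb_train$constants)
  log_stage("fit", t0, c("model_presence.json", "model_abundance.json"),
            extra = list(inputs_hash = hash_obj(cfg$gam)))

  # -- stage 5: out-of-sample validation ------------------------------------
  t0 <- as.numeric(Sys.time())
  test_cov <- obs_cov[!is_train, ]
  pp <- predict(presence_model, test_cov)
  pa <- predict(abundance_model, test_cov)
  metrics <- classification_metrics(observations$presence[!is_train], pp$label)
  r2 <- r_squared(observations$cover_percent[!is_train], pa$cover_pred)
  preds <- data.frame(site_id = test_cov$site_id, obs_year = test_cov$obs_year,
                      probability = pp$probability, label = pp$label,
                      cover_pred = pa$cover_pred,
                      cover_pred_clamped = pa$cover_pred_clamped,
                      extrapolation_flag = pp$extrapolation)
  utils::write.csv(preds, file.path(out_dir, "predictions_test.csv"), row.names = FALSE)
  report <- c(unclass(metrics), list(r_squared = r2,
                                     test_fraction_obs = split$test_fraction_obs))
  jsonlite::write_json(report, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- utils::capture.output(print(metrics))
  writeLines(c(txt, sprintf("cover R-squared (obs vs pred): %.3f", r2)),
             file.path(out_dir, "metrics.txt"))
  log_stage("validate", t0, c("predictions_test.csv", "metrics.json", "metrics.txt"),
            extra = list(inputs_hash = hash_obj(report)))

  # -- stage 6: hindcast ----------------------------------------------------
  t0 <- as.numeric(Sys.time())
  hc_years <- cfg$hindcast$start:cfg$hindcast$end
  hc_cov <- covariates[covariates$obs_year %in% hc_years, ]
  strata <- stratify_sites(sites)
  occ <- annual_occupancy(presence_model, hc_cov, strata,
                          threshold = cfg$gam$threshold,
                          by_aspect = cfg$hindcast$by_aspect)
  trends <- trend_estimate(occ, endpoints = cfg$hindcast$endpoints)
  utils::write.csv(occ, file.path(out_dir, "occupancy.csv"), row.names = FALSE)
  utils::write.csv(trends, file.path(out_dir, "trends.csv"), row.names = FALSE)
  log_stage("hindcast", t0, c("occupancy.csv", "trends.csv"),
            extra = list(inputs_hash = hash_obj(cfg$hindcast)))

  manifest_out <- list(seed = cfg$seed, n_stages = length(manifest),
                       stages = manifest)
  jsonlite::write_json(manifest_out, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest_out)
}
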