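#!/usr/bin/env Rscript
# Stage 2: seasonal rate sums, watershed split, covariates, observations.
#
# Monthly rate sums become per-observation-year seasonal sums (fall =
# Oct-Dec of the preceding year, spring = March). A third of the watershed
# units is held out; spatial scaling constants are computed on training
# sites only and frozen, then the four covariates are built for every
# site-year and ~2000 site-years receive simulated presence/cover
# observations from the default generative truth.

library(ratesumSDM)

SEED <- 42L
out <- "results"
monthly <- read.csv(file.path(out, "monthly_rate_sums.csv"))
sites <- read.csv(file.path(out, "sites.csv"))

seasonal <- seasonal_rate_sums(monthly, 1990:2004)
write.csv(seasonal, file.path(out, "seasonal_rate_sums.csv"), row.names = FALSE)
cat(sprintf("seasonal rate sums: %d site-years; mean fall %.2f, mean spring %.2f\n",
            nrow(seasonal), mean(seasonal$fall_rate_sum), mean(seasonal$spring_rate_sum)))

split <- split_by_watershed(data.frame(site_id = sites$site_id),
                            sites[, c("site_id", "watershed_id")],
                            test_fraction = 1/3, seed = SEED + 10L)
write.csv(data.frame(watershed_id = c(split$train_watersheds, split$test_watersheds),
                     partition = rep(c("train", "test"),
                                     c(length(split$train_watersheds),
                                       length(split$test_watersheds)))),
          file.path(out, "split.csv"), row.names = FALSE)
cat(sprintf("held out %d of %d watersheds (%.0f%% of sites)\n",
            length(split$test_watersheds),
            length(split$test_watersheds) + length(split$train_watersheds),
            100 * split$test_fraction_obs))

train_sites <- sites$site_id[split$train_idx]
cb_train <- build_covariates(seasonal[seasonal$site_id %in% train_sites, ], quiet = TRUE)
cb_all <- build_covariates(seasonal, constants = cb_train$constants, quiet = TRUE)
write.csv(cb_all$covariates, file.path(out, "covariates.csv"), row.names = FALSE)
yaml::write_yaml(list(spatial = cb_train$constants$spatial,
                      site_set = cb_train$constants$site_set),
                 file.path(out, "scaling_constants.yaml"))

covariates <- cb_all$covariates
set.seed(SEED + 11L)
obs_rows <- sort(sample(nrow(covariates), 2000))
observations <- simulate_observations(covariates[obs_rows, ], synth_truth(),
                                      seed = SEED + 12L)
write.csv(observations, file.path(out, "observations.csv"), row.names = FALSE)
cat(sprintf("simulated %d observations; presence frequency %.2f\n",
            nrow(observations), mean(observations$presence)))

cand <- list(
  fall_rate_sum = data.frame(site_id = seasonal$site_id, obs_year = seasonal$obs_year,
                             value = seasonal$fall_rate_sum),
  spring_rate_sum = data.frame(site_id = seasonal$site_id, obs_year = seasonal$obs_year,
                               value = seasonal$spring_rate_sum))
screen <- screen_covariates(observations, cand)
write.csv(screen, file.path(out, "covariate_screen.csv"), row.names = FALSE)
cat("correlation screening of seasonal rate sums against cover:\n")
print(screen, row.names = FALSE)
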