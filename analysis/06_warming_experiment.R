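#!/usr/bin/env Rscript
# Stage 6: climate-trend experiment.
#
# Reruns a 60-site, 1989-2019 study with the emulator imposing a fall
# (Sep-Dec) soil-warming trend of 0.8 C/decade at sites below 1500 m only,
# and a fall-dominated generative truth. The fitted presence model is then
# hindcast: low-elevation occupancy should trend upward while
# high-elevation sites stay abiotically unfavorable (flat at ~0).

library(ratesumSDM)

SEED <- 11L
out <- "results"
dir.create(out, showWarnings = FALSE)

sites <- generate_sites(60, 8, seed = SEED)
mcfg <- microclimate_config(trend_c_per_decade = 0.8, trend_months = 9:12,
                            trend_below_elevation_m = 1500)
params <- rate_params()
site_seeds <- derive_seeds(SEED + 1L, nrow(sites))
monthly <- vector("list", nrow(sites))
for (i in seq_len(nrow(sites))) {
  ser <- simulate_microclimate(sites[i, ], 1989, 2019, seed = site_seeds[i],
                               config = mcfg)
  monthly[[i]] <- monthly_rate_sums(ser, params)
}
seasonal <- seasonal_rate_sums(do.call(rbind, monthly), 1990:2019)
cov <- build_covariates(seasonal, quiet = TRUE)$covariates

truth <- synth_truth(beta0 = -1.4, fall_spatial_peak = 4, fall_spatial_curv = 0.3,
                     spring_spatial_scale = 0, fall_temporal_scale = 2.5,
                     spring_temporal_slope = 0)
obs <- simulate_observations(cov, truth, seed = SEED + 2L)
m <- fit_presence(cov, obs$presence)

occ <- annual_occupancy(m, cov, stratify_sites(sites), by_aspect = FALSE)
trends <- trend_estimate(occ)
write.csv(occ, file.path(out, "warming_occupancy.csv"), row.names = FALSE)
write.csv(trends, file.path(out, "warming_trends.csv"), row.names = FALSE)

cat("occupancy trends under low-elevation fall warming (1990-2019):\n")
print(trends, row.names = FALSE)
lo <- trends[trends$stratum == "low", ]
cat(sprintf("\nlow-tercile occupancy: %.2f -> %.2f (fitted endpoints), %+.1f%% over the window\n",
            lo$fit_start, lo$fit_end, lo$relative_change_pct))
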