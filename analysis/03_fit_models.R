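#!/usr/bin/env Rscript
# Stage 3: fit the presence and cover GAMs on the training watersheds.
#
# Both models share the additive structure: four cubic-regression-spline
# smooths (k = 10, even knots, REML with double-penalty shrinkage), one per
# rate-sum covariate. The presence model is binomial-logit on the >2%-cover
# flag; the cover model is Gaussian-identity on raw percent cover.

library(ratesumSDM)

out <- "results"
covariates <- read.csv(file.path(out, "covariates.csv"))
observations <- read.csv(file.path(out, "observations.csv"))
sites <- read.csv(file.path(out, "sites.csv"))
split <- read.csv(file.path(out, "split.csv"))

train_ws <- split$watershed_id[split$partition == "train"]
ws_of <- setNames(sites$watershed_id, sites$site_id)
obs_cov <- merge(observations, covariates, by = c("site_id", "obs_year"), sort = FALSE)
is_train <- ws_of[obs_cov$site_id] %in% train_ws

presence_model <- fit_presence(obs_cov[is_train, ], obs_cov$presence[is_train])
abundance_model <- fit_abundance(obs_cov[is_train, ], obs_cov$cover_percent[is_train])
model_to_json(presence_model, file.path(out, "model_presence.json"))
model_to_json(abundance_model, file.path(out, "model_abundance.json"))
saveRDS(list(presence = presence_model, abundance = abundance_model,
             obs_cov = obs_cov, is_train = is_train),
        file.path(out, "models.rds"))

cat("presence model diagnostics:\n"); print(model_diagnostics(presence_model))
cat("\ncover model diagnostics:\n"); print(model_diagnostics(abundance_model))

pe <- partial_effects(presence_model)
write.csv(pe, file.path(out, "partial_effects_presence.csv"), row.names = FALSE)
pea <- partial_effects(abundance_model)
write.csv(pea, file.path(out, "partial_effects_cover.csv"), row.names = FALSE)
cat("\nfitted partial-effect shapes (presence, central grid):\n")
for (tm in unique(pe$term)) {
  s <- pe[pe$term == tm, ]
  cat(sprintf("  %-16s rank corr with x: %+.2f; argmax: %+.2f\n", tm,
              cor(s$x, s$effect, method = "spearman"),
              s$x[which.max(s$effect)]))
}
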