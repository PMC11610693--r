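#!/usr/bin/env Rscript
# Stage 4: out-of-sample validation on the held-out watersheds.
#
# The presence model is scored by class-wise, balanced and overall accuracy
# at the 0.5 threshold; the cover model by squared Pearson correlation of
# observed vs predicted percent cover.

library(ratesumSDM)

out <- "results"
st <- readRDS(file.path(out, "models.rds"))
test <- st$obs_cov[!st$is_train, ]

pp <- predict(st$presence, test)
pa <- predict(st$abundance, test)
metrics <- classification_metrics(test$presence, pp$label)
r2 <- r_squared(test$cover_percent, pa$cover_pred)

preds <- data.frame(site_id = test$site_id, obs_year = test$obs_year,
                    probability = pp$probability, label = pp$label,
                    cover_pred = pa$cover_pred,
                    cover_pred_clamped = pa$cover_pred_clamped,
                    extrapolation_flag = pp$extrapolation)
write.csv(preds, file.path(out, "predictions_test.csv"), row.names = FALSE)
jsonlite::write_json(c(unclass(metrics), list(r_squared = r2)),
                     file.path(out, "metrics.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat("out-of-sample performance on held-out watersheds:\n")
print(metrics)
cat(sprintf("cover R-squared (observed vs predicted): %.3f\n", r2))
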