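# The 200-site, 1989-2004 synthetic study used by the parameter-recovery
# checks: hourly microclimate -> monthly -> seasonal rate sums -> the four
# covariates. Built once per test run and memoized (the weather layer is a
# single seeded draw; recovery replicates re-draw observations and splits).
.chain_cache <- new.env(parent = emptyenv())

recovery_chain <- function() {
  if (!is.null(.chain_cache$chain)) return(.chain_cache$chain)
  sites <- generate_sites(200, 20, seed = 101)
  params <- rate_params()
  site_seeds <- derive_seeds(102, nrow(sites))
  monthly <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    ser <- simulate_microclimate(sites[i, ], 1989, 2004, seed = site_seeds[i])
    monthly[[i]] <- monthly_rate_sums(ser, params)
  }
  seasonal <- seasonal_rate_sums(do.call(rbind, monthly), 1990:2004)
  cb <- build_covariates(seasonal, quiet = TRUE)
  .chain_cache$chain <- list(sites = sites, seasonal = seasonal,
                             covariates = cb$covariates,
                             constants = cb$constants)
  .chain_cache$chain
}
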