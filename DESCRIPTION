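Package: ratesumSDM
Title: Germination Rate-Sum Covariates for Invasive Annual Grass Distribution Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts hourly shallow-soil microclimate (temperature and water
    potential at 2 cm) into wet-thermal germination rate sums for cheatgrass
    (Bromus tectorum), builds seasonal spatial and temporal rate-sum covariates,
    fits smooth additive presence and cover models with penalized cubic
    regression splines, validates them with watershed-blocked holdouts, and
    hindcasts occupancy trends by elevation tercile and aspect. Includes a
    seeded synthetic-data module that emulates soil microclimate and field
    observations so the whole chain is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
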