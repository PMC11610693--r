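# ratesumSDM

Modeling invasive annual grass (cheatgrass, *Bromus tectorum*) distribution
and abundance from **germination rate sums**: mechanistic seedbed-favorability
covariates derived from hourly shallow-soil microclimate, feeding smooth
additive species distribution models.

## The problem and the approach

Cheatgrass invasion in the sagebrush steppe is governed by brief windows when
shallow soil is simultaneously warm and wet enough for germination. Remote
sensing maps where the grass is, but says little about *why* — the
species–climate relationship is buried under a reflectance model. This
package takes the mechanistic route:

1. **Wet-thermal germination rate.** For every hour *t* with soil temperature
   `T > 0 °C` and soil water potential `ψ > −1.25 MPa` (at 2 cm depth), the
   germination rate of the 35% seed subpopulation is

   `rate(T) = 1.29e-4 + 6.16e-4·T − 1.25e-5·T²`   (per hour, clipped at 0)

   and exactly 0 outside those conditions. Summing hourly rates over a window
   gives a **rate sum**: a dimensionless index of how favorable the seedbed
   was during that window.

2. **Four covariates.** Seasonal rate sums — late fall (October–December
   preceding the observation) and spring (March) — are scaled two ways:
   *spatially* (site-mean rate sum z-scored across sites: between-site
   climate) and *temporally* (site-year value z-scored within site:
   weather anomaly). Spatial scaling constants are computed on training
   sites only and frozen for test/hindcast use.

3. **Two GAMs.** Presence (cover > 2%) is fitted with a binomial-logit GAM,
   percent cover with a Gaussian GAM; each uses four cubic regression
   splines (k = 10, even knots, REML with double-penalty shrinkage).

4. **Watershed-blocked validation.** Whole watershed units (1/3 of them) are
   held out, so test sites are spatially independent; presence is scored by
   class-wise/balanced/overall accuracy, cover by observed-vs-predicted R².

5. **Hindcast.** The presence model is applied to all site-years over a
   multi-decade window and occupancy fractions are tracked by elevation
   tercile × aspect class, with OLS trends and fitted-endpoint relative
   change.

A seeded synthetic-data module emulates the inputs end to end — sites with
elevation/aspect/watershed structure, hourly soil temperature (elevation
lapse, seasonal and diurnal cycles, aspect term, AR(1) weather) and water
potential (episodic wetting with an October–May wet season, exponential
dry-down), and presence/cover observations generated from known smooth
effects of the four covariates — so the whole chain is testable without any
external data. Real soil-model output in the same CSV schema
(`site_id, timestamp, soil_temp_c, soil_wp_mpa`) is accepted anywhere the
synthetic microclimate is.

## Worked example

The `analysis/` scripts run the whole study at desk scale (200 sites × 16
simulated years, ~2000 observations); each stage reads/writes `results/`:

```sh
Rscript analysis/01_simulate.R            # sites + hourly microclimate -> monthly rate sums
Rscript analysis/02_covariates.R          # seasonal sums, split, covariates, observations
Rscript analysis/03_fit_models.R          # presence + cover GAMs
Rscript analysis/04_validate.R            # out-of-sample metrics
Rscript analysis/05_hindcast.R            # occupancy by tercile x aspect
Rscript analysis/06_warming_experiment.R  # low-elevation fall-warming experiment
```

Output from one run (seed 42):

```
correlation of total fall rate sum with elevation: -0.91
simulated 2000 observations; presence frequency 0.53

out-of-sample performance on held-out watersheds:
n = 752  (TP 316, FP 60, TN 333, FN 43)
presence accuracy (sensitivity): 0.880
absence accuracy (specificity):  0.847
balanced accuracy:               0.864
overall accuracy:                0.863
cover R-squared (observed vs predicted): 0.630

mean predicted occupancy by elevation tercile:
 stratum fraction_occupied
    high        0.037
     low        0.934
     mid        0.726
```

Lower (warmer) sites accumulate larger fall rate sums; the fitted presence
model separates held-out watersheds well above chance; predicted occupancy
collapses with elevation as cold fall/spring soils suppress the rate sums.
The warming experiment (fall soils warming 0.8 °C/decade below 1500 m only)
yields a rising low-tercile occupancy trend (+0.010/yr) while the high
tercile stays flat at 0 — the synthetic analog of climate-driven range
expansion at low and mid elevations.

In code, the core chain is:

```r
library(ratesumSDM)
site  <- generate_sites(10, 3, seed = 1)[1, ]
hours <- simulate_microclimate(site, 2001, 2004, seed = 2)
rates <- hourly_rates(hours)                       # per-hour germination rates
mon   <- monthly_rate_sums(hours)                  # calendar-month rate sums
seas  <- seasonal_rate_sums(mon, 2002:2004)        # fall (Oct-Dec) + spring (March)
germination_rate(20, -0.1)                         # 0.007449 per hour
```

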