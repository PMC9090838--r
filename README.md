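# barleyclim

Potential-yield simulation and climate attribution for highland barley
at alpine meteorological stations.

Highland barley is the staple cereal of high-altitude plateau
agriculture. Its *potential* yield — the ceiling set by radiation,
temperature and crop traits when water, nutrients and management are
non-limiting — is the reference against which yield gaps and
climate-change impacts are judged. `barleyclim` is for agroclimatologists
and crop modellers who want that whole analysis chain as tested,
reusable R functions:

1. **Weather preprocessing** — daily global radiation from sunshine
   duration via the Angstrom–Prescott relation
   `Ra = Ra_max · (a + b·n/N)` with `a = 0.27`, `b = 0.55` and FAO-56
   astronomy for `Ra_max` and daylength; actual vapour pressure
   `ea = RH/100 · (e⁰(Tmax)+e⁰(Tmin))/2` with the Tetens curve; 2-m
   wind via the power-law profile `V = V10 · (2/10)^0.16`.
2. **Crop simulation** — a daily-timestep WOFOST-style
   potential-production engine: thermal-time phenology (base 0 °C,
   variety temperature sums 1600/1750/1950 °C·d), Gaussian-quadrature
   canopy photosynthesis with diffuse/direct light and sunlit/shaded
   leaves, Q10 maintenance respiration, development-stage-indexed
   dry-matter partitioning, and cohort-based leaf senescence. Every run
   closes its carbon balance to ~1e-16 relative.
3. **Trend estimation** — Mann–Kendall test (continuity-corrected
   `Z = (S∓1)/σ`, tie-adjusted or plain variance) with Sen's slope
   (exact odd/even median rule) and MAKESENS-style significance
   markers.
4. **Attribution** — first-difference detrending, temperature-zone
   stratification by annual accumulated temperature above 0 °C
   (<2000 … ≥3500 °C·d), Pearson correlation and bidirectional
   p-value stepwise regression of ΔYp on ΔTave, ΔTmax, ΔTmin, ΔEAT,
   ΔTDR, ΔRA.
5. **Synthetic data** — a seeded generator of 40-year alpine station
   archives (seasonal harmonics, cross-correlated AR(1) anomalies,
   configurable warming/dimming trends) so everything runs and is
   testable without any external archive.

## Worked example

Simulate one synthetic station-year and inspect the result:

```r
library(barleyclim)

cfg    <- weather_gen_config(seed = 42, n_stations = 1, years = 2005)
arc    <- gen_station_weather(cfg)
daily  <- derive_daily(arc$weather, arc$meta$lat[1])
params <- crop_params(arc$meta$variety[1])
run_potential(daily, params, sowing_doy = 100, latitude = arc$meta$lat[1])
#> potential-production run (Chaiqing-1): sowing doy 100, emergence 122, anthesis 177, maturity 233
#>   potential yield 5647 kg/ha (maturity)
```

Sowing on day 100 (10 April), emergence after the 100 °C·d
pre-emergence requirement, maturity on day 233 when the anthesis
temperature sum completes; the storage-organ weight at maturity is the
potential yield. The matching growing-season climate summary:

```r
seasonal_summary(daily, c(100, 233))
#>   station_id year start_doy end_doy    tave     tmax     tmin      tdr     EAT
#> 1     SYN001 2005       100     233 12.1841 18.85231 5.516119 13.33619 1632.67
#>         RA annual_AT0 n_days
#> 1 3102.178    2414.19    134
```

A full pipeline — archive generation, simulation, per-station trends,
zone attribution — is one call:

```r
res <- run_pipeline(pipeline_config(seed = 42, n_stations = 6, years = 1998:2017),
                    write_outputs = FALSE)
res$station_means
#>   station_id mean_yield_kg_ha
#> 1     SYN001         6708.414
#> 2     SYN002         5508.755
#> 3     SYN003         5066.699
#> 4     SYN004         7042.661
#> 5     SYN005         6492.726
#> 6     SYN006         4397.246
res$attribution$regressions$ALL
#> dYp = -427.72*dTave -11.27
#>   F = 30.94, p = 1.95e-07, R2 = 0.223, RMSE = 656.3, n = 110
```

Station-mean potential yields land in the 3.5–8.1 t/ha range observed
for the region. The stepwise fit on the pooled first-difference panel
selects the predictor that best explains year-over-year yield changes
(here, with only 20 years and 6 stations, inter-annual temperature
variation; larger ensembles with a dimming trend surface the radiation
term). `res$trends` carries Mann–Kendall `Z`, Sen slope per decade and
significance markers (`*`, `x`, `+`, `-`) for yield and each climate
factor per station.

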