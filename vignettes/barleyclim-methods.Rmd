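---
title: "Methods: potential-yield simulation and climate attribution for highland barley"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: potential-yield simulation and climate attribution for highland barley}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barleyclim)
```

`barleyclim` implements a complete analysis chain for assessing the
climate-driven potential productivity of highland barley at alpine
meteorological stations: daily weather preprocessing, a
potential-production crop growth simulator, nonparametric trend
estimation, and first-difference regression attribution of yield changes
to climate factors, stratified by temperature zone. This vignette
documents the models, the parameters that matter, the numerical choices,
and what the bundled synthetic-data generator does and does not emulate.

## Weather preprocessing

Raw station records carry daily mean/max/min temperature, sunshine
hours, 10-m wind, mean relative humidity and precipitation. Three
empirical conversions produce the quantities the simulator needs.

**Radiation.** Daily global radiation is estimated from relative
sunshine duration with the Angstrom–Prescott relation
$R_a = R_{a,\max}\,[a + b\,(n/N)]$, with $a = 0.27$ and $b = 0.55$, the
values recommended for high-altitude continental stations.
$R_{a,\max}$ and the daylength $N$ come from the FAO-56 astronomical
formulas (solar declination, sunset hour angle, inverse relative
Earth–Sun distance). The working unit is kJ m⁻² d⁻¹; seasonal totals
are reported in MJ m⁻², with the 10⁻³ conversion applied only at
reporting boundaries. As a formal totality convention, a polar-night
day with zero recorded sunshine returns the overcast limit
$a\,R_{a,\max} = 0$; recorded sunshine on such a day is a data error.

**Vapour pressure.** Actual vapour pressure is
$e_a = \frac{RH_{mean}}{100}\cdot\frac{e^0(T_x)+e^0(T_n)}{2}$ with the
FAO-56 Tetens saturation curve
$e^0(T) = 0.6108\,\exp\!\big(\frac{17.27\,T}{T+237.3}\big)$ (kPa).

**Wind.** 10-m wind is converted to the 2-m crop reference height with
the power-law profile $V = V_H\,(Z/Z_H)^{0.16}$.

Missing daily means are imputed as $(T_{max}+T_{min})/2$; records that
remain unusable (missing extremes, inverted extremes, humidity outside
[0, 100]%, negative wind) are dropped and counted. Sunshine that
exceeds the astronomical daylength by archive rounding is clipped to
$N$.

**Seasonal summaries** average Tave/Tmax/Tmin and the diurnal range
(TDR = Tmax − Tmin) over a day-of-year window and accumulate the
effective accumulated temperature EAT $= \sum \max(T_{ave}, 0)$ (base
0 °C) and the radiation total RA. The window is the simulated
phenological season [sowing, maturity]; when maturity is not reached
the window falls back to [sowing, 30 September]. The common
alternative — a fixed calendar window — is available by calling
`seasonal_summary()` with any window. The annual accumulated
temperature above 0 °C, used for zoning, is always computed over the
full calendar year.

## The potential-production crop simulator

The engine is a daily-timestep WOFOST-style potential-production model:
growth limited only by radiation, temperature and crop traits, with
water and nutrients assumed non-limiting — the right abstraction for
estimating a climatic yield ceiling.

**Phenology** is thermal time with base 0 °C in all phases (the zoning
convention of the study region; no other base is defensible from the
calibration data). Variety-specific temperature sums are: sowing to
emergence 100 °C·d for all three varieties; emergence–anthesis /
anthesis–maturity 650/850 (Chaiqing-1), 700/950 (Zangqing-2000),
800/1050 (Diqing-1) °C·d, grand totals 1600/1750/1950 °C·d. Phase
intervals are half-open [start, end): a transition day's heat counts
toward the new phase exactly once, so simulated dates equal a
cumulative-threshold enumeration exactly at integer-day resolution.
Development stage DVS runs 0 → 1 → 2 (emergence, anthesis, maturity).
Sowing dates are fixed at 10/20/30 April by variety; runs that do not
reach maturity by 31 October terminate as `season_end`, are retained
and flagged, and are excluded from trend statistics by default. A
vernalization requirement beyond the sowing–emergence temperature sum
is not modelled: the calibration encodes pre-emergence development as
a single 100 °C·d requirement.

**Canopy assimilation.** Half of global radiation is PAR. With station
latitude available (the pipeline default), the full WOFOST scheme is
used: the day is integrated at three Gaussian points of solar
elevation; instantaneous PAR is split into diffuse and direct parts
from the atmospheric transmission; and at three Gaussian canopy depths
sunlit and shaded leaf fractions absorb their respective fluxes, with
leaf scattering 0.2 and elevation-dependent canopy reflection. The
leaf light response is $A = A_{max}(1 - e^{-\varepsilon I/A_{max}})$
with $A_{max} = 35$ kg CO₂ ha⁻¹ h⁻¹ and initial slope
$\varepsilon = 0.45$ kg CO₂ ha⁻¹ h⁻¹ per J m⁻² s⁻¹; the diffuse
extinction coefficient is 0.60. Leaf capacity declines with
development stage (full to DVS 1.3, then to 12.8% at maturity) and
responds to daytime temperature (zero at 0 °C, full between 15 and
25 °C, zero again at 35 °C), both standard spring-barley response
tables. Gross CO₂ is converted to CH₂O by 30/44. Without solar
geometry (e.g. unit tests exercising the operation in isolation) a
simplified homogeneous-canopy profile with a cosine diurnal course is
used. Three-point Gaussian quadrature agrees with a 100-point
composite integration of the same leaf response to well under 2%.

One deliberate property of the diffuse/direct split: increasing global
radiation raises atmospheric transmission and therefore shifts light
from the diffuse stream (which reaches shaded leaves) to the direct
beam (which saturates sunlit leaves). Daily gross assimilation is
therefore only *near*-monotone in radiation — ripples below 0.1% occur
in the transmission band where the diffuse fraction falls fastest.
Season-level yield remains monotone under radiation scaling, which is
what the tests assert.

**Respiration and growth.** Maintenance respiration is
$(0.03\,W_{lv} + 0.015\,W_{st} + 0.01\,W_{so} + 0.01\,W_{rt})\cdot
Q_{10}^{(T-25)/10}$ with $Q_{10} = 2$, capped at the day's gross
assimilation so that cold overcast days cannot produce negative
growth. Net assimilate is split root/shoot and then over leaves,
stems and storage organs by development-stage-indexed fraction tables
whose shoot fractions sum to one at every stage (shared interpolation
nodes make the constraint hold identically between nodes). Conversion
efficiencies are 0.685/0.662/0.709/0.694 kg DM per kg CH₂O for
leaf/stem/storage/root. Initial dry weight at emergence is 75 kg ha⁻¹.

**Leaf dynamics** are cohort-based: each day's new leaf weight forms a
cohort; cohorts age by $\max(T,0)/35$ physiological days (one per day
at 35 °C) and die at age SPAN = 25. Leaf area follows specific leaf
area 0.0022 ha kg⁻¹, with the juvenile exponential phase (LAI below
0.75 before anthesis) capped at relative growth rate 0.0075 °C·d⁻¹.
The water-stress death rate (PERDL) is carried in the parameter set
but inactive at the potential production level.

**Accounting.** Every run closes its carbon balance — gross
assimilation minus maintenance, conversion losses and senesced
biomass equals the total organ-weight increment — to relative error
below 10⁻⁶ (in practice ~10⁻¹⁶); the run result carries the full
balance. Identical inputs give bit-identical results.

## Calibration and validation

`derive_tsum()` recomputes phase temperature sums from observed
phenology with the same half-open convention, optionally rounded to
the nearest 50 °C·d — the calibration table's values are round
numbers, and the raw sums are always reported alongside. Agreement
between simulated and observed values uses five standard scores:
Pearson $r$, $R^2 = r^2$, RMSE, relative RMSE
($RMSE/\overline{obs}\times 100\%$) and the percentage deviation
coefficient $PDC = \sum(obs - sim)/\sum obs \times 100\%$. The
calibration/validation partition of a mixed observation set is left to
the caller: published station records mix calibration and validation
years in ways that cannot be reconstructed exactly, so the package
does not hard-code one.

## Trend estimation

The Mann–Kendall statistic $S=\sum_{i<j}\mathrm{sgn}(X_j-X_i)$ is
normalized with the continuity correction $Z = (S \mp 1)/\sigma$.
Two variance modes are provided because spreadsheets in wide use apply
the tie-adjusted variance while the plain formula
$\sigma^2 = n(n-1)(2n+5)/18$ ignores ties: the default is
tie-adjusted, and `variance = "as_printed"` reproduces the plain form
exactly. Significance classes at the 0.1/0.05/0.01 levels carry the
conventional marker symbols (`+`, `x`, `*`). The minimum series length
for testing is 4 — below that the normal approximation is meaningless.
Sen's slope is the median of all pairwise slopes using the explicit
odd/even rule on the sorted slope list; the intercept is the median of
$Y_i - slope\cdot t_i$ (Conover's estimator), and per-decade rates are
10× the annual slope. No prewhitening is applied: with the ~0.3
lag-one autocorrelation typical of annual series the size distortion
is modest, and the type-I error calibration is checked by simulation
on white noise.

## Attribution

Yearly first differences (Δ) remove long-term trends before
correlation; differences are never taken across a gap in a station's
year sequence. Stations are assigned to temperature zones by annual
accumulated temperature above 0 °C with left-closed intervals — below
2000, [2000, 2500), [2500, 3000), [3000, 3500), and 3500 °C·d and
above — resolving the overlapping range labels common in tabulations;
the zoning quantity is an explicit input rather than being inferred
from growing-season sums, whose window conventions differ. Zone
panels pool station-year differences without station fixed effects,
matching the single-equation-per-zone reporting form.

Pearson correlations of each Δ-factor with ΔYp carry two-sided
t-based significance. The stepwise regression is bidirectional on
ordinary least squares with entry p ≤ 0.05 and removal p ≥ 0.10
(configurable; the common statistical-package defaults), iterated to a
fixed point; rank-deficient candidates never enter, and the selected
model's coefficients equal a direct OLS refit by construction. With
six candidate predictors and entry p = 0.05, a pure-noise panel admits
a spurious predictor with probability at most $1 - 0.95^6 \approx
26.5\%$; simulation confirms the realized rate sits at this bound.

## The synthetic weather generator

The generator emulates 40-year daily archives at alpine stations so
the whole chain is testable without any external download. Per
station: annual-mean temperature decreases 4.5 °C per km of elevation
from 9 °C at 2500 m and increases 0.45 °C per degree of latitude south
of 33° N (southern valleys are warmer); the seasonal cycle is a single
harmonic of amplitude 10.5 °C peaking on day 197; daily maximum and
minimum temperatures add a station-specific diurnal range
(10.5–15 °C) and cross-correlated AR(1) anomalies (φ = 0.7, innovation
s.d. 2 °C, cross-correlation 0.6); draws that invert the extremes are
swap-repaired, and the daily mean is the midpoint of the repaired
extremes. Warming trends default to 0.33 (Tmax) and 0.47 (Tmin) °C
per decade — the reported regional magnitudes — which also fixes the
realized daily-mean trend at their average; sunshine fraction is
Gaussian around a station mean near 0.55 with a mild dimming trend
(−0.008 decade⁻¹), producing seasonal radiation declines of the order
of tens of MJ m⁻² per decade. Humidity, wind and precipitation are
drawn from plausible unconditional distributions; precipitation realism
matters only for file-format completeness, since potential production
does not consume it. These defaults were chosen once so that
growing-season climatology falls inside the reported observational
ranges (mean temperature 9.7–18.8 °C, radiation totals
2389–3662 MJ m⁻², EAT within 1394–2707 °C·d) and are configuration,
not code.

What the generator does **not** emulate: real station geography and
its orography, spatially correlated weather between stations, seasonal
structure in cloudiness or humidity, and observational artifacts
(instrument changes, relocations). Passing tests on synthetic archives
therefore demonstrate the correctness and calibration of the methods —
trend recovery, regression recovery, physical invariants — not the
reproduction of any particular station's published values, which would
require the original archive.

Varieties are assigned by latitude band (Chaiqing-1 north of 34° N,
Zangqing-2000 for 30–34° N, Diqing-1 south of 30° N), mirroring the
real planting geography.

The panel generator draws the six Δ-predictors from a configurable
multivariate normal (by default independent, with inter-annual
difference scales 0.5/0.6/0.5 °C, 60 °C·d, 0.6 °C, 120 MJ m⁻²) and
builds ΔYp from configured true coefficients plus Gaussian noise,
recording the truth as an attribute.

## Pipeline, reproducibility and problem sizes

`run_pipeline()` chains generation → preprocessing + simulation →
trends → attribution, writes each stage as a plain CSV, and records a
JSON manifest with the seed, configuration and MD5 checksums; a rerun
with the same configuration reproduces identical bytes, and deleting a
stage output and rerunning restores it exactly. All randomness flows
from the single configured seed.

Default problem sizes were chosen to keep a full desk run comfortable:
the standard ensemble is 12 stations × 40 years (the simulator runs a
50-station × 40-year ensemble, 2000 station-years, in about two
minutes); statistical calibrations use 5000 white-noise series for the
type-I error, 1000 replicates for trend recovery, and 500–1000
replicates for selection rates. The reported potential yields from
these ensembles fall in the 3.5–8.1 t ha⁻¹ range reported for the
study region, with station means typically 4–7.5 t ha⁻¹.

## Known limitations

- The potential production level only: no water- or nutrient-limited
  yields, no transpiration-driven stress, no vernalization or
  photoperiod response.
- Simplified leaf-area source limitation (constant specific leaf area;
  no self-shading death rate): peak LAI is realistic (~4–5) but the
  post-anthesis LAI decline rests on cohort ageing alone.
- No spatial interpolation, mapping, or spatial autocorrelation
  modelling; stations are independent columns of the analysis.
- The Mann–Kendall test is applied to annual series without
  prewhitening; strongly autocorrelated series will show inflated
  significance.
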