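---
title: "Quantifying prescribed-fire burn windows from gridded daily weather"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying prescribed-fire burn windows from gridded daily weather}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxwindows)
```

## The problem

Prescribed fire is planned around a "burn prescription": a window of weather
and dead-fuel moisture conditions inside which a fire burns intensely enough
to meet its objectives but stays controllable. Both tails matter — vegetation
can be too moist to carry fire usefully, and too dry to burn safely. A day on
which every prescribed variable falls inside its acceptable range is a
prescribed-fire day (an *RxDay*), and the number of RxDays per season and per
year is the climatological quantity of interest: how large is the burn
window, where, in which season, and how is it trending as the climate warms
and dries?

`rxwindows` implements this analysis end to end on daily gridded surface
meteorology (daily Tmax/Tmin, RHmax/RHmin, daily-mean 10 m wind, daily
precipitation): NFDRS-style dead fuel moisture and ignition component,
median prescription envelopes assembled from sets of operational burn plans,
binary per-grid-day classification, quantile-mapping bias correction for
model-derived metrics, air-stagnation day counts as a smoke-ventilation
proxy, and seasonal/annual/regional count climatologies with trends, epoch
differences and ensemble agreement. A stochastic weather generator provides
statistically realistic inputs so the whole chain is testable without
multi-hundred-gigabyte meteorological archives.

## Fuel moisture model

Dead fuels are classed by response time (1-h, 10-h, 100-h, 1000-h). The
package uses the classical 1978/1985 NFDRS formulation; every empirical
constant is centralised in `nfdrs_constants()`.

**Equilibrium moisture content (EMC).** A three-regime polynomial in
relative humidity and dry-bulb temperature (Fahrenheit internally; all
public interfaces are SI and conversion happens once at the module
boundary). The daily value is a daylight-weighted average of the daytime
extreme (Tmax, RHmin) and the night-time extreme (Tmin, RHmax):

$$\overline{EMC} = \frac{D \cdot EMC_{day} + (24 - D)\cdot EMC_{night}}{24},$$

with day length $D$ from standard solar declination geometry at the cell's
latitude.

**Fine fuels.** $FM_1 = 1.03\,\overline{EMC}$ and
$FM_{10} = 1.28\,\overline{EMC}$ respond essentially instantaneously at the
daily time step.

**Heavy fuels.** The 100-h and 1000-h classes relax day by day toward a
boundary condition mixing dry-hour EMC with a wet-hour term driven by
precipitation duration $PDUR$:

$$B_{100} = \frac{(24-PDUR)\,\overline{EMC} + PDUR\,(0.5\,PDUR+41)}{24},
\qquad
FM_{100}^{(t)} = FM_{100}^{(t-1)} + (B_{100}^{(t)} - FM_{100}^{(t-1)})
\,(1 - 0.87 e^{-0.24}),$$

and analogously for the 1000-h class with boundary coefficients
$(2.7\,PDUR + 76)$, update fraction $1 - 0.82 e^{-0.168}$, and the boundary
averaged over a trailing 7-day window. Both recursions are contractions, so
any two initialisations converge geometrically; the package initialises at
the first boundary value (100-h) and the mean of the first seven boundaries
(1000-h) and discards a 90-day spin-up by default — generous relative to
both time constants.

**Precipitation duration.** Daily archives provide amounts, not durations,
so a monotone capped model supplies the hours: 0 below a 0.25 mm trace,
otherwise $\min(8, \lceil \mathrm{mm}/5 \rceil)$. It is exposed as
configuration (`precip_duration()` parameters) because any such mapping is a
convention, not physics.

**Ignition component.** The probability-of-ignition chain (heat-of-ignition
polynomial, chi transform, power law) evaluated at $FM_1$ and the day's
maximum temperature, truncated to an integer index in $[0, 100]$. Two
simplifications are deliberate: no cloud-cover fuel-temperature offset
(daily archives carry no cloudiness) and no spread-component coupling
(spread and energy-release indices are outside this package's scope). The
index is nonincreasing in fuel moisture, nondecreasing in temperature, and
0 for saturated fuels.

## Prescription envelopes and RxDays

Each burn plan bounds a subset of: air temperature, relative humidity,
mid-flame wind, the four fuel moisture classes and the ignition component.
The applied envelope takes, per variable, the **median of the plan lower
bounds and the median of the plan upper bounds**, separately for forest and
non-forest plan sets; a variable present in only some plans is pooled over
the plans that include it. Non-forest plans never bound the 100-h/1000-h
classes, so non-forest envelopes carry no heavy-fuel constraints.

Classification evaluates **peak-burning conditions**, not daily means:
daily maximum temperature, daily minimum relative humidity, and the
daily-mean 10 m wind scaled by 1.5 (afternoon peak) and then 0.4 (mid-flame
height) — a net factor of 0.6, in that order. A grid-day is an RxDay when
*every* bounded variable lies inside its range. Bounds are inclusive: plans
state acceptable ranges, and a value exactly at a stated limit is
operationally acceptable. If an envelope bounds a variable the evaluation
cannot supply, classification errors rather than silently passing — an
envelope must never weaken by accident.

Definition variants support sensitivity analysis: vegetation-aware (forest
envelope on forest cells, non-forest elsewhere — the primary definition),
each envelope applied uniformly, an all-plans pooled envelope, a
meteorology-only definition (all fuel moisture and ignition bounds
dropped), and a no-heavy-fuels definition (100-h/1000-h dropped). Dropping
bounds can only add RxDays — a conjunction-monotonicity property the test
suite checks, and the mechanism behind the "drying paradox": in a
persistently moist regime a drying trend *adds* RxDays (fuels fall into
range), while in a dry regime the same trend removes them.

## Bias correction

Fire-danger metrics derived from model meteorology inherit biases from
covariance and serial-correlation errors that survive univariate
downscaling, so corrected metrics — not corrected weather — are the target.
The package uses empirical quantile mapping per grid cell: 100 evenly
spaced quantile nodes, pooled by calendar month by default (an all-days
pool is available for short series), linear interpolation between nodes,
and constant-offset extrapolation beyond the training range (the offset at
the extreme node), which preserves modelled change signals outside the
training support. The mapping is monotone, the identity on a self-fit, and
drives the two-sample KS statistic between corrected-model and observed
training distributions below 0.05 at n = 5000 in the acceptance checks.
Node count, pooling and training window are configuration, as no single
convention is canonical.

## Air stagnation

Low-level stagnation days proxy poor smoke ventilation: daily-mean 10 m
wind **strictly** below 3.2 m/s and daily precipitation **strictly** below
1 mm (equality is not stagnant, following the printed thresholds). The
classical third criterion (weak 500 mb winds) is deliberately omitted: the
near-surface criteria are what govern low-level ventilation and scavenging,
and daily near-surface fields are what the pipeline carries.

## Counts, trends and ensembles

Seasonal tallies use meteorological seasons with December attached to the
following year's DJF; incomplete leading/trailing seasons are dropped
rather than reported short. Regional series average per-cell counts with
cos(latitude) weights (an unweighted option is retained for sensitivity).
Trends are ordinary least squares on yearly values, reported as slope,
accumulated change (slope times the year span), percent change, and the
two-tailed t-test p-value. The percent-change baseline defaults to the
fitted value at the first year (the period mean is available as an
option). Running means are centred with truncated end windows so smoothed
series span the full period. Ensemble agreement counts the members whose
own accumulated change passes a threshold; members are classified first
and their counts averaged afterwards, so the ensemble mean is a mean of
derived quantities rather than a quantity of mean weather.

## The synthetic-data generator

Each primitive variable (Tmax, diurnal range, RHmin, RH range, 10 m wind)
is a seasonal cosine climatology plus a linear trend (units per decade), a
latitudinal gradient, and AR(1) anomalies whose innovations are spatially
smoothed white fields (separable Gaussian kernel, variance renormalised).
Parameterising the diurnal range and RH range — rather than Tmin and RHmax
directly — makes `tmax >= tmin` and `rhmin <= rhmax` true by construction
for any parameter choice. RHmin anomalies are anti-correlated with Tmax
anomalies (default coefficient −0.6) so hot extremes are dry extremes, as
in real fire weather. Precipitation is a seasonal Bernoulli wet-day process
(occurrence spatially coherent via thresholding the same smoothed Gaussian
field) with iid gamma amounts. One master seed drives everything; per-
variable and per-member streams are derived deterministically from it, so a
member's field does not change when an unrelated variable is added.

Default parameters describe a mid-latitude interior-western-US climate:
warm-season temperature peak, cool-season humidity and precipitation peaks,
annual-mean wind near 3 m/s, daily anomaly standard deviations of a few
degrees / ~10% RH, lag-1 autocorrelation 0.7. Pseudo-model ensembles
perturb the climatology means and trends additively per member, so a
member's bias is recoverable exactly in the noise-free limit.

What the generator does *not* emulate: full geostatistical spatial
covariance (one smoothing scale instead), precipitation amount
autocorrelation and spatial structure, humidity-precipitation coupling,
orography, and observational error structure. Tests passing on synthetic
data therefore demonstrate the correctness and calibration of the
*method* — classification semantics, recursion fixed points, trend
estimator size and bias, distribution matching — not the realism of any
particular regional number.

## Numerical choices and degenerate inputs

* The heavy-fuel trailing-window means are computed with explicit
  oldest-to-newest additions so the gridded code and a scalar per-cell
  reference iteration agree bit for bit.
* Quantile tables with zero spread (constant training series) fall back to
  a constant-offset transfer.
* Even plan counts use the usual mean-of-middle-two median for envelope
  bounds.
* The vegetation mask thresholds a smoothed Gaussian field by rank, so the
  realised forest fraction matches the target to within one cell.
* Physical clipping: RH into [0, 100], wind and precipitation nonnegative,
  diurnal range at least 0.5 degC. EMC is floored at 0; the corrected
  ignition component is clipped to [0, 100].
* Invalid inputs error early with named messages (reversed date ranges,
  negative standard deviations, RH outside [0, 100], polar latitudes,
  missing NetCDF variables, envelopes bounding unavailable variables).

## Problem sizes

The test suite and the acceptance script run on desk-scale cases chosen to
exercise every code path with comfortable statistical power: 3x3 to 10x10
grids, 2 to 80 years of daily data, 6-member ensembles, 1000-replicate
calibration checks. The full acceptance study (10x10, 1980-2060, 6
members, bias correction) completes in a few minutes on one core; the same
code scales to larger grids linearly in cells and days.

## Worked example

```{r, eval = FALSE}
spec <- climate_spec(n_lat = 10, n_lon = 10,
                     start = "1980-10-01", end = "2020-12-31",
                     trend = c(tmax = 0.3, rhmin = -0.8), seed = 42)
weather <- generate_weather_grid(spec)
fm <- compute_fuel_moisture(weather, spinup = 92)
plans <- generate_burn_plans(14, 8, seed = 42)
mask <- generate_vegetation_mask(weather$lat, weather$lon, 0.5, seed = 42)
rx <- rxday_grid(weather, fm, mask,
                 median_envelope(plans, "forest"),
                 median_envelope(plans, "non-forest"))
annual <- regional_mean(seasonal_counts(rx, "annual"), wus_regions()$WUS)
linear_trend(annual)
```

Or, end to end with artifacts on disk:

```{r, eval = FALSE}
cfg <- pipeline_config(spec = list(n_lat = 10, n_lon = 10,
                                   start = "1980-10-01",
                                   end = "2020-12-31"),
                       seed = 42, spinup = 92, out_dir = "run1")
res <- run_pipeline(cfg)
```

## Known limitations

The RxDay metric is meteorological: it carries no regulatory, staffing,
ecological or smoke-permission constraints, and a composite envelope drawn
from a modest plan set cannot represent local prescriptions; counts are
comparable across space, time and scenario, not against implementation
records. The generator's simplifications above mean regional numbers from
synthetic runs illustrate the method's behaviour, not any real region's
climatology. Quantile mapping is univariate and per-cell; multivariate or
explicitly trend-preserving variants (beyond constant-offset tails) are out
of scope.
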