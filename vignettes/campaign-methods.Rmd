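---
title: "Methods: from raw campaign streams to exposure and sound summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw campaign streams to exposure and sound summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airsound)
```

## The measurement problem

`airsound` processes urban monitoring campaigns with a hybrid design: a
few **fixed** sites monitored continuously across two seasons, and many
**rotating** sites visited once per season for about three days.
Instruments at each site record minute-resolution PM2.5 from a low-cost
light-scattering sensor, a 24-h-integrating gravimetric filter sampler,
and minute-resolution A-weighted sound levels. The design trades depth
for spatial coverage, which creates three methodological problems the
package solves in sequence:

1. low-cost sensors are biased relative to gravimetric mass, and the
   bias is season-dependent (aerosol composition and humidity differ);
2. three-day snapshots taken in different weeks are not comparable when
   the whole city trends within a season;
3. decibel data cannot be averaged arithmetically, and "loudness" alone
   misses how *eventful* a soundscape is.

## Gravimetric and black-carbon chain

A filter is accepted when three consecutive weights agree within 3 µg;
the accepted mass is their mean (`accept_weighing()`). Sampled mass is
the post-minus-pre difference, corrected by the season's field-blank
median (defaults 2 µg dry, 4 µg wet), and divided by the sampled volume

$$V\,[\mathrm{m^3}] = \text{minutes} \times \text{flow}\,[\mathrm{L/min}]
  \times \text{duty} / 1000,$$

so a 24-h sample at 1.0 L/min with a 50% duty cycle draws 0.72 m³.
Black carbon uses the transmissometer convention
$\mathrm{ATN} = 100\ln(I_0/I)$: after subtracting the seasonal blank
median (2.03 dry, 0.15 wet, in ATN units), the surface loading is
$\mathrm{ATN}/\sigma$ with $\sigma = 16.6\ \mathrm{m^2/g}$ at 880 nm —
so a blank-corrected ATN of 16.6 is exactly 1 µg/cm² — then scaled by
the 8.6 cm² sampled area and divided by the volume. Negative
blank-corrected masses and loadings are floored at zero and flagged;
physically a concentration cannot be negative, and the flags keep the
flooring auditable. Exact cancellations (corrected value of zero) are
flagged too, since they carry no usable signal.

## Sensor calibration

Each deployment carrying both instruments contributes one calibration
pair: the deployment-mean raw sensor value over the filter's sampling
window against the filter concentration — the filter integrates exactly
the air the sensor saw, so deployment-level means are the natural
pairing resolution. The correction is ordinary least squares of
gravimetric on sensor, fitted per season, and applied per minute as
$\hat{c} = a + b \cdot \text{raw}$ (floored at zero). Regressing in
this direction (rather than sensor on gravimetric) lets the fitted line
be applied directly to the raw stream. An intercept is retained: a
pure-ratio model is a special case, and `sensor_bias_summary()` reports
the ratio-style mean under/overestimate separately. Sites flagged
*high-range* (an extreme industrial site whose concentrations sit far
above the rest of the network) get their own model per season when at
least three pairs exist; otherwise they fall back to the general model
with a warning — also when the stratum is degenerate, e.g. when all its
deployment means coincide.

Curvature in the sensor–gravimetric relationship is screened with
`check_linearity()`: a single-knot piecewise-linear fit (knot at the
median sensor mean) is compared with the straight line, and a drop in
RMSE above 10% flags non-linearity. A one-knot linear spline is the
smallest model that can bend; with deployment-level sample sizes,
richer splines overfit before they inform.

## Weekly temporal adjustment (TAF)

City-wide PM2.5 trends within a season, so rotating sites measured in
different weeks are confounded with time. The temporal adjustment
factor for week $w$ is

$$\mathrm{TAF}(w) = \frac{\bar{x}_{\text{ref}}(w)}{\bar{x}_{\text{ref}}
  (\text{season})},$$

where the reference is the mean over included fixed sites of their
weekly mean of daily values (the extreme high-range site is excluded so
one site cannot steer the city-wide reference), optionally averaged
with equal weight against an external regulatory monitor's weekly mean
for PM2.5. Equal weighting treats the pooled fixed network and the
independent monitor as two references of comparable standing. Weeks are
consecutive 7-day blocks anchored at the season's first sampling day —
calendar (ISO) weeks would split the first block arbitrarily. Each
deployment is assigned the week of its midpoint, and its retained
measurement-day values are *divided* by that week's TAF; the seasonal
reference mean defaults to the duration-weighted mean of the weekly
means, which makes the duration-weighted mean TAF exactly 1, so
adjustment re-centres rather than re-scales a season. Missing interior
weeks are linearly interpolated from neighbours; at season edges the
lookup fails loudly rather than extrapolate. The TAF is a weekly
scalar, so it is applied to 24-h measurement-day means (and identically
to a day's day/night-window means), leaving diurnal shape untouched.

A measurement-day is a rolling 1440-minute block counted from the
deployment start; a day is retained when at least 80% of its minutes
were observed (a configurable completeness fraction — a strict 100%
rule would discard a day over a single dropped minute). Seasonal site
summaries are means and SDs over retained days; annual values are the
plain average of the site's available seasonal means, so a season is
not up-weighted for having more retained days.

## Sound metrics

Minute levels are A-weighted decibels, so averaging happens on the
energy scale: $L_{Aeq} = 10\log_{10}\!\big(\tfrac1n\sum_i
10^{L_i/10}\big)$. Day (06:00–20:59) and night (21:00–05:59) windows
partition the clock by minute start time. The intermittency ratio
treats a minute as an *event* when its level reaches the window's own
LAeq plus a threshold $K$ (default 4 dBA; 3 and 5 as sensitivity
settings), and reports the percentage of total acoustic energy carried
by event minutes. The event criterion is closed ($\geq$) at the
threshold. IR is computed directly on the minute levels the instruments
log; the same construction applies per window with that window's LAeq
as reference, so IR is invariant to adding a constant to every minute.
Cross-site sound summaries use medians and IQRs (the decibel scale is
non-linear), and both seasons are pooled for sound; PM summaries use
means and SDs.

Guideline comparisons count minutes below the WHO traffic limits
(53 dBA day / 45 dBA night), flag sites against the Bangladesh
area-based limits that apply to their land use (residential 55/50,
industrial 75/70 dBA; other categories have no directly applicable
limit and are reported `NA`), and flag measurement-days above the WHO
24-h PM2.5 guideline of 15 µg/m³.

## Spatial statistics

Land-use contrasts of site-level metrics use the Kruskal–Wallis
rank-sum test with the chi-squared approximation (group sizes here are
around 8–19, where the approximation is standard); PM contrasts are
season-specific because the land-use signal can differ by season.
Day-of-week contrasts regress daily values on weekday indicators with
site-clustered CR1 robust standard errors — repeated days at one site
are correlated, and with singleton clusters CR1 collapses to HC1, which
the test suite checks against a hand-built oracle. Site-averaged air
and sound metrics are correlated with Spearman's rank correlation
(average ranks under ties). The bivariate hotspot map assigns each site
PM and sound tertiles with quantile breaks at 33.33% and 66.66%
(linear-interpolation quantile convention; values equal to a break fall
in the lower tertile, and a metric constant across sites degenerates to
tertile 1 with a warning); *co-hotspots* are sites in the top tertile
of both.

## The synthetic campaign generator

Because raw field data are not bundled, every stage is validated
against `simulate_campaign()`, whose defaults encode the study
conditions the analysis assumes: 8 fixed + 62 rotating sites with
land-use shares 19/16/8/18/9 across residential, commercial/industrial,
green–blue–open, transportation and mixed-use; a dry season
(2023-01-18 to 2023-03-17) and wet season (2023-07-22 to 2023-09-24);
5-day fixed replacement cycles and 3-day rotating deployments staggered
across the season's weeks; and an 11% per-deployment battery-failure
probability that truncates the record at a uniform point in the final
40% of the planned duration.

True exposure is multiplicative lognormal:

$$x_{s}(t) = \underbrace{B_{\text{season}}}_{\text{50 or } 50 \times 4
  \ \mathrm{\mu g/m^3}} \times m_{\mathrm{LU}(s)} \times h_s \times
  u_s \times r^{w(t)-1} \times d(t) \times \varepsilon_t ,$$

with land-use multipliers $m$ taken from the relative annual levels of
the campaign summary table (0.90–1.10), a high-range multiplier
$h = 3.6$ on one fixed industrial site, a mean-corrected lognormal site
effect $u_s$ (log-SD 0.15) and minute noise $\varepsilon_t$ (log-SD
0.35), a weekly trend $r$ (0.93/week dry — pollution declines through
the dry season — and 1.02/week wet), and a day/night factor $d$ giving
night/day mean ratios of 1.20 (dry) and 1.07 (wet). Trend and diurnal
factors are normalised to duration-weighted mean 1, so
`expected_site_mean()` is the exact expectation of a site's seasonal
mean — the anchor for the parameter-recovery and TAF tests. The
multiplicative form guarantees positivity and the right-skew of ambient
PM. Sensors see $0.64x$ (dry) or $0.98x$ (wet) plus 5 µg/m³ Gaussian
noise, truncated at zero. Filters integrate the true series through the
duty-cycled volume, add the seasonal blank offsets and weighing noise,
and encode BC through the same ATN optics the lab stage inverts, with
seasonal BC mass fractions of 7.0% and 5.4%. Sound is a land-use
background at the summary-table medians (55–73 dBA) plus a site offset
(SD 1.5 dBA), +1.8/−3.0 dBA day/night offsets, five daily
prayer-call events (+12 dBA for 5 minutes) and 4 dBA Gaussian noise,
clamped to [25, 130] dBA.

What the generator does **not** emulate: spatial correlation between
sites (site effects are independent), meteorology, sensor drift or
humidity response, within-day missingness other than tail truncation,
and heavy-tailed sound events beyond the fixed daily schedule. Passing
tests therefore demonstrate that the *estimators* recover known
structure under the assumed data-generating process — not that the
instruments themselves behave.

The within-season variance structure of rotating-site levels is not
pinned down by any published summary; the site log-SD of 0.15 matches
the coefficient of variation of rotating-site annual means a campaign
of this shape reports, and is a free parameter of the generator, not a
field claim.

## Numerical and reproducibility choices

* All timestamps are naive local clock time (carried as UTC POSIXct);
  day/night windows are clock windows.
* Every generator stage derives its own sub-seed from the campaign
  seed, so campaigns are byte-reproducible and identical configs yield
  identical output files (the run manifest records MD5 checksums).
* The linearity check treats an RMSE below numerical noise
  ($10^{-8}$ of the response scale) as an exact fit, so rounding error
  is never flagged as curvature.
* TAF lookups interpolate interior weeks linearly and refuse to
  extrapolate beyond the observed week range.
* Degenerate inputs fail loudly with classed conditions
  (`airsound_error_*`) rather than returning silent `NA`s: zero
  sampled volume, zero gravimetric mean, single-cluster robust errors,
  all-tied rank tests, constant tertile metrics (warning + tertile 1).

## Problem sizes used in validation

Unit tests run scaled campaigns (2 fixed + 6 rotating sites, two-week
seasons). Calibration recovery uses a dry season with 90 sites giving
~100 sensor–filter pairs; the TAF-effectiveness experiment uses 20
replicate campaigns of 3 fixed + 10 rotating sites over a six-week dry
season with a strong (0.85/week) declining trend; and the acceptance
script runs the full 70-site two-season campaign. These sizes are the
package's validation choices: large enough for the convergence
tolerances the tests assert, small enough to run routinely.
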