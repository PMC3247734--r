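---
title: "From half-hourly dendrometer records to monthly growth-climate response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From half-hourly dendrometer records to monthly growth-climate response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrosri)
```

## The problem

Automated point dendrometers press a sensing rod against a tree stem and
record radial displacement (in micrometers) every half hour. The raw signal
mixes three things: irreversible wood growth, a reversible diel cycle of
water-driven swelling and shrinking (nocturnal recharge and morning expansion
to a pre-noon maximum, afternoon/evening contraction), and sensor noise or
outright failures. `dendrosri` implements the processing chain that isolates
daily growth from such records and relates it to weather, for a tropical
treeline setting governed by the North American Monsoon (a June--October wet
season delivering ~85% of annual precipitation).

The chain is: half-hourly logger ingest with quality flags, daily weather
summaries including derived vapor pressure deficit (VPD), Stem Radial
Increment (SRI) extraction, growth phenology (cumulative curves, monthly
shares, growing season, soil-temperature onset), and monthly bootstrapped
correlation / principal component regression (PCR) between daily SRI and
twelve environmental variables. Because no field dataset ships with the
package, a first-class synthetic generator emulates the study conditions so
every stage is exercisable and scored against known ground truth.

## Stem Radial Increment

For each tree and calendar day, the day's maximum stem size is compared with
the previous day's maximum:

* `SRI(t) = max_stem(t) - max_stem(t-1)`, floored at zero. Negative
  differences are reversible water loss, not negative growth; a shrinking
  (for example, beetle-infested) tree records SRI = 0, and its cumulative SRI
  plateaus.
* Differences greater than 350 um are physically implausible for these trees
  (typical growing-season SRI is ~15 um with SD < 20 um) and are set missing
  (`basis = "spurious"`). The test is strict (`> 350`), applied to the signed
  difference **before** the zero floor, and only to positive exceedances:
  a large negative drop floors to zero rather than being discarded.
* If the previous day has no usable maximum (gap, outage, start of record)
  the day is missing (`basis = "no_previous_max"`); days are never compared
  across a gap.

The calendar day (local midnight to midnight) is used as the 24-hour window
for both weather and stem summaries. A rolling-window reading would change
SRI on days whose maximum falls just before midnight; with a pre-noon diel
maximum this is rare, and the calendar-day convention keeps weather and
growth aligned on the same dates.

Site-level SRI is the arithmetic mean of per-tree SRI over trees with a
non-missing value that day (median and single-tree alternatives are
available). Cumulative SRI adds missing days as zero but reports their count.

## Vapor pressure deficit

Saturation vapor pressure is the Magnus-type form
`SVP = 6.11 exp(17.2693882 AT / (AT + 237.3))` hPa, and ambient vapor
pressure is `VP = RH x SVP x P / (RH x SVP + 100 (P - SVP))`, with `RH` in
percent and barometric pressure `P` in hPa. VPD = SVP - VP is computed per
half hour and then averaged over the day. The ordering matters: because SVP
is convex in temperature, the daily mean of half-hourly VPD differs from the
VPD of daily-mean inputs, and a guard test asserts the pipeline uses the
former. The coefficient set is implemented exactly as printed in the source
formulas, with no substitution of other Magnus variants.

## Daily summaries and eligibility rules

A day needs at least 75% of its 48 half-hour slots to be retained
(configurable); otherwise all its summaries are missing -- never zero.
Totals (precipitation, solar radiation) sum present slots; extremes and means
use present slots. Out-of-range readings (for example RH > 100) are flagged
suspect at ingest and treated as missing, never silently dropped, with counts
in the parse report. Duplicate timestamps keep the first occurrence; absent
grid slots are materialized explicitly so no gap is silent.

For the response analysis, a year-month enters only with at least 21 paired
(SRI, variable) days -- inclusive at 21. "Paired" is evaluated per variable
(pairwise-complete): a month can be eligible for some variables and report
`/` (unavailable) for others.

## Bootstrap significance and PCR

For each eligible month x variable, 1,000 resamples of day pairs are drawn
with replacement; the Pearson correlation is computed on each; and the median
estimate is declared significant when its absolute value exceeds half the
spread between the 97.5th and 2.5th percentiles of the resample distribution.
Percentiles use empirical order statistics with linear interpolation
(`stats::quantile`, type 7). Resampling is iid within the month (the day pair
is the resampling unit, pairing preserved across variables); no block
bootstrap is attempted, a documented limitation for autocorrelated daily
series. Degenerate resamples (zero variance) are redrawn up to 100 times,
then counted.

A property worth knowing: under independence at month-scale sample sizes
(n = 30), this percentile-spread rule rejects at roughly 7--10%, not at its
nominal 5%. The bootstrap half-width at n = 30 averages ~0.34 while
1.96 x SD(r-hat) is ~0.37, and the spread shrinks in proportion to
(1 - r-hat^2) exactly when |r-hat| is large, making the rule
anti-conservative. The calibration test in the acceptance suite measures
this rate directly and documents it; the rule is nevertheless implemented
exactly as stated, since it is the procedure under study.

PCR regresses SRI on the leading principal components of the twelve
standardized predictors and back-transforms coefficients to the original
scale. The published component-selection criterion used by the original
procedure (the "PVP criterion") is not specified in a reproducible form, so
the default rule -- drop components with correlation-matrix eigenvalue below
0.7 x the mean eigenvalue -- is a clearly labelled stand-in behind a
swappable `selection` interface. Retaining all components provably reproduces
ordinary least squares, and a test asserts this identity.

## What the synthetic generator emulates

`climate_config()` defaults encode the target climate regime as monthly
normals: annual rainfall ~1,220 mm with ~85% in June--October, September
wettest (277 mm) and April driest (8 mm); annual mean air temperature
~6.6 C with May warmest (8.4 C) and January coldest (4.2 C); damped soil
temperatures that stay above 3.5 C in winter yet sit below the air mean in
winter and above it in summer; relative humidity peaking in September;
insolation peaking in spring before monsoon cloudiness. Mechanically:

* **Precipitation** is per-slot Bernoulli occurrence with gamma intensities
  (monthly parameters), modulated by a persistent daily cloudiness anomaly, a
  yearly monsoon-strength factor (log-sd 0.07) and small per-month jitter.
  The yearly factor scales all monsoon months together, so wet and dry years
  occur without distorting the within-season shape. These variance parameters
  are deliberately modest: they give ~+-10% interannual spread in annual
  totals (somewhat narrower than real monsoon variability) so that
  multi-year climatological summaries are stable at the 7-year problem size
  used throughout.
* **Air temperature** follows the seasonal normals (periodic-spline
  interpolated to day of year) plus an AR(1) daily anomaly and a diel cosine
  peaking at 14:00 with month-specific amplitude.
* **Soil temperature** is a seasonal soil baseline plus an exponentially
  smoothed (strongly damped) transform of the half-hourly air anomaly. A
  single constant offset from air temperature cannot reproduce the observed
  pattern -- winter soil means below the air mean but above 3.5 C, summer
  means above it, and a diurnal range a fraction of the air range -- so the
  seasonal baseline is specified directly and only the anomaly is
  transferred.
* **Humidity, radiation, soil moisture, pressure, wind** are built from the
  same anomalies with the right signs (cloudy days: wetter, dimmer, more
  humid), giving realistic cross-correlations among predictors.

`stem_config()` builds each tree as baseline + cumulative true increment +
diel cycle + Gaussian reading noise. The diel term is a double cosine ramp
with maximum at 11:30 and minimum at 18:30; its default 60 um contraction
depth is *uncalibrated* (the source material describes the shape and timing
but prints no amplitude) and is flagged as such. Daily growth accrues from
midnight and completes by the diel maximum, so with noise off the day's
maximum equals baseline plus cumulative increment exactly and the SRI
pipeline recovers the generator's ground truth day by day -- the closure test
the whole chain is scored against. The seasonal rate curve is a skewed
Gaussian peaking mid-May (sharp 30-day spring rise, slow 75-day monsoon
decay) over a small year-round base rate, scaled so the April--September mean
is 15 um/day; growth is gated to zero on days whose mean soil temperature is
below 5 C (the documented onset band is 4--6 C), and the resulting monthly
shares exceed 5% exactly in April--September with the May maximum.

Two climate signals are deliberately encoded for recovery testing: daily
increments scale log-linearly with the soil-temperature anomaly in
April--May and with the precipitation anomaly in June--July (strength 0.5
each). The multipliers are normalized to mean one within each year-month, so
they redistribute growth within a month without changing monthly totals --
the correlation signal is preserved while calibration summaries stay stable.
Artifacts (isolated gaps, full-day outage windows, additive spikes with
substantial mass above 350 um) are injected by a separate operation that logs
every corruption so filters can be scored. Ground truth is emitted on a
separate channel the pipeline never reads.

What the generator does **not** emulate: physically based sap-flow or water
storage dynamics, snow, lightning, bark hydration, within-day growth timing
beyond the ramp, or autocorrelated sensor drift. Passing tests therefore
demonstrate that the pipeline implements its rules correctly and recovers
known signals under realistic noise -- not that it would be unbiased on any
particular field deployment.

## Numerical and design choices

* Timestamps are naive local standard time on a strict half-hour grid; each
  stamp labels the interval it closes. No daylight-saving logic (the site is
  near 19 N).
* Stem readings are sensor-relative displacements; all downstream math uses
  differences, and a test asserts SRI is invariant to the origin.
* Range-check boundaries are inclusive; the growing-season rule is strict
  (`> 5%`), as is the spurious rule (`> 350`), with ties on run length going
  to the earliest run.
* Growth onset requires 5 consecutive qualifying days, so a one-day
  soil-temperature blip does not start the season.
* Diel-phase decomposition uses the day's observed extrema, not clock times:
  contraction = maximum-to-subsequent-minimum fall; expansion = recovery
  capped at the contraction; increment as in SRI.
* All randomness descends from one root seed; per-tree substreams are drawn
  from it, and every public stochastic function is bit-reproducible under a
  fixed seed.
* Problem sizes in the tests and acceptance script -- 7 simulated years for
  climatology, one focal year for SRI, 200 replicates for the significance
  calibration, 50 replicates for signal recovery -- were chosen as the
  smallest sizes at which the corresponding summaries are statistically
  stable (sampling SD comfortably inside the stated tolerances).

## Known limitations

* The PVP component-selection rule is a stand-in (see above).
* The percentile-spread significance rule is anti-conservative at monthly
  sample sizes; results tables inherit that property by design.
* The iid day bootstrap ignores within-month autocorrelation.
* Thermal-expansion errors of the sensors (17 um per 10 C for a point
  dendrometer's 10 cm rod; 112 um per 10 C for a band on a 1 m
  circumference) are quantified by `thermal_error()` but deliberately not
  subtracted from the series, since they are small against water-related
  stem changes at the daily-maximum timescale.
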