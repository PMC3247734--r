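# dendrosri

Processing and analysis of automated point-dendrometer records from a
tropical treeline monitoring campaign: from half-hourly stem-radius and
weather-station readings to daily **Stem Radial Increment (SRI)** series and
monthly bootstrapped growth–climate response tables.

The package is aimed at dendroecologists working with high-resolution
dendrometer data in monsoon-dominated, high-elevation settings, where the
reversible diel cycle of stem swelling and shrinking must be separated from
irreversible wood growth before any climate attribution is possible.

## The method

For each tree and calendar day, growth is the positive part of the change in
daily maximum stem size,

```
SRI(t) = max(0, max_stem(t) − max_stem(t−1)),
```

with day-over-day differences above 350 μm treated as spurious (set missing)
and days without a usable previous maximum left missing. Daily weather
summaries include the twelve explanatory variables — SolRad, Prec, TSmax,
TSmin, TAmax, TAmin, RH, SWV, AirPr, WG, WS and VPD — where vapor pressure
deficit is derived per half hour from

```
SVP = 6.11 · exp(17.2693882 · AT / (AT + 237.3))          [hPa]
VP  = RH · SVP · P / (RH · SVP + 100 · (P − SVP))         [hPa]
VPD = SVP − VP
```

and then averaged over the day. For every month with at least 21 paired
days, 1,000 bootstrap resamples of day pairs yield a median Pearson
correlation (and, optionally, principal-component-regression coefficients)
per variable; the median is significant when its absolute value exceeds half
the spread between the 97.5th and 2.5th bootstrap percentiles. Results are
tabulated as signed coefficients, `ns` (tested, not significant) or `/`
(data unavailable).

Because no field dataset is distributed, a calibrated synthetic generator
emulates the study conditions — a North American Monsoon climate
(~1,220 mm yr⁻¹, ~85% falling June–October, September wettest at ~277 mm,
annual mean air temperature ~6.6 °C) and a diel stem cycle with a pre-noon
maximum over a May-peaking growth season gated by a ~5 °C soil-temperature
onset — with ground-truth daily increments emitted on a separate channel.
See the methods vignette (`vignettes/stem-growth-climate.Rmd`) for the full
model description and design rationale.

## Worked example

The `analysis/` directory holds the four-stage workflow; each stage is a
thin driver over package functions and writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # 7 y weather + 1 y stem series + artifacts
Rscript analysis/02_daily_summaries.R   # ingest -> daily table -> monthly climatology
Rscript analysis/03_sri_growth.R        # SRI, cumulative growth, phenology
Rscript analysis/04_climate_response.R  # monthly bootstrap correlations + PCR
```

A run with the scripts' default seed prints, among other things:

```
mean annual rainfall 1215 mm (range 926-1449); 85.4% falls Jun-Oct
wettest month: 9 (289 mm); mean annual air temperature 6.66 C
monthly growth shares peak in month 5 (20.3%); season months 4-9
growing-season daily SRI: mean 16.1 um, sd 11.9 um
soil-temperature growth onset (5 C sustained): 2002-03-09
```

i.e. the simulated climate regime matches its calibration targets, growth
peaks in May, the >5%-per-month growing season runs April–September, and
growth switches on when mean daily soil temperature sustains 5 °C in early
March. The stage-4 response table recovers the generator's encoded signals
with the expected seasonal structure — positive soil-temperature
correlations in spring, and at the monsoon onset a positive precipitation
signal with its negative solar-radiation/VPD counterpart (a drought signal
during the wet season):

```
        SolRad  Prec   TSmax  TSmin  ...  RH     ...  VPD
2002-04 ns      ns     0.69   0.63        ns          ns
2002-05 -0.24   ns     0.57   0.57        0.35        ns
2002-06 -0.62   0.97   ns     ns          0.63        -0.63
2002-07 ns      0.97   ns     ns          ns          ns
```

Sensor-error context: `thermal_error()` quantifies temperature-driven
apparent stem change — 17 μm per 10 °C for a point dendrometer's 10 cm rod
versus 112 μm per 10 °C for a band dendrometer on a 1 m circumference —
which is why point-sensor SRI is analyzed and the error is not corrected
for.

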