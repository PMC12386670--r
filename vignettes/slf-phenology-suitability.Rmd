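---
title: "Methods: degree-day phenology and climatic suitability for the spotted lanternfly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: degree-day phenology and climatic suitability for the spotted lanternfly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slfrisk)
```

## The model in brief

`slfrisk` implements a linear, cohort-structured degree-day model of
spotted-lanternfly (*Lycorma delicatula*) seasonal development on daily
Tmin/Tmax rasters, coupled with a climatic-suitability model driven by
cold- and heat-stress accumulation. Linear thermal-time models are the
norm for operational decision support: the lanternfly's published
temperature–development data are well fitted by a straight line, daily
gridded extremes are the best spatial data routinely available, and
non-linear rate models would demand sub-daily inputs and far more
computation for little accuracy gain on this pest.

The life cycle is univoltine with the egg overwintering. Following the
four-stage convention of degree-day platforms, the nymphal instars 1–4 are
modelled as the "larval" stage, the pre-oviposition adult period as the
"pupal" stage, and the first-to-50%-oviposition period as the "adult"
stage; the model year starts 1 January and each cohort halts after one
complete cycle (obligate diapause — eggs need chilling before they can
resume development, so a second within-year generation is not simulated).

## Daily thermal arithmetic

Degree-days use the single-triangle method with an upper threshold: the
day's temperature trace is a triangle from Tmin up to Tmax and back, and
accumulation is the triangle area above the lower developmental threshold
(LDT) with the region above the upper threshold (UDT) cut off horizontally
(temperatures above the UDT contribute as if equal to it). The closed form
is exact, continuous in both extremes, bounded by UDT − LDT, and is
verified in the test suite against brute-force 1-minute integration of the
triangular wave (1,000 randomized days; agreement well below 0.05 °C·d).

Stress units reuse the same triangular geometry for internal consistency:
cold stress is the area *below* the cold threshold, heat stress the area
*above* the heat threshold, with no second cutoff. The integration rule
for stress is a package definition — platforms differ here and the choice
is documented rather than hidden — but any rule monotone in the daily
extremes would produce the same exclusion geography up to recalibration of
the unit limits.

Degenerate inputs are handled explicitly: a constant day (Tmin = Tmax)
contributes max(T − LDT, 0) capped at the UDT; Tmax < Tmin is an error at
the arithmetic level and is coerced to nodata (with a logged count) when
reading external rasters, where such artifacts occur.

## Parameters

All species parameters ship in a flat `key = value` file
(`inst/extdata/spotted_lanternfly.params`) using the standard code names.

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `eggLDT` … `adultLDT` | 10 | °C | common lower developmental threshold |
| `eggUDT` … `adultUDT` | 35 | °C | common upper threshold (horizontal cutoff) |
| `eggDD`, `larvaeDD`, `pupDD`, `adultDD` | 202, 890, 630, 146 | °C·d | stage durations |
| `larvaeEventDD` | 442 | °C·d | nymphs-halfway trigger (within stage) |
| `pupaeEventDD`, `adultEventDD` | 1, 1 | °C·d | adult-emergence / oviposition triggers |
| `eggEventDD` | 100 | °C·d | diapausing-egg trigger |
| `distro_mean`, `distro_var` | 190, 15000 | °C·d, (°C·d)² | overwintered-egg completion distribution |
| `xdist1`, `xdist2`, `ncohorts` | 135, 360, 7 | °C·d | distribution bounds and cohort count |
| `coldstress_threshold` | −16 | °C | cold stress threshold |
| `coldstress_units_max1/2` | 300 / 475 | °C·d | moderate / severe cold limits |
| `heatstress_threshold` | 37 | °C | heat stress threshold |
| `heatstress_units_max1/2` | 115 / 175 | °C·d | moderate / severe heat limits |

Note that `distro_mean` (190) differs from `eggDD` (202) by design: the
cohort requirement governs completion of the *overwintered* egg, whose
development partially advances before 1 January, whereas `eggDD` applies
to the freshly laid first-generation egg. The `larvaeEventDD` value 442 is
used verbatim (not `larvaeDD / 2` = 445); it encodes the halfway point as
published for the platform rather than a derived rounding.

## Cohort discretization

The distribution of hatch requirements is specified by shape (normal),
mean, variance, bounds, and cohort count — but not by a discretization
rule. The package's rule is chosen to be deterministic and testable:
partition [`xdist1`, `xdist2`] into `ncohorts` equal-width bins, set each
cohort's requirement to its bin midpoint, and weight it by the normal
probability mass of the bin renormalized over the truncated range.

```{r cohorts}
build_cohorts(species_params())
```

Weights are validated against numeric integration of the truncated normal
density to 1e-6 and sum to 1 within 1e-9. Other discretizations (equal
mass, quantile midpoints) would shift event dates by at most a few days;
the equal-width rule keeps the requirement spacing independent of the
variance, which makes the calibration search better conditioned.

## The daily engine

Per cell and cohort, each day's degree-days under the current stage's
thresholds are added to a within-stage accumulator. The overwintered egg
completes — the egg-hatch event — when *cumulative* degree-days since 1
January reach the cohort's requirement; subsequent stages complete at
their stage durations, and events fire on the first day the within-stage
accumulator reaches the event trigger (ties at exact equality fire that
day; day-of-year is 1-based). Excess degree-days on a transition day carry
into the next stage — without the carry, every transition would be biased
late by up to one day's accumulation, which compounds over four
transitions. The event/transition loop re-checks after each transition, so
a stage crossed entirely within one day (possible for the 1-DD triggers)
still registers its event. Cohorts are independent: no density effects,
no interactions.

Nodata handling is deliberately strict: a cell missing either temperature
on any day carries no predictions at all (every event map is nodata
there). Partial-year imputation would silently bias accumulation and is
out of scope.

Event maps are reduced over cohorts in two ways: `earliest` (minimum
day-of-year — "first" events) and `weighted_mean` (cohort-weighted average
over the cohorts in which the event occurred, weights renormalized over
those cohorts — "peak" events). For validation against overwintered-egg
encounters, the *last* egg hatch (the latest cohort's hatch) is the
relevant prediction, since hatch ends the availability of overwintered
eggs.

## Climatic suitability

Annual cold and heat stress units are classified against the moderate
(`max1`) and severe (`max2`) limits. Boundary semantics are strict
inequality — a cell is moderately excluded only when units *exceed*
`max1`, severely only beyond `max2` — chosen for determinacy since the
calibration narrative says only "exceed"; the tests pin the boundaries
exactly. The combined category is the worse of cold and heat, and the
multi-year potential distribution counts the years with combined category
`none`. Stress never decays within a year (no recovery from thermal
stress), and exclusion does not kill cohorts mid-simulation: suitability
is an overlay on the phenology maps, not a feedback, which matches how
the map products present the two layers.

## Calibration

`x_intercept_fit()` is ordinary least squares of development rate (1/days)
on temperature; the lower threshold is the x-intercept −a/b and the stage
duration 1/b. The published phrase "forcing through the x-intercept" could
alternatively denote a constrained regression, but no constraint is
specified; plain OLS with the threshold read from the x-intercept is the
standard reading of the x-intercept method and recovers noise-free
parameters exactly (tested to 1e-9).

`select_cohort_params()` ranks candidate (`xdist1`, `distro_mean`,
`xdist2`) triples — variance fixed at 15,000 °C·d² — by fewest
overpredictions (predicted hatch later than observed), then lowest MAE,
then smallest |bias|. The primary criterion is the published one; the MAE
and |bias| tie-breaks are the package's definition, ordered so that
accuracy breaks ties before direction. Earliest and peak comparisons are
pooled into a single difference vector. The search provably recovers
generating parameters from engine-generated observations (five synthetic
site-years in the tests).

## Validation machinery

Monitoring-style first-date records are paired with predicted event days
at the nearest grid cell (no interpolation — cells are the model's native
resolution) and summarized by MAE, bias (predicted − observed) with SD and
range, and an OLS regression of predicted on observed day with pointwise
95% confidence and prediction intervals; interval lengths are averaged
over the observed points. The prediction-interval formulas are validated
by simulation: empirical coverage of held-out Gaussian observations is
within 2 percentage points of 95% over 1,000 replicates.

Single-encounter records carry no first-appearance information, so they
support only a directional test: a one-sided paired Wilcoxon signed-rank
test of whether predictions fall before observations (after observations,
for overwintered eggs). Zero differences are dropped and |difference| ties
take midranks; the null distribution is exact for n ≤ 25 without ties and
a normal approximation with continuity correction otherwise. The
implementation is cross-checked against full 2^n sign-pattern enumeration
in the tests. Stage concordance compares the predicted stage on the
record's date — cohort-weighted modal by default, earliest-cohort
optionally, since platforms differ on this and both views are useful —
against the observed stage on the ordered scale overwintered egg < early
nymph < late nymph < adult < first-generation egg, with nymphs split at
the 442-DD halfway trigger and both adult periods presenting as adults.
A published "31 June" cutoff for separating overwintered from
first-generation egg observations is read as 30 June (the date does not
exist).

## Synthetic climate

The generator emulates the structure that matters to this model in
mid-latitude gridded daily products: a latitudinal mean-temperature
gradient (default 0.8 °C per degree, annual mean 14 °C at 45°N–35°N
domain centre), a sinusoidal seasonal cycle (amplitude 12 °C, peak near
day 200), a fixed diurnal range (10 °C) split evenly around the daily
mean, and independent Gaussian day/cell noise (SD 2 °C). These defaults
describe a generic eastern-North-American study window at the model's
working resolution.

What it does *not* emulate: spatially and temporally autocorrelated
weather systems, elevation, coastal moderation, skewed diurnal cycles,
heat waves and cold snaps with realistic persistence, or shared
interannual variability. Tests passing on synthetic grids therefore
demonstrate the *mechanics* of the model — thermal arithmetic, cohort
bookkeeping, event ordering, monotone responses, exclusion geography —
not predictive skill on real landscapes, which requires real climate
rasters and field observations.

With zero noise the generator is a closed-form function of latitude and
day, which the tests assert exactly; with a fixed seed it is reproducible
bit-for-bit (the global RNG state is saved and restored around the draw).

## Numerical and format choices

- All degree-day arithmetic is double precision; daily accumulation is
  date-ascending, so results are bitwise reproducible.
- Weekly extremes (coldest-week Tmin, hottest-week Tmax) use rolling
  7-day windows over every alignment rather than calendar weeks: a
  "coldest week" is an extreme, and the rolling minimum bounds any
  calendar-week value from below.
- Leap years use the actual day count; day-of-year is 1-based throughout.
- Rasters are stored as 32-bit TIFF with a JSON sidecar carrying extent,
  CRS, dates and the linear packing scale (samples are packed into
  [0.05, 0.95], with 0 reserved for nodata); round-trip error is below
  1e-4 °C. Rasters are north-up, row 1 northernmost; observations are
  matched to cells after transforming coordinates to the grid's CRS.
- Block-mean aggregation averages the valid cells of each block; an
  all-nodata block stays nodata; trailing partial blocks average the
  cells they contain.

## Problem sizes

The shipped checks run on deliberately small instances chosen to exercise
every code path while staying instant: 20 × 20-cell synthetic grids for
annual runs, 1,000 randomized days for the integration oracle, 1,000
replicates for interval coverage, five synthetic site-years for the
cohort search, and 3-year stacks for the potential-distribution
combination. All quantities scale linearly in cells × days × cohorts, so
continental runs differ only in wall time.

## Known limitations

- No host-plant effects on development or survival, though host species
  measurably affect nymphal development time.
- No mechanistic diapause termination (chilling/photoperiod); the cohort
  distribution absorbs this variation empirically, and its calibration
  may not transfer to regions with much shorter or longer winters.
- No moisture or precipitation suitability factors; temperature is the
  only survival-limiting variable.
- Thermal tolerances are constant within and across populations; no
  acclimation, body-size, or alternating-regime effects.
- Single calendar year per run: cohorts partially developed at year end
  do not carry over, consistent with obligate diapause but not with
  climates where development continues across the boundary.
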