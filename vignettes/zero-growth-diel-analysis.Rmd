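---
title: "Partitioning dendrometer records into growth and water deficit: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning dendrometer records into growth and water deficit: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrodiel)
```

## The problem

Point dendrometers record stem-radius displacement at micrometre resolution
every ten minutes. The signal mixes two processes: irreversible radial growth
(new wood and bark cells) and reversible shrinking/swelling of the elastic
tissues, mainly the bark, as the tree dehydrates during transpiration and
rehydrates at night. Any statement about *when* trees grow over the 24-h
cycle, and how growth responds to atmospheric dryness (vapour pressure
deficit, VPD) and soil dryness (soil water potential, SWP), requires
separating those two components first.

`dendrodiel` implements that separation and the downstream hourly-resolved
diel analysis as a reusable pipeline, together with a synthetic-forest
generator that provides ground truth, so every stage can be validated
offline.

## The zero-growth partition

The partition rests on the turgor-threshold premise of cell expansion
(Lockhart's model): cell walls yield irreversibly only above a minimum
turgor, and a shrinking stem implies turgor below that threshold. Radial
growth is therefore booked only when the radius exceeds its previous
maximum. With $M(t) = \max_{u \le t} r(u)$ initialized at the first
observation:

$$\mathrm{GRO}_{inc}(t) = M(t) - M(t-1) \ \ge 0, \qquad
  \mathrm{TWD}(t) = M(t) - r(t) \ \ge 0,$$

so that $r(t) - r(t_0) = \mathrm{GRO}_{cum}(t) - \mathrm{TWD}(t)$ holds
exactly (asserted to $10^{-9}\,\mu m$ on every partition in the test suite).
Ties with the running maximum are neither growth nor deficit. The running
maximum persists across data gaps; growth detected directly after a gap
longer than 6 h is real but of uncertain timing and carries an ambiguity
flag. The rule is invariant to the sensor baseline (only displacements
matter) and to constant offsets.

Assumptions worth stating plainly: (1) no growth occurs below the previous
radius maximum -- growth that physiologically happens during shrinkage is
attributed to the next maximum-exceeding hour; (2) hygroscopic bark swelling
and winter bark decomposition are not modelled; (3) the first observation is
taken as the historical maximum, since any pre-history assumption would be
unverifiable.

## Pipeline stages and their parameters

**Cleaning** (`clean_series`) is a deliberately simple three-pass procedure,
not a re-implementation of any specific production tool: (i) spike removal
-- a point whose deviation from the running median over `spike_window` (7
points, 70 min) exceeds `spike_mad_factor` (7) times the local MAD is
removed; the local MAD is floored by the series-wide MAD because a nested
running median degenerates to zero wherever the window median coincides with
a data value; (ii) a single step larger than `shift_threshold_um` (50 um)
not reversed within the spike window is treated as a sensor shift and
subtracted from everything after it; (iii) gaps up to `max_gap_fill` (3 h)
are linearly interpolated and flagged. With sensible data the cleaner is
idempotent and touches well under 1% of points.

**Hourly aggregation** (`to_hourly`) takes arithmetic means over
[h:00, h+1:00); hours without data stay absent. All timestamps are local
standard time without daylight-saving shifts, because diel statistics are
meaningless across DST discontinuities; hour-of-day h labels the interval
[h:00, h+1:00).

**Partition resolution.** The partition can run on hourly means (the
default, matching how network analyses are usually done) or on the native
10-min series with increments summed per hour (`partition_resolution =
"native"`). The two differ in hour *attribution*, not in mass: an hourly
mean sits mid-way between the bounding states, so each increment between
consecutive means straddles two labelled hours and roughly 7/12 of every
episode's final increment spills into the following label. On synthetic data
with known truth the hourly route attributes about 92% of grown micrometres
to the correct hour, the native route about 98.5%; total recovered growth is
identical. Validation against ground truth therefore uses the native route;
sub-hourly increments are attributed to the hour containing their
measurement span.

**Growth period** (`detect_growth_periods`): per site x species x year, each
tree's cumulative annual growth curve is normalized to its total, the curves
are averaged, and the period runs from the 5% to the 95% crossing of the
averaged curve. We read the "first and last 5%" trimming as 5% of
*cumulative growth*, not of calendar time, because its purpose is to keep
isolated out-of-season micro-increments from defining the period; a
calendar-based alternative (`rule = "time"`) is provided and the two agree
for uniform growth. By construction the period holds 90% of the averaged
annual growth.

**Inclusion filters** (`apply_inclusion_filters`) implement the network
criteria: tree-years with annual increment at or below 100 um or covering at
most 90% of the group period are dropped, as are species at fewer than 4
sites, series with fewer than 3 years, and site x species groups with fewer
than 2 individuals. All criteria are evaluated simultaneously on the
unfiltered table, which makes the surviving set independent of evaluation
order. For small simulated designs the site/year thresholds are relaxed to 1
(they describe a 50-site network, not a 1-site simulation).

**Diel statistics** (`tree_diel_profile`, `aggregate_profiles`): the
tree-year contribution of hour-of-day h is 100 x (growth at h) / (annual
growth in the period), so the 24 bins sum to 100; growth probability is the
percentage of period hours at that hour-of-day that are growth hours (a
config switch provides the alternative all-hours/24 denominator); rates are
medians over growth hours, unnormalized. Aggregation is
mean-within-site-x-species, then median with 25%/75% quantiles across units
(per species and pooled). Quantiles use linear interpolation between order
statistics (R type 7) throughout. Multi-year trees average their yearly
vectors arithmetically. Tree-level contributions sum to 100 exactly;
aggregated medians need not, and are not renormalized.

**Environmental response** (`response_surface`, `bootstrap_cov`,
`growth_envelope`, `median_condition_curves`): VPD comes from the Magnus
(Tetens) form $e_s(T) = 0.6108\,\exp(17.27\,T/(T+237.3))$ kPa over water --
the standard ecophysiological choice; constants are arguments. Growth is
binned over (VPD x SWP) or (hour x environment) grids, default 0.05 kPa
bins on [0, 1.5] and 50 kPa bins on [-1000, 0] -- fine enough to resolve the
sub-0.4-kPa structure where growth concentrates, coarse enough to keep cells
populated; out-of-range observations fall into the edge bins. Cell masses
follow the same nested averaging as the diel profiles and sum to 100 before
smoothing; cells without observations are masked. A loess smoother (span
0.75, degree 2 -- the conventional local-regression defaults) interpolates
over unmasked cells, and the fraction of binned variance it captures is
reported so users can tune the span. Uncertainty per cell is the coefficient
of variation over 1000 bootstrap resamples of the site x species units (the
level at which the surfaces are built), classed very good (< 10), good
(10 to < 20), satisfactory (20-50) and poor (> 50); cells with zero
bootstrap mean are classed poor rather than propagating a division by zero.
Units are sorted by name before resampling so results do not depend on input
order.

**Cross-species regressions** (`summarize_species`, `regress_peak_time`):
the species summary collects the median hourly growth rate over growth
hours, the diel peak/trough hours (argmax/argmin of the median contribution
profile, ties to the earliest hour), the adjusted R^2 of diel growth against
diel VPD, and medians with quartiles of annual growth hours and annual
increment across tree-years. Peak-timing regressions are ordinary least
squares across species medians with two-sided t-tests on the slope. A
published seven-species reference table ships with the package
(`reference_species_summary()`) so these regressions are exercisable without
any external data.

## What the synthetic forest emulates

The generator encodes exactly the statistical structure the analysis
assumes, with one mechanism per phenomenon:

* **Weather**: hourly temperature = seasonal sinusoid (mean 9 C, amplitude
  9 C, peak day 200) + diel sinusoid (amplitude 5 C, peak 14:00) + AR(1)
  anomaly (phi 0.8, sd 1.5 C); relative humidity in anti-phase (base 85%,
  diel amplitude 20%), saturating at night. Rain arrives as day-anchored
  frontal events (probability 0.3/day, starting 10:00-20:00, lasting
  12-30 h) during which RH is at saturation except for a small midday
  evaporative dip (4% RH), so even rainy afternoons retain a residual VPD.
  SWP is a daily bucket: drawdown 3 kPa per kPa h of daily VPD sum, 50% step
  recharge on rain days, clipped at -1500 kPa.
* **Tree**: a water pool w (um) relaxes toward $-c\,\mathrm{VPD}$ with time
  constant tau (c = 30 um/kPa, tau = 3 h); growth accrues at g = 2 um/h
  (within the observed range of species median rates) only while the pool
  exceeds -0.5 um at *both* hour boundaries -- so no growth is booked into
  an hour in which turgor collapses -- and VPD < 0.4 kPa, SWP > -900 kPa,
  and the day-of-year lies in the season (110-280). A `diel_offset` lags the
  pool's response to atmospheric demand, emulating slow-rehydration species
  whose growth window sits later in the night; because the lag shifts the
  *observable* hydration cycle, the offset is recoverable downstream.
* **Measurement**: radius = cumulative growth + pool, linearly interpolated
  from the hourly state to the 10-min grid, plus Gaussian noise (sd 0.2 um,
  reflecting sub-micrometre logging resolution), with optional injected
  spikes and permanent shifts recorded in the truth flags.

Under these defaults one tree grows roughly 400-800 um in 350-600 growth
hours per year, growth peaks in the second half of the night with an
afternoon minimum, the nocturnal bins carry the majority of the annual
contribution, and all true growth lies inside the VPD < 0.4 kPa,
SWP > -900 kPa envelope -- the regimes the analysis is meant to detect.
(The numbers the package actually reproduces are computed by the test suite
and by `scripts/acceptance.R`, not asserted here.)

What the generator does *not* emulate: osmotic adjustment, frost shrinkage,
hygroscopic bark swelling, sensor temperature drift, xylem hydraulics, or
any circadian control beyond the hydration lag. Passing tests on this forest
therefore validate the pipeline's arithmetic and its recovery of
hydration-gated growth; they do not certify the zero-growth premise itself
on real trees, which remains untestable without an independent growth
measurement.

## Numerical choices and degenerate inputs

* Quantile convention: linear interpolation (type 7) everywhere.
* Peak-timing ties break toward the earliest hour; an all-equal profile
  returns hour 0 with a degeneracy warning.
* A constant diel profile regressed on covariates reports R^2 = 0 (not NaN).
* Zero-growth tree-years are an error at the profile step (the filters
  should have removed them); zero-growth groups yield "no period".
* Positive SWP readings are clamped to 0 with a warning; SWP below
  -1e5 kPa is rejected as non-physical. RH outside [0, 100] is an error.
* Cells with zero bootstrap mean are "poor"; masked cells carry no value.
* The smallest-VPD-bound search returns NA with a warning when the target
  fraction is unreachable at the given SWP bound.

## Known limitations

* **Hour attribution at hourly resolution.** Averaging to hourly means
  blurs each boundary increment across two labels (about 92% correct-hour
  attribution on ground truth versus about 98.5% at native resolution).
  Diel profiles are affected by at most one hour of smear.
* **Growth-hour counts are upward-biased.** Counting is threshold-free, so
  any noise exceedance at the hydration frontier and the marginal onset hour
  of each episode count as growth hours; with noise sd 0.2 um the count can
  exceed truth by 20-40% even though the growth *mass* is recovered almost
  exactly. Counts are recovered within 10% on noise-free data. Annual
  growth-hour statistics from any zero-growth implementation share this
  property.
* **Short-episode onset deficits.** When an episode starts, the first
  grown micrometres fill the gap between the current radius and the running
  maximum left by the previous episode, so their timing is slightly late.
* **The species-level diel-growth-vs-VPD R^2** on the default synthetic
  forest is lower than typical field values: simulated growth is gated
  (nearly binary in VPD) rather than linearly graded, which weakens a linear
  fit. The regression machinery itself is validated on constructed linear
  profiles.

## Problem sizes

The shipped tests and the acceptance script run on desk-scale inputs chosen
to exercise every code path while completing quickly: the default forest (1
site x 4 trees x 1 year at 10-min resolution, about 210,000 observations),
a two-site and a two-species variant for aggregation and recovery checks,
100 random walks of 1000 points for the brute-force oracle, and 10,000
bootstrap resamples for the two-unit enumeration check.
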