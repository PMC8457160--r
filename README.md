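# dendrodiel

Hourly-resolved analysis of radial stem growth from point-dendrometer
networks.

High-precision dendrometers record stem-radius displacement (µm) every ten
minutes, but the record mixes irreversible growth with reversible
water-driven shrinking and swelling of the bark. `dendrodiel` is for
ecophysiologists who want to know *when* trees grow over the day–night
cycle and how growth depends on atmospheric and soil dryness: it separates
the two components, computes diel growth statistics through a nested
tree → site×species → species aggregation, relates growth to vapour
pressure deficit (VPD) and soil water potential (SWP), and runs the
cross-species regressions of diel peak timing against annual growth. A
synthetic-forest generator with ground-truth growth makes every stage
testable offline.

## The core method

Under the turgor-threshold view of cell expansion, a shrinking stem cannot
grow. The **zero-growth partition** therefore books growth only when the
radius exceeds its running maximum `M(t) = max(r(u), u ≤ t)`:

```
GRO_inc(t) = M(t) − M(t−1) ≥ 0        irreversible growth per hour
TWD(t)     = M(t) − r(t)   ≥ 0        tree water deficit
r(t) − r(t0) = GRO_cum(t) − TWD(t)    exact conservation
```

Hours with `GRO_inc > 0` are *growth hours*. Downstream, the relative
contribution of each hour-of-day to annual growth (24 bins summing to
100%), the growth probability per hour-of-day, and median hourly growth
rates are aggregated as means within site×species and medians (with
quartiles) across units. Growth–environment structure comes as binned,
loess-smoothed response surfaces over (VPD × SWP) with per-cell bootstrap
coefficients of variation, main-growth envelopes (fraction of growth with
`VPD < 0.4 kPa` and `SWP > −900 kPa`), and median-condition curves.

## Worked example

Simulate the default forest (1 site, 4 trees, 1 year, 10-min resolution),
run the full analysis, and inspect the species summary:

```r
library(dendrodiel)

forest <- generate_forest(synthetic_config(seed = 1))
res <- analyze_forest(forest)

res$summary[, c("species", "gro_hr", "time_gro_max", "time_gro_min",
                "h_gro_yr", "gro_yr")]
#>   species gro_hr time_gro_max time_gro_min h_gro_yr gro_yr
#> 1     SPA   1.92            5           12      530    785
```

The simulated species grows at a median 1.92 µm per growth hour, its diel
contribution peaks at 05:00 and bottoms out at noon, and the median tree
accumulates 785 µm over 530 growth hours per year. The pooled diel profile
shows the nocturnal rise toward the pre-dawn peak:

```r
head(res$agg$pooled[, c("hour", "contribution_pct", "probability_pct",
                        "rate_um_h")], 8)
#>   hour contribution_pct probability_pct rate_um_h
#> 1    0             4.86            16.4      1.53
#> 2    1             7.29            22.5      2.00
#> 3    2             9.12            29.1      1.96
#> 4    3            11.36            34.4      2.00
#> 5    4            13.51            40.9      1.99
#> 6    5            14.80            50.9      1.91
#> 7    6            12.20            42.9      1.66
#> 8    7             8.29            25.3      1.96

growth_envelope(res$joined, vpd_max = 0.4, swp_min = -900)
#> [1] 100
```

(contribution in % of annual growth per hour-of-day; probability in % of
period hours at that hour-of-day that are growth hours; rates in µm h⁻¹ —
here all recovered growth falls inside the humid envelope, as configured.)

The cross-species peak-timing regressions run on the shipped seven-species
reference table:

```r
ref <- reference_species_summary()
regress_peak_time(ref, "h_gro_yr")
#> Cross-species fit: h_gro_yr ~ time_gro_max (n = 7 species)
#>   slope -75.331  intercept 770.9  R2 0.803  adj R2 0.764  p 0.006294
regress_peak_time(ref, "gro_yr")
#> Cross-species fit: gro_yr ~ time_gro_max (n = 7 species)
#>   slope -146.735  intercept 1726.5  R2 0.502  adj R2 0.402  p 0.07492
```

Species that reach their diel growth peak earlier in the night accumulate
more growth hours and more annual increment.

A file-based pipeline (`run_pipeline()`, or `Rscript scripts/dendrodiel.R
<subcommand> --out DIR --seed N`) materializes every stage as CSV
(`partition.csv`, `periods.csv`, `profiles.csv`, `grid.csv`,
`summary.csv`, `report.json`) so stages can be re-run and inspected
independently.

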