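# thermoreg

Behavioural thermoregulation analysis for field studies of small ectotherms,
built around the classical null-model (Hertz) protocol and a two-era warming
comparison for an alpine lizard population. The package estimates a preferred
temperature range from laboratory thermal-gradient selections, scores field
body temperatures and operative (copper-model) temperatures against it,
computes bootstrap-supported thermoregulation indices, profiles microhabitat
thermal quality hour by hour, contrasts two sampling eras a quarter-century
apart, and reports thermal safety margins below the optimal performance
temperature. Because the original field data are not publicly deposited, the
package also ships calibrated synthetic-data generators that reproduce the
statistical structure of the study — sample sizes, means, dispersions,
regression slopes and explained variance — so the whole analysis is runnable
and testable end to end.

## The science in brief

A thermoregulating lizard keeps its body temperature T_b near a preferred
range it selects when temperature is free (the PTR, the central 50% of
gradient selections). How hard it must work depends on the habitat: operative
temperatures T_e measured by physical null models describe what a
non-regulating animal would experience. With `d(t) = max(0, lower − t,
t − upper)` the deviation from the PTR, the protocol's indices are

- **accuracy** `mean d_b` — mean deviation of field body temperatures,
- **thermal quality** `mean d_e` — mean deviation of operative temperatures,
- **effectiveness** `E = 1 − mean d_b / mean d_e` — 1 for a perfect
  thermoregulator, 0 for a thermoconformer.

Standard errors come from independently bootstrapping the two deviation sets
(500 resamples by default) and recomputing all three quantities per resample.
The warming comparison contrasts era means of body, air and substrate
temperature with routed location tests (Mann–Whitney U with exact
tie-corrected p-values, or one-way ANOVA), tests the temperature-type × era
interaction and the homogeneity of the body-on-environment regression slopes
across eras, and expresses the buffering of body temperature as the ratio of
its rise to the environmental rise. Safety margins are distances of era mean
body temperatures below the optimal sprint temperature of 34.53 °C.

## Worked example

```r
library(thermoreg)

## Simulate the study: gradient selections, two capture eras, logger series
sel  <- generate_selected_temperatures(seed = 1)
era1 <- generate_field_records(era1_config(), seed = 2)
era2 <- generate_field_records(era2_config(), seed = 3)
ops  <- generate_operative_series(microhabitat_config(), seed = 4)

## Preferred range and thermoregulation indices for the present-day era
ptr <- compute_ptr(sel)
print(ptr)
#> Preferred temperature range: [31.28, 32.44] degC (breadth 1.16, central 50%)

db <- compute_deviation_set(era2$t_b, ptr, "body")
de <- thermal_quality(ops, ptr)
bootstrap_thermoreg(db, de, seed = 11)
#> Bootstrap thermoregulation indices (500 resamples, seed 11)
#>   accuracy        mean d_b = 1.449 +/- 0.232 degC (n = 40)
#>   thermal quality mean d_e = 9.168 +/- 0.061 degC (n = 9720)
#>   effectiveness   E        = 0.842 +/- 0.025

## The 25-year warming contrast
compare_eras(era1, era2)
#> Era comparison: 1983-1989 vs 2012
#>   t_b  27.65 +/- 0.39 (87)  ->  30.16 +/- 0.30 (40)   delta +2.51   [Mann-Whitney U, p = 7.57e-05]
#>   t_a  20.76 +/- 0.38 (84)  ->  24.88 +/- 0.38 (40)   delta +4.12   [one-way ANOVA, p = 6.08e-10]
#>   t_s  22.58 +/- 0.57 (83)  ->  30.38 +/- 0.59 (40)   delta +7.80   [Mann-Whitney U, p = 1.18e-12]
#>   type x era interaction: F = 13.929, p = 1.48e-06
#>   t_b ~ t_a slope homogeneity: F = 0.370, p = 0.544
#>   t_b ~ t_s slope homogeneity: F = 0.750, p = 0.388
#>   buffering ratio delta(t_b)/delta(t_a) = 0.61, delta(t_b)/delta(t_s) = 0.32

## Safety margins below the optimal performance temperature
opt <- optimal_temperature(34.53, se = 0.50, source = "locomotor performance")
safety_margin(mean(era1$t_b), opt)   # 6.88 degC
safety_margin(mean(era2$t_b), opt)   # 4.37 degC
```

Substrate warmed almost twice as much as air, body temperature rose by well
under the environmental rise (buffering ratios 0.61 and 0.32), the lizards
thermoregulate effectively (E ≈ 0.84) in a thermally poor habitat
(mean d_e ≈ 9.2 °C), and the safety margin shrank by ~2.5 °C between eras —
the qualitative fingerprint of behavioural buffering with an eroding thermal
cushion.

## The analysis workflow

The full study pipeline lives in `analysis/` as numbered drivers over the
package API; each reads its predecessors' outputs from `results/` and writes
plain CSV:

| script | does |
|---|---|
| `analysis/01_simulate.R` | generate selections, both capture eras and logger series to `results/data/` (`THERMOREG_SEED` env var, default 1) |
| `analysis/02_ptr.R` | preferred temperature range from the gradient selections |
| `analysis/03_indices.R` | bootstrap d_b / d_e / E for the present-day era |
| `analysis/04_microhabitat.R` | per-microhabitat hourly profile, hourly suitability, Kruskal–Wallis + Nemenyi ranking |
| `analysis/05_compare_eras.R` | sex-pooling check, era deltas, interaction and slope-homogeneity tests |
| `analysis/06_margins.R` | safety margins and the illustrative performance curve |

Run them in order with `Rscript analysis/01_simulate.R` etc., or all at once
with `for f in analysis/0*.R; do Rscript "$f"; done`. The same pipeline is
available programmatically for measured (non-synthetic) CSV inputs via
`run_config()` / `run_pipeline()` / `write_report_bundle()`.

## Documentation

The methods vignette (`vignettes/thermoreg-methods.Rmd`, source form)
documents the model and its assumptions, every generator default and the
arithmetic that fixed it, the conventions chosen where the protocol is
ambiguous (quantile interpolation, suitability criterion, activity-window
restriction), and the limits of what the synthetic data can establish.
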