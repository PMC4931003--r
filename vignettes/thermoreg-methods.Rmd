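---
title: "Quantifying behavioural thermoregulation: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying behavioural thermoregulation: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoreg)
```

## The null-model protocol

An active ectotherm's body temperature alone says little about
thermoregulation: a lizard sitting in a warm habitat can match its
physiological set-points without regulating at all. The Hertz protocol
therefore contrasts field body temperatures against *operative temperatures*
(T~e~): the equilibrium temperatures of physical null models (hollow copper
cylinders fitted with loggers) scattered across the microhabitats an
individual could occupy. Three quantities summarise the contrast, all
measured relative to the *preferred temperature range* (PTR) established in a
cost-free laboratory thermal gradient:

* **d~b~ (accuracy of thermoregulation)** — deviation of each field body
  temperature from the PTR: zero inside the range, distance to the nearer
  bound outside. Lower mean d~b~ means body temperatures sit closer to the
  set-points.
* **d~e~ (thermal quality of habitat)** — the same deviation applied to every
  operative reading. Higher mean d~e~ means the habitat, as experienced by a
  non-regulating animal, is thermally worse.
* **E = 1 − mean d~b~ / mean d~e~ (effectiveness)** — 1 for a perfect
  thermoregulator, 0 for a thermoconformer, negative for an animal that
  avoids thermally favourable sites.

The deviation operator is the canonical distance-to-nearer-bound form
(`deviation_from_range()`); the protocol literature names d~b~ and d~e~
without restating the formula, and no alternative operationalisation is in
use, so the package adopts it explicitly rather than exposing a choice.

Uncertainty comes from a bootstrap (`bootstrap_thermoreg()`, default 500
resamples): body and operative deviation sets are resampled *independently*
(they are unpaired by design — tens of captures against thousands of logger
readings), each resample yields mean d~b~\*, mean d~e~\* and
E\* = 1 − mean d~b~\*/mean d~e~\*, and the pseudo-distribution standard
deviation is reported as the standard error. E is computed per resample from
that resample's means — it is a ratio of means, defined only at the sample
level — rather than by resampling per-observation "E values", which do not
exist. Resamples with mean d~e~\* = 0 leave E\* undefined; they are excluded
and counted, not silently zeroed. All resampling requires an explicit seed;
there is no hidden global randomness, and identical seeds give bit-identical
summaries.

## Estimating the preferred range

`compute_ptr()` takes the central 50% of pooled gradient selections (the
interquartile interval). Two conventions were genuinely open:

* **Quantile interpolation.** The quartiles use linear interpolation between
  order statistics (type 7), the default of most scientific software; the
  convention is exposed as an argument. At n = 156 the difference between
  common conventions moves the bounds by under ~0.1 °C, which is why the
  published bounds (31.18–32.50 °C) can be emulated but not re-derived
  exactly from a generator.
* **Pooling.** Selections are pooled across individuals and hours, matching
  the design that yields 156 selections from 24 lizards; per-lizard averaging
  would change the effective sample size and is deliberately out of scope.

## The statistics layer

Classical machinery (one-way ANOVA, OLS regression, ANCOVA slope
homogeneity, Kruskal–Wallis with tie correction) delegates to base R model
fits behind a uniform `thermo_test` surface. Two pieces are implemented in
full because no installed package provides their required conventions:

* **Mann–Whitney U** reports min(U₁, U₂) — the convention of the published
  U values — uses midranks for ties, and computes the p-value by exact
  enumeration of the permutation distribution of the rank sum when
  min(n₁, n₂) ≤ 20 (a subset-sum dynamic program over doubled midranks,
  summing both tails around the null mean), switching to the tie-corrected
  normal approximation with continuity correction for larger samples. The
  exact branch reproduces `wilcox.test`'s exact p-values in the tie-free
  case and agrees with the normal branch to within 0.02 at n = 15 + 15.
* **Nemenyi post hoc** after Kruskal–Wallis offers the studentized-range
  variant (classical, equal group sizes) and the tie-corrected chi-square
  variant, with the chi-square form chosen automatically for unequal sizes —
  the situation of the field design. Which variant the original analysis
  software applied is not documented; the chi-square default is the
  conservative choice for unequal n.

The interaction tests (temperature-type × era, and the ANCOVA slope test)
are model-comparison F-tests — full versus reduced model — which handle the
unbalanced era sizes (87 vs 40) without ambiguity about sums-of-squares
types for the interaction term. Numerically saturated fits (residual SS at
machine zero, e.g. noise-free constructed data) are reported as F = 0, p = 1
when the comparison SS is also null, and as unbounded evidence otherwise,
instead of returning rounding noise. All p-values are two-sided. Which
location test compares the eras for each variable is a configuration map
(`default_test_routing()`: rank-based for body and substrate temperature,
ANOVA for air), not an automated normality decision — automated routing
would make the analysis non-deterministic under resimulation.

## Microhabitat profiling

`summarize_operative()` bins logger readings by microhabitat and GMT hour
(timestamp truncation) within the activity window, 09:00–18:00 GMT by
default. `thermal_quality()` pools all window readings unweighted across
microhabitats — the design reports a single mean d~e~ over all readings, not
an availability-weighted version, and availability maps are out of scope.
Whether d~e~ should use all 24 h of logger data or only the activity window
is not documented in the protocol's applications; the package restricts to
the activity window by default (deviations while lizards are inactive do not
describe the habitat they actually face) and exposes the window as an
argument. Hourly suitability (`hourly_suitability()`) defaults to "at least
one reading inside the PTR during that hour", with "hourly mean inside the
PTR" as the stricter alternative; the qualitative claim it operationalises
("a suitable place existed") is itself ambiguous, so both are available and
the choice is recorded in the run configuration.

## The synthetic-data generators and their calibration

Field data for this system are not deposited, so the package ships
generators that reproduce the *statistical structure* the analysis assumes.
Their defaults are fixed once, from the published summary statistics, and
are study conditions, not tuning knobs:

* **Gradient selections** (`generate_selected_temperatures()`): truncated
  normal on the 20–60 °C gradient span, centre 31.84 °C (the midpoint of the
  published range) and sd 1.0 °C, chosen because a normal interquartile
  breadth of 1.349 × sd then matches the published breadth of 1.32 °C;
  n = 156 assigned round-robin to 24 lizards (12 of each sex) and hours.
* **Field records** (`generate_field_records()`): capture times uniform over
  09:00–18:00 GMT; air temperature is a diel sinusoid (peak 13:30 GMT,
  amplitude 4 °C) plus noise, with the peak value and noise sd set so the
  era mean and sd equal the published mean and SE·√n (era 1: 21.13 ± 3.67;
  era 2: 24.90 ± 2.53); substrate is air plus the published mean offset plus
  noise matched to the published substrate sd; body temperature follows the
  era regression on air with residual variance
  slope² · var(T~a~) · (1 − R²)/R², which targets the published R² directly
  — the published quantity — rather than a free residual-sd knob. A
  consistency check falls out of this: the implied body-temperature sds
  (3.67 and 2.1 °C) reproduce the published body-temperature SEs without
  further adjustment. Era 1 marks 3 and 4 records as missing air/substrate
  readings, mimicking the unequal published per-variable n (87/84/83).
  The published regression intercepts and era means are mutually
  inconsistent by ~0.1–0.15 °C (the regressions were presumably fitted on
  the complete-pairs subset); the generator keeps the published slopes and
  R² and reconciles the intercepts (16.25, 19.88) so the era mean body
  temperatures hit the published means, which keeps the era *deltas* —
  the quantities the warming comparison tests — exact in expectation.
  Relatedly, the study's abstract describes the body-temperature rise as
  "less than 2 °C" while its own era means differ by 2.47 °C; the package
  reports the means-based delta.
* **Operative series** (`generate_operative_series()`): one model per
  microhabitat logging every 5 min for 10 days around the clock, each
  following a per-microhabitat sinusoid plus noise
  (`default_microhabitat_params()`). Amplitudes, baselines and peak hours
  were set once so that (i) the activity-window pooled mean falls near the
  published 21.60 °C, (ii) flat rock, moss and south-facing rock approach
  the PTR near midday and are statistically similar, (iii) east/west faces
  peak in morning/evening — which is what keeps a suitable site available at
  every activity hour — and (iv) soil, north faces and under-rock sites stay
  cold and buffered. A 10-day × 5-min × 9-model design yields 25 920 readings
  (9 720 in the activity window); the published count of ~8 114 usable
  readings is not reproducible from any simple window arithmetic, so the
  generator exposes the cadence parameters and accepts the mismatch.

What the generators deliberately do **not** emulate: day-to-day weather,
temporal autocorrelation within logger series, cloud events, behavioural
non-independence of captures, and the physics of copper-model heat exchange.
Passing tests therefore show that the *analysis machinery* recovers the
parameters of a correctly specified generating model at the study's sample
sizes — not that the field inferences themselves are robust to
misspecification.

## Fitness margins

`safety_margin()` is the arithmetic distance of a mean body temperature
below the optimal performance temperature (34.53 ± 0.50 °C from locomotor
performance work on a congeneric population). The accompanying
`skewed_performance_curve()` is explicitly illustrative: performance curves
for this species have no published functional form, so the package provides
a piecewise power shape — zero at the critical limits, 1 at the optimum,
convex rise and concave fall — whose only asserted properties are the ones
that matter for interpreting margins (left skew; steeper decline than rise
at equal distances from the optimum, the Jensen-inequality argument for why
overshooting costs more than undershooting). Its critical-limit defaults
(5 and 42 °C) are placeholders spanning a typical small-lacertid tolerance
range, not species estimates, and the curve feeds plots only — never an
acceptance quantity.

## Numerical and testing choices

Problem sizes in the test suite are the study's own: 156 selections, eras of
87 and 40 captures, nine logger series. Null-calibration checks use 2000
replicates per test (size within [0.03, 0.07] at α = 0.05), parameter
recovery uses 200 seeds, and the bootstrap convergence check uses 10 000
resamples against the plug-in estimate at the study's 40/8114 sample sizes.
Recovery of the era-1 regression is asserted on the mean refit across seeds:
a single refit's sampling error at n = 87 and R² = 0.3 (slope SE ≈ 0.09) is
part of the generating model, not an implementation defect. Temperatures are
validated against a plausibility window of [−10, 70] °C at I/O boundaries;
malformed rows are rejected and logged with line numbers rather than
poisoning downstream statistics.
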