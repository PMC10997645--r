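---
title: "Methods: from stomatal ozone dose to crop production loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from stomatal ozone dose to crop production loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ozoneyield)
library(dplyr)
```

## The problem

Ground-level ozone enters crop leaves through stomata and damages yields of
sensitive species; common bean (*Phaseolus vulgaris*) is among the most
ozone-sensitive staples. Where surface monitoring is sparse — as across most
of sub-Saharan Africa — the practical route to a national risk estimate is to
combine modelled stomatal ozone flux with gridded crop production and an
experimentally derived flux–effect relationship, and to report losses at the
administrative level where agricultural statistics live. `ozoneyield`
implements that pipeline end to end for a bimodal (two growing seasons per
year) cropping system with one unimodal exception region, following the
approach used for Ugandan beans:

1. accumulate daily phytotoxic ozone dose over 90-day seasonal windows,
2. convert dose to percentage yield loss through a linear flux–effect slope,
3. convert yield loss plus observed production into production loss,
4. aggregate to sub-regions and nationally, and
5. co-locate ozone risk with five other crop stresses in a composite score.

Every input has a seeded synthetic emulator, so the full pipeline is testable
without any external download.

## Dose: POD accumulation

The exposure metric is POD₃IAM — phytotoxic ozone dose above a stomatal flux
threshold of 3 nmol m⁻² s⁻¹, with the simplified vegetation-class
parameterisation used for integrated assessment. The primary input is a cube
of *daily dose increments* (mmol m⁻² d⁻¹) as emitted by chemical-transport
models with an embedded stomatal-exchange scheme; `hourly_to_daily_pod()`
additionally offers the hour-level threshold integration
(`Σ max(flux − 3, 0) × 3600 × 10⁻⁶`) for callers who start from hourly flux.
We deliberately do not model stomatal conductance itself (light, temperature,
VPD multipliers): pretending to re-derive a deposition scheme the package
does not contain would only obscure provenance.

`accumulate_pod()` sums increments over an inclusive Julian-day window.
The shipped presets are the three 90-day windows of the bean assessment —
season 1 days 91–180 (April–June), season 2 days 257–346 (mid-September to
mid-December), and the unimodal window days 182–271 (July–September) —
each spanning roughly anthesis to the end of grain fill before the season's
harvest. Julian days are used as-is in leap years; fixed start/end days keep
windows 90 days long by construction.

Missing days inside a window are handled by a configurable policy whose
default is *loud*: `error`. `skip` drops missing days; `scale` rescales the
partial sum by `90 / valid days`, which is unbiased only when missingness is
unstructured in time. The default is an error because silently shortened
accumulation windows are the classic way exposure metrics go quietly wrong.

## Dose–response: the flux–effect fit

The flux–effect relationship is a linear regression of relative yield
(percent of reference yield) on accumulated dose. Experimental spread grows
with dose, so `fit_flux_effect()` models the residual standard deviation as
σ·podᵟ and profiles δ over the fixed grid {0, 0.25, …, 2} by Gaussian
likelihood; conditional on δ the fit is weighted least squares with weights
pod⁻²ᵟ. Zero-dose points take the weight of the smallest positive dose —
a power law has no variance at zero, and the reference treatment must not be
dropped. The grid profile (rather than a continuous optimiser) keeps the fit
deterministic, derivative-free and trivially reproducible; the selected δ is
reported as `variance_exponent`.

Confidence intervals and the slope p-value use heteroscedasticity-consistent
(HC3) standard errors of the selected weighted fit with t(n − 2) quantiles.
The variance power law is a working model; real experimental spread is
rarely an exact power of dose, and the sandwich form keeps interval coverage
near nominal under such mild misspecification, which the acceptance suite
verifies by simulation (500 replicates, n = 40, affine noise law: slope bias
below 2%, CI coverage within 0.95 ± 0.03).

Applied risk uses the *slope only*, anchored at a reference dose:
`%YL = slope × max(POD − POD_ref, 0)`, clamped to [0, 99.9]. Zero exposure
is thereby tied to zero effect; the fitted intercept (whose 95% interval
contains 100 for the bean data) is not propagated. The shipped default model
is slope 1.175% per mmol m⁻², reference dose 0 — the published bean
parameterisation. The underlying experimental points are not redistributed
with the package, so the default is constructed, not refit; refitting is
exercised on synthetic data only. The reference dose is 0 because a constant
10 ppb ozone atmosphere over the 90-day experiment keeps stomatal flux below
the 3 nmol m⁻² s⁻¹ threshold; `reference_pod_for_experiment()` records the
provenance of any override.

The clamp at 99.9% rather than 100% keeps the production-loss division
defined everywhere; observed losses top out near 27.5%, so the clamp is a
numerical guard, not a modelling statement.

## Production loss

With observed production P (tonnes) and yield loss `yl` (%), relative yield
is `RY = 1 − yl/100` and

```
production loss = P / RY − P = P · yl / (100 − yl).
```

Observed production is what *survived* the loss, so the loss is measured
against the inflated pre-loss potential — at 20% yield loss, 100 t observed
implies 25 t lost, not 20. A literal reciprocal reading of relative yield
(`RY = 1/(yl/100)`) circulates in print; it produces negative, dimensionally
inconsistent losses and is provided only behind
`production_loss(literal = TRUE)` so the discrepancy can be audited. The
`1 − yl/100` reading is the only one consistent with positive, finite losses
of the reported magnitude (≈17% national loss on ≈1 Mt ⇒ ≈0.2 Mt).

```{r eq2}
production_loss(100, 20)
uganda_bean_losses() |> aggregate_losses() |> filter(sub_region == "National")
```

## The exposed stock: conversion factors and seasonal splits

Production rasters usually represent a base year different from the
assessment year. `derive_conversion_factors()` moves them using two
agricultural-survey snapshots: regional totals are interpolated linearly in
time between the survey anchors and the factor is
`interp(target year) / interp(base year)` per region. Linear interpolation
is the minimal reading of "how regional production changed between the
surveys" when only two anchors exist; the functional form is recorded with
the output, and a region with unchanged totals gets a factor of exactly 1.
Factors apply at the parent-region level through a sub-region → region
lookup.

Annual production is split between the two growing seasons per sub-region.
The national default is 60:40 (season 1:season 2); three sub-regions of the
bean assessment deviate enough for printed overrides (West Nile 30:70, Lango
69:31, North Buganda 61:39), and the unimodal sub-region carries shares
(1, 0) with all of its production assessed against its own window.
`split_seasons()` conserves tonnes cell by cell and refuses to split an
already-seasonal raster.

## Spatial plumbing

All geometry is planar in degrees. The domains sit on the equator, where a
degree box is a rectangle to well under a part in a thousand, and planar
shoelace/clipping arithmetic keeps every overlap area exactly reproducible
by brute force — which the tests exploit. Cell footprints are half-open in
both axes with 0-based indices, so a point falls in exactly one cell.

Cells are assigned to sub-regions by majority overlap area
(`assign_cells()`), the same rule the flood-district layer uses; ties go to
the first-listed polygon, making assignment deterministic. Regridding
(`regrid()`) offers area-weighted means for intensive fields, a
sum-conserving transfer for extensive fields (tonnes are conserved to 1e-9
relative), majority for categorical fields, and nearest-cell sampling.
The coarse (0.3°) dose field is sampled onto the fine (0.0833°) production
grid by `nearest` by default — each fine cell inherits the coarse cell
containing its centre, which is how a coarse exposure field is
conventionally read — with `area_weighted_mean` available where smoother
fields are wanted; the choice is a config key because no convention is
universal. Any statistic over zero contributing cells is missing, never
zero.

## Aggregation rules

Sub-region mean yield loss is the unweighted mean over cells *with
production data, including zero-production cells*: the yield-loss map is a
statement about potential risk wherever beans could be grown, not a
production-weighted average. Production losses are summed over cells with
production > 0. National rows aggregate at the *cell* level — the mean over
all contributing cells and the sum of all losses — not as a mean of
sub-region means; with unequal sub-region sizes the two differ, and the
cell-level form is the one consistent with the published national averages.
Whether the unimodal sub-region belongs in the season-1 national mean is
not decidable from the published tables; the package includes its (single
window) cells there, and its loss appears once in annual totals, in the
season-1 position. A `production`-weighted mean is exposed as an option in
spirit via `zonal_stat(..., mask =)`, but the reported tables use unweighted
means.

## Composite crop-stress score

Six layers — soil-nutrient constraint class, 6-month SPEI, flood occurrence,
mean daily maximum temperature, deprivation index, and season-1 ozone yield
loss — are each scored 1 (very low risk) to 5 (very high risk) and summed,
giving a composite in [6, 30]. The exact published breakpoints are not
reproduced in the source's main text, so the defaults are package choices,
fully overrideable, anchored where the text anchors them:

| layer | scored | default classes |
|---|---|---|
| soil | categorical ladder | "No constraints" → 1 … "Very severe" → 5 |
| SPEI (lower worse) | breakpoints −1.5, −1, −0.5, 0 | standard dryness categories |
| flood occurrences | 1, 2, 4, 6 | 0 / 1 / 2–3 / 4–5 / ≥6 |
| temperature (°C) | 28, 29.5, 32, 35 | bean growth optimum ≤28; ≥35 aborts pods |
| deprivation (0–100) | 20, 40, 60, 80 | quintiles |
| ozone %YL | 5, 10, 16, 22 | narrative bands of the assessment |

Continuous binning is half-open (a value equal to a breakpoint falls in the
class above it). A cell missing in any layer is missing in the composite,
with per-layer missing counts attached. Stress interactions are explicitly
out of scope: the score co-locates stresses, it does not model their joint
effect.

## The synthetic-data module

`synthetic_scenario()` fixes the study conditions the generators emulate:
a ~4° × 5° equatorial domain; a 0.3° exposure grid over a 0.0833°
production grid (the published resolutions); 14 rectangular sub-regions in
4 parent regions with one unimodal sub-region; a daily dose field
`max(0, baseline + gradient · NW-proximity + seasonal sinusoid + noise)`
with defaults (baseline 0.15, gradient 0.08, amplitude 0.04, noise sd
0.02 mmol m⁻² d⁻¹) chosen so 90-day doses span roughly 10–21 mmol m⁻² and
yield losses land in the published 8–27% range, higher in the north-west;
patchy production as Bernoulli(0.6) × log-normal with mean 350 t per
occupied cell (national totals near 1 Mt); and survey snapshots that are
stated multiples of the generated base-year regional totals, so the
conversion-factor derivation has an exact truth. All randomness flows from
one seed through named substreams, one per generator, so adding a generator
never perturbs another's draws.

What the emulation does *not* reproduce: real geography and the chemistry
and meteorology behind real dose fields, spatial autocorrelation of
production beyond region blocks, and survey measurement error. Passing
tests therefore demonstrate that the *machinery* is correct under known
truth, not that the published national numbers are independently
reproduced — the published dose and production rasters are not deposited,
which is also why the headline sub-regional averages are checked as
arithmetic on the published loss table rather than recomputed from raw
inputs.

Two degenerate switches give closed-form oracles: `per_region_constant`
dose (every cell of a sub-region accumulates exactly its prescribed dose
over any 90-day window) and `constant` production. `scenario_truth()`
states the full loss table for such scenarios, and the end-to-end test
requires agreement to 1e-9 relative.

## Numerical choices and degenerate inputs

* Half-open cells and half-open score bins: boundary values have exactly one
  home.
* Assignment ties broken by polygon order; regrid target cells with no
  non-missing source are missing.
* Zero-area polygons, empty polygon sets, disjoint grids, constant-dose
  fits, shares not summing to 1 (tolerance 1e-9), negative doses and
  out-of-range yield losses all fail fast with named errors.
* Problem sizes in the tests: grids up to 8 × 8 for brute-force geometry
  oracles, the full 48 × 60 / 14 × 17 scenario for end-to-end runs, 500
  replicates × n = 40 for the fit-recovery study, 100 random fixtures for
  the conservation suite — sizes at which every oracle is exact or its
  Monte-Carlo error is well below the asserted tolerance.
* The pipeline driver (`run_all()`) writes a manifest with md5 checksums
  and a `resolved.yaml` carrying every effective default, from which a run
  is reproducible.

## Known limitations

* The stomatal-conductance chain (concentration → flux) is out of scope;
  the package starts at flux or dose.
* Planar-degree geometry is inappropriate far from the equator without a
  latitude correction.
* The seasonal split and conversion factors are regional scalars; no
  within-region heterogeneity.
* The composite stress score is ordinal and additive by construction;
  equal weights are a convention, not an inference.
* Irrigated dose pathways are handled by running the pipeline a second time
  with an irrigated cube, not by a dedicated code path.
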