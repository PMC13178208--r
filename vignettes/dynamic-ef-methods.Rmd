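---
title: "Dynamic emission factors for agricultural N2O: model, synthetic world, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic emission factors for agricultural N2O}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n2odyn)
```

## The problem

Inventory practice converts fertilizer nitrogen applied to agricultural
soils into nitrous oxide emissions with a fixed emission factor (EF): the
IPCC Tier-1 value assumes 1% of applied N is lost as N2O-N, everywhere and
forever.  Field and process-model evidence says the true EF is none of
those things: it rises with N application rate and with temperature, and
varies with moisture regime and soil properties.  A projection built on a
static EF therefore understates future emissions whenever fertilizer use
grows or the climate warms — and understates how much mitigation is needed.

`n2odyn` implements the dynamic alternative as a complete, testable
pipeline.  Its central objects are:

* a **true EF response surface** — a closed-form function
  `EF(N, T, AI, SOC, pH)` that stands in for a multi-model process-model
  ensemble and defines the synthetic world's ground truth;
* an **EF emulator** — a statistical surrogate trained on noisy samples of
  that surface, playing the role the machine-learning component plays when
  the training data come from process models;
* **scenario machinery** — seven policy-by-climate combinations (INMS1-7)
  that steer country-level fertilizer totals through nitrogen-use-efficiency
  (NUE) trajectories while preserving the baseline spatial pattern;
* **projection and mitigation analysis** — per-member emission series,
  ensemble percentile bands, reduction-goal timelines, hotspot ranking, and
  nitrification-inhibitor (NI) adoption along the hotspot gradient.

Emissions are always `E = (EF/100) × N rate × fertilized area`, summed over
cells; the static branch fixes EF = 1 exactly.  Only direct emissions
attributable to mineral fertilizer are modelled: unfertilized cells emit
zero, and background, manure-driven, and indirect pathways are out of scope.

## The true EF surface

The surface is a product of positive factors:

* logistic, **increasing** in N rate (midpoint 120 kg N/ha, width 60,
  running from 0.6 to 1.4 of the base level) — EF grows as N saturates the
  crop's capacity to take it up;
* exponential, **increasing** in temperature, `exp(0.04 (T - 12 °C))` —
  roughly +4% EF per degree of warming;
* unimodal in aridity index (Gaussian bump at AI = 0.8, floor 0.4) — both
  very dry and very wet regimes emit relatively less per unit N;
* mild SOC (tanh, ±10%) and pH (quadratic, -5% at ±2 pH units from 6.5)
  modifiers.

Monotonicity in N rate and temperature therefore holds *by construction*,
at every point — the package tests verify it by finite differences rather
than assume it.  The overall scale is calibrated so the fertilized-area-
weighted mean EF of the 2010 synthetic world falls in 1.18–1.22%: above the
Tier-1 1%, which is what makes the dynamic-vs-static gap positive from the
start and growing under warming.  Because the mean is linear in the scale,
calibration converges in one step; a bounded iteration guards degenerate
inputs.  Setting `constant =` in `ef_surface_params()` replaces the whole
surface with a fixed EF — the handle used by the static-limit equivalence
test.

## What the synthetic world emulates — and what it does not

`synthetic_world()` builds 2000 cells in 18 one-region countries by
default; most tests use a few hundred cells, which preserves every
statistical property at lower cost.  The stated-world choices that the
sources do not pin down were made once, as field-plausible values, and not
revisited:

| quantity | default | why |
|---|---|---|
| mean fertilizer rate | 80 kg N/ha/yr | mid-range of global cropland application rates |
| rate distribution | log-normal, log-sd 1 | right-skew strong enough that the top decile of cells carries ≈40% of N, the hotspot premise |
| member temperature bias sd | 0.6 °C | typical inter-GCM spread at grid scale |
| monthly noise sds | 0.5 °C, 0.25 log-pr | weather variability around the climatology |
| warming trends | 0.10 / 0.25 / 0.45 °C per decade | orders SSP1-2.6 < SSP2-4.5 < SSP5-8.5 |
| label noise | 0.3 EF points | matches the emulator-skill criterion's noise floor |
| 2010 NUE by region | 0.35 (China) – 0.65 (USA/Canada) | low where over-fertilization is documented |
| demand growth | 0.3%/yr OECD – 2%/yr Africa | population-driven demand gradients |

The generator reproduces the *structure* the analysis relies on — skewed
fertilizer with hotspots, spatially autocorrelated soils, biased ensemble
members around an observed climatology, pathway-ordered warming, a monotone
EF response — but not the magnitudes of the real world: global totals are a
toy-scale fraction of a Tg.  A green test therefore establishes that the
*method* behaves as claimed (conservation, ordering, convergence,
equivalences), never that the real-world numbers would be reproduced.
Crop-type and management differentiation, real data ingestion (CRU, CMIP6,
HWSD, HYDE), and manure/indirect pathways are deliberately absent.

## The emulator

The regressor is an `mgcv` generalized additive model with a Gaussian
log link, one smooth per feature (N rate, annual mean temperature, annual
precipitation, aridity index, SOC, pH, bulk density, sand, clay).  A tree
ensemble would serve too, but the GAM has three properties that decided it:
the truth surface is a product of positive smooth factors, which is exactly
additive on the log-link scale; fitting is deterministic without any seed
management; and the log link keeps fitted EF positive without clipping the
fit itself.  Predictions are still clipped to `[0, ef_max]`
(default 25%) as a guard against extrapolation.  Year and cell identity are
excluded from the features so the emulator generalizes over climate rather
than memorizing cells.

Training holds out a seeded 20% split and refuses to return a model whose
held-out RMSE exceeds a configured ceiling (default 1 EF point).  On the
default world with 0.3-point label noise the held-out RMSE lands at the
noise floor (≈0.30), and validation against the *noiseless* truth surface
along binned aridity and SOC gradients gives RMSE well under the 0.3-point
reporting threshold.  A constant-label table (the static-limit world) is
fitted with an intercept-only model, since a full smooth basis is singular
there.

## Numerical choices

* **Delta bias correction** is `projected − (mean(model) − mean(obs))` per
  cell and calendar month over a reference period (default 1995–2014);
  precipitation is floored at zero.  The printed form of the underlying
  equation is ambiguous about grouping; this is the standard delta method
  and the only reading anchored to observations.
* **Aridity index** is annual P/PET with Thornthwaite PET at a fixed
  12-hour day length; PET = 0 (all months frozen) maps to a configurable
  cap (default 10) and zero precipitation maps to AI = 0.
* **Percentiles** use the linear-interpolation convention (R type 7).
* **Goal years** are first crossings, not sustained attainment.  The
  cumulative basis compares the running emission sum since the baseline
  year with holding the reduced 2010 level every year.
* **NUE trajectories** are linear to the target (reached 2030 under high
  ambition for OECD, 2035 non-OECD; 2050 under moderate), flat under BAU,
  and close half the gap by 2050 under low ambition.  The best-case,
  best-case-plus and bioenergy variants add demand-reduction ramps of
  −10/−20/−15% by 2050 on top of the high-ambition NUE path — their
  dietary and food-waste mechanisms enter only as a fertilizer-demand
  delta.
* **Hotspot fractions** are fractions of fertilized (agricultural) *area*,
  with the boundary cell counted pro-rata; ranking ties break by ascending
  cell id.  The minimal adoption fraction inverts the piecewise-linear
  prefix-emission curve exactly rather than bisecting it — same answer,
  no iteration — and the descending-rate prefix is optimal among
  equal-area subsets because all cells share one proportional reduction
  efficiency (a continuous-knapsack argument, verified against exhaustive
  subset search in the tests).
* **CO2-equivalent conversion** uses GWP100 = 265 on N2O mass by default
  (with the ratio 44/28 from N2O-N to N2O).  The constant is an argument
  because published values differ; the package's default is the one
  consistent with standard AR5 numbers.

## Known limitations

Uncertainty bands reflect climate-member spread only; fertilizer-pathway
and surface-parameter uncertainty are not sampled.  The NI analysis is the
idealized one: a uniform 34% efficiency applied instantly on adopted area,
with no adoption barriers, costs, or site-specific effectiveness.  Gridded
outputs are CSV rather than NetCDF — the tables carry the same
cell/time/member coordinates, and a NetCDF writer would add a dependency
the analysis itself never needs.

## A minimal run

```{r, eval = FALSE}
w    <- synthetic_world(n_cells = 400, hist_years = 2003:2014, seed = 3)
tt   <- emit_training_table(w$surface, w$climate_obs, w$soil,
                            w$fertilizer, w$domain, seed = 2)
em   <- train_emulator(tt, seed = 5)
clim <- generate_climate(w$domain, 2010:2050, "SSP5-8.5", n_members = 5,
                         hist_end = 2009, seed = 7)
fert <- build_scenario_fertilizer("INMS1", w$fertilizer, w$domain,
                                  years = 2010:2050)
pr   <- project_scenario("INMS1", em, clim, fert, w$domain, w$soil)
ensemble_summary(pr)
static_dynamic_gap(ensemble_summary(pr), pr$static_tg)
```

Every empirical statement above (noise-floor RMSE, gradient skill, gap
sign, ordering) is computed by the test suite or the acceptance script,
not asserted here.
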