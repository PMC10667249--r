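---
title: "Chamber-to-budget methods in fenflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chamber-to-budget methods in fenflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fenflux)
```

# The measurement model

A closed chamber sealed on a permanent collar accumulates (or depletes) gas;
the flux is the ordinary least-squares slope of concentration against time
converted by the ideal-gas law,

$$F = s \cdot 10^{-6}\,\frac{P}{R\,T}\,h\,M \cdot 86400,$$

in g gas m⁻² d⁻¹, uptake negative. The effective height $h$ is the chamber
height plus the collar rim headspace minus the water depth inside the collar
— standing water inside the collar displaces headspace, so submerged collars
have a smaller $h$ (the package errors if $h \le 0$). Pressure is rarely
logged for chamber work, so $P$ defaults to 101.325 kPa and is a
configuration entry (`default_config(pressure_kPa = ...)`). Molar masses are
the integers 44 and 16 so that the downstream carbon conversions are the
familiar ratios 12/44 and 12/16; the deviation from the exact masses
(44.01, 16.04) is below 0.3% and far inside every tolerance used here.

## Quality control

Four thresholds, all configuration entries:

* CO2 runs whose concentration range is **< 2 ppm** are zero flux (a stable
  headspace within instrument noise). A range of exactly 2 ppm is *not*
  zero.
* remaining CO2 runs with slope **r² ≤ 0.75** are rejected as non-linear
  (exactly 0.75 is rejected);
* CH4 runs whose range is **≤ 0.5 ppm** — within the precision of vial
  sampling and gas chromatography — are zero (exactly 0.5 *is* zero);
* remaining CH4 runs with **r² < 0.60** are rejected as
  ebullition-contaminated (exactly 0.60 is accepted).

The zero rule is applied before the r² rule for both gases: a flat series
has a meaningless r², and classifying it as zero is the physically correct
reading. For a mathematically constant series, r² is defined as 0; the range
rule classifies such runs as zero anyway. Zero-classified fluxes enter all
downstream steps as true zeros; rejected fluxes are excluded from every fit
and budget (the test-suite asserts this by fault injection).

# Flux partitioning and the empirical models

Within a campaign, the darkened run (PAR = 0) measures ecosystem respiration
(ER ≥ 0); each lit run measures net ecosystem exchange, and gross ecosystem
productivity is GEP = NEE − ER (≤ 0). A campaign without a usable dark run
is flagged: its lit runs still yield NEE but no GEP.

## Light response

GEP follows the rectangular hyperbola
$\mathrm{GEP} = \mathrm{PAR}\,Q\,GP_{max} / (\mathrm{PAR}\,Q + GP_{max})$,
with the quantum efficiency $Q$ (initial slope, g CO2 m⁻² d⁻¹ per
µmol m⁻² s⁻¹) and the asymptote $GP_{max}$ both negative. Fitting is
Levenberg–Marquardt least squares with deterministic, data-driven start
values: $Q_0$ is the OLS slope of GEP against PAR over the lowest PAR
tertile (fallback −0.01 if non-negative or undefined) and
$GP_{max,0} = 1.2\times$ the most negative observed GEP (fallback −1). Fits
returning parameters of mixed sign are treated as failures, because the
hyperbola then has a pole at positive PAR.

Seasonal drift in the parameters is handled by candidate partitions of the
season into early (May–June), mid (July) and late (August–September) parts:
the three parts separately, the two two-part merges, or the pooled whole
season. Each candidate is scored by AICc computed from the pooled Gaussian
residuals with $k = 2\,(\text{parts}) + 1$ parameters, and a candidate is
feasible only if every part has at least 4 observations at 3 distinct PAR
levels. Candidates are evaluated simplest-first, so exact ties go to fewer
parts. The protocol this emulates chose periods "by best fit" without naming
a criterion; AICc is our concrete, reproducible choice and penalises the
extra parameters a finer partition spends.

## Respiration

Two functional forms compete per collar:

* linear, $ER = a\,T + b\,\mathrm{WTL} + c$, with $T$ either air temperature
  or soil temperature at 5 cm, with and without the water-table term;
* exponential (Lloyd–Taylor-type),
  $ER = ER_{ref}\exp\!\big(E_0\,[1/(T_{ref}-T_0) - 1/(T_{air}-T_0)]\big)$,
  evaluated in Kelvin with $T_{ref}$ = 283.50 K (10.35 °C) and $T_0$ =
  237.48 K (−35.67 °C), the conventional constants for northern peatlands.
  $ER_{ref}$ is the respiration at the reference temperature and $E_0$ (K)
  the temperature sensitivity; start values are $ER_{ref,0}$ = mean observed
  ER and $E_0$ = 100 K.

Selection is again AICc ($k$ = coefficients + 1), with exact ties broken
toward fewer parameters and then toward the exponential form (it is the
mechanistically motivated one and never predicts negative respiration).
`fit_er(forms = "exponential")` restricts the candidate set when a single
relationship is wanted. At least 5 ER observations are required; collars
failing the minimums are reported unfittable with a warning and excluded
from upscaling — no silent imputation.

# Seasonal integration

Hourly GEP is predicted from the chosen partition and hourly PAR; hourly ER
from the selected model and hourly temperature (and water table, offset per
collar). Linear-form ER predictions are floored at zero: respiration is
non-negative by definition and a linear extrapolation to a cold night can
cross zero. Each hourly value is a daily-rate sample covering 1/24 day, so
seasonal totals are $\sum/24$ over the grid. The default season window is
[2016-05-24, 2016-09-14), end-exclusive — exactly 113 days, 2712 hourly
steps; the window is a configuration entry. Gaps in the grid are an error
naming the missing timestamps, never silently skipped.

Sparse CH4 campaigns are integrated by the trapezoid rule between
consecutive accepted/zero measurements, $F_{1\text{–}2} = \tfrac12 (f_1 +
f_2)(t_2 - t_1)$. The window edges are filled by constant extension of the
first and last measurement — the conservative choice over extrapolating a
trend, since the edge segments are short relative to the season. Rejected
measurements simply leave a longer trapezoid between their neighbours.

Derived quantities satisfy exact identities, asserted on every budget
produced: $C = \mathrm{NEE}\cdot 12/44 + \mathrm{CH_4}\cdot 12/16$ (g C
m⁻²) and $\mathrm{GWP} = \mathrm{NEE} + 27\,\mathrm{CH_4}$ (g CO2-e m⁻²;
27 is the 100-year global warming potential of non-fossil methane, a
configuration entry). Budgets keep full precision; rounding to printed form
(integers; one decimal for CH4) happens only in `run_report()`.

# Cover-type upscaling

Survey plots (and collars) are classified by fixed rules: open water is its
own type; otherwise bare if vascular cover < 20% — the bare rule is applied
*before* the shrub rule, so a plot with 18% vascular and 21% shrub cover is
bare — then shrubs if shrub cover > 20%, else herbaceous. Sector weights are
plot-count proportions (plots are laid out evenly along transects whose
number is proportional to sector area, so counts are an area proxy). Sector
budgets are per-type means ± SD plus the cover-weighted `ALL` row; the
weighted SD column is the cover-weighted mean of per-type SDs, matching how
such tables are conventionally printed. If a weighted cover type has no
budgeted collar, its weight is dropped and the rest renormalised, with a
warning.

The vegetation volume index implemented here is the mean over sticks of the
mean per-band visual obstruction (0–100). The external program historically
used for this transformation is not specified openly, so this documented
index is a stand-in and should be used as a *relative* covariate only, never
compared numerically to published volume-index values.

# The synthetic site

`gen_site()` generates a four-sector site (24 collars) emulating a rewetting
chronosequence: unrestored (bare-dominated, water table −15 cm), first-year
rewetted-and-profiled (flooded +40 cm, open water, unvegetated — only dark
CO2 and CH4 runs, mirroring how submerged collars are measured), first-year
rewetted (mixed cover, water table at the surface) and a reference fen
(+8 cm). Drivers are hourly: PAR a day-length-aware half-sinusoid times a
daily cloudiness factor (zero at night), air temperature a seasonal arc +
diurnal cycle + AR(1) noise, soil temperature a strongly damped filter of
air temperature, water table a slow mean-reverting walk. Campaigns run every
10 days ± 1 day at noon — 11 visits, emulating one-to-two-weekly sampling —
with CO2 shade sequences (fractions 1, 0.5, 0.25, 0) of 15-s readings over
3 min and 4-point CH4 series at 7/15/25/35 min.

Per-cover-type truth parameters are set at magnitudes typical of
growing-season fen chamber work (e.g. herbaceous $Q$ = −0.05,
$GP_{max}$ = −40, $ER_{ref}$ = 4 g CO2 m⁻² d⁻¹, $E_0$ = 200 K; CH4 base
rates 0.02–0.10 g CH4 m⁻² d⁻¹, all above the detection implied by the
0.5 ppm rule so zero-classification stays meaningful). The methane truth
model is log-linear in soil temperature with a piecewise water-table
response rising to +30 cm of standing water and declining above — the shape
reported qualitatively for rewetted fens, with the exact functional form our
own. Reading noise is 1 ppm (CO2) and 0.05 ppm (CH4 vials). Ebullition is
injected with 7% probability as a concentration spike on the mid-series CH4
sample; a spike there reliably drives the linear r² below the 0.60 cut,
whereas a persistent step on the last samples of a 4-point series cannot
(its r² is bounded near 0.82 regardless of magnitude), so the spike is the
simplest event the QC rule can actually catch. All randomness flows from one
seed; equal configurations are byte-identical.

What the generator does *not* emulate — and hence what passing tests cannot
show about real data: instrument drift and calibration error, chamber
artefacts (pressure perturbations, heating), plant phenology beyond the
PAR/temperature responses, spatial autocorrelation between collars,
rainfall-event water-table dynamics, and non-growing-season fluxes.

# Verification sizes and limitations

The test-suite runs parameter-recovery ensembles of 100 seeds (12-point
light-response fits at noise SD 0.5 g m⁻² d⁻¹; 10-campaign respiration fits
at 10% noise), a 200-run chamber-noise recovery check, and one full-pipeline
run on the default 24-collar, 11-campaign site — sizes chosen so the whole
suite completes in well under a minute while leaving the ensemble statistics
stable. Known limitations: only the rectangular-hyperbola light response and
the two respiration forms above are offered; no uncertainty propagation
beyond per-type SDs; the season window treats the site as snow-free
throughout; and weighted sector means inherit whatever bias the plot-count
weights carry relative to true areal cover.
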