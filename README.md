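# fenflux

Growing-season CO2 and CH4 budgets from closed-chamber measurements on
peatlands, with cover-weighted upscaling from collars to site sectors.

Peatlands drained for peat extraction are strong CO2 sources; rewetting them
can restore wetland vegetation and the carbon sink function, at the cost of
renewed methane emission. Quantifying that trade-off from field data means
walking a long chain: raw chamber concentration series → quality-controlled
instantaneous fluxes → light-response and respiration models per collar →
hourly gap-filled seasonal totals → CO2-equivalent budgets → area-weighted
sector means. `fenflux` implements that chain as tested, composable R
functions, for researchers and restoration practitioners working with static
chamber data on rewetted or reference peatland sites. A synthetic-data
generator with full truth bookkeeping lets every stage be verified end to
end without field data.

## The models

**Chamber fluxes.** Each deployment's concentration series (ppm vs seconds)
is fitted by ordinary least squares and converted to a mass flux by the
ideal-gas law:

```
F = s · 10⁻⁶ · P/(R·T) · h · M · 86400        [g gas m⁻² d⁻¹]
```

with `s` the slope, `h` the effective chamber height, and `M` = 44 (CO2) or
16 (CH4). Negative flux is uptake. QC follows the standard static-chamber
rules: CO2 runs spanning < 2 ppm (CH4: ≤ 0.5 ppm) are zero flux; CO2 runs
with slope r² ≤ 0.75 are rejected as non-linear; CH4 runs with r² < 0.60 are
rejected as ebullition-contaminated.

**Partitioning.** The darkened run (PAR = 0) of each campaign measures
ecosystem respiration (ER); lit runs measure net ecosystem exchange (NEE),
and gross ecosystem productivity is GEP = NEE − ER.

**Light response.** Per collar (and per seasonal period, chosen by a
corrected information criterion), GEP follows a rectangular hyperbola:

```
GEP = PAR · Q · GPmax / (PAR · Q + GPmax)
```

**Respiration.** ER is modelled either linearly, `ER = a·T + b·WTL + c`
(T = air or 5 cm soil temperature, WTL = water table level), or by the
Lloyd-Taylor-type exponential in Kelvin with Tref = 283.50 K, T0 = 237.48 K:

```
ER = ERref · exp( E0 · [ 1/(Tref − T0) − 1/(Tair − T0) ] )
```

The best candidate is selected per collar by AICc.

**Budgets.** Hourly GEP and ER predictions over the 113-day season are
summed (each hourly value is a daily-rate sample, so totals are Σ/24);
sparse CH4 campaigns are integrated by the trapezoid rule
`F₁₋₂ = ½(f₁+f₂)(t₂−t₁)` with constant extension to the season edges. Then
`C = NEE·12/44 + CH4·12/16` and `GWP = NEE + 27·CH4` (100-year, non-fossil
methane). Collar budgets are upscaled to sector means weighted by vegetation
cover-type proportions from survey plots (open water; bare if vascular cover
< 20%; shrubs if shrub cover > 20%; else herbaceous).

## Worked example

```r
library(fenflux)

# one CO2 chamber run: 15-s readings over 90 s
sl <- fit_slope(c(0, 15, 30, 45, 60, 75, 90),
                c(401.2, 404.1, 407.3, 409.8, 413.0, 415.9, 419.1))
sl$slope_ppm_per_s              # 0.1976  (ppm/s)
sl$r2                           # 0.9994  -> qc_co2: "accepted"
slope_to_flux(sl$slope_ppm_per_s, 18.5, 0.33, "CO2")
# 10.36 g CO2 m^-2 d^-1 (positive: emission)

# full pipeline on a synthetic rewetted-fen site (24 collars, 11 campaigns)
site <- gen_site(sim_config(), seed = 42)
res <- run_pipeline(site$runs, site$wells, site$drivers,
                    site$collars, site$plots)
run_report(res$summary)
```

```
 sector_id cover_type n weight  nee nee_sd  ch4 ch4_sd    c c_sd  gwp gwp_sd
        R1       bare 2   0.17  676     32  3.0    0.0  187    9  758     32
        R1 herbaceous 2   0.67 -459      7 15.2    0.1 -114    2  -49      6
        R1     shrubs 2   0.17 -435     13 12.2    0.1 -110    4 -106     17
        R1        ALL 6   1.00 -266     12 12.7    0.1  -63    3   76     12
       REF herbaceous 3   0.53 -475     10 17.6    0.1 -116    3   -1      7
       REF     shrubs 3   0.47 -453     24 14.2    0.0 -113    7  -70     24
       REF        ALL 6   1.00 -465     17 16.0    0.1 -115    4  -33     15
       RP1 open_water 6   1.00  292      3 11.4    0.1   88    1  599      3
       RP1        ALL 6   1.00  292      3 11.4    0.1   88    1  599      3
       UNR       bare 3   0.83  686     10  2.2    0.0  189    3  746     10
       UNR herbaceous 3   0.17 -468     23 11.1    0.1 -119    6 -169     20
       UNR        ALL 6   1.00  493     12  3.7    0.0  137    3  594     12
```

Each row is a sector × cover type: mean (± SD across collars) seasonal NEE
(g CO2 m⁻²), CH4 (g CH4 m⁻²), total carbon (g C m⁻²) and GWP (g CO2-e m⁻²)
over 113 days; `ALL` rows are the cover-weighted sector means. In this
simulated site the vegetated rewetted sectors (R1, REF) are net CO2 sinks
while the unrestored (UNR) and flooded unvegetated (RP1) sectors are
sources, and methane offsets part of the CO2 uptake in the GWP column —
the qualitative pattern the generator is built to emulate.

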