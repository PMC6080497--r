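# canemass

Sugarcane ground campaigns convert cheap, non-destructive biometrics —
stalk height *H*, stalk diameter *D*, cane counts per row-metre *C*, leaf
area index — into the yield quantities that agronomic models and satellite
products need: cane biomass per cane and tons cane per hectare (TCH).
`canemass` implements that chain for campaign scientists and remote-sensing
validators, together with a full uncertainty budget for every step.

The core model is allometric: the stalk is a tapered cylinder,

    BM_S = (π D² / 4) · H · ρ_S(t) · F        BM_C = BM_S + BM_L(t)
    TCH  = BM_C · C(t) · 10 / S

with stalk mass density `ρ_S(t)` (linear trend, kg/m³), leaf biomass per
cane `BM_L(t)` (through-origin quadratic trend, kg), taper factor
`F = 0.977` calibrated from destructive samples, and mean row spacing
`S = 1.2` m. Seasonal interpolation uses three-parameter logistic curves
fitted by constrained hierarchy: a pooled *general* fit supplies starting
values and widened 95% confidence bounds for per-field biomass re-fits and
per-sampling-unit cane-density re-fits.

Uncertainty comes in three tiers — instrument operation, idealization
(local plant variability) and function-fitting precision — propagated two
ways: analytically (first-order delta method plus second-order corrections,
validated against Monte-Carlo oracles) and empirically (100 × 100
measurement-perturbation ensembles that re-fit the growth curves and band
the TCH profiles). Transect variograms and a weather-station precipitation
agreement rate round out the campaign analytics, and a synthetic-campaign
generator with known ground truth makes the whole pipeline testable without
field data.

## Worked example

```r
library(canemass)

# the biomass equation on one mature cane
cane_biomass(D = 0.030, H = 3.00, rho_S = 1100, BM_L = 0.100)
#> # A tibble: 1 × 2
#>    BM_S  BM_C
#>   <dbl> <dbl>
#> 1  2.28  2.38

# 2.379 kg per cane at 8 canes per row-metre, 1.2 m row spacing
tch(2.379, C_row = 8)
#> [1] 158.6
```

A cane with a 3 cm diameter, 3 m stalk and 1100 kg/m³ stalk density carries
2.28 kg of stalk and, with 0.1 kg of leaves, 2.38 kg total; at 8 canes per
row-metre that stand yields 158.6 t/ha.

The same functions drive whole campaigns. Here a synthetic campaign with
known truth is simulated, the growth-curve hierarchy fitted, and TCH
evaluated per sampling unit:

```r
cfg  <- truth_config(seed = 1)       # 4 fields, 16 units, 8 visits
cmp  <- simulate_campaign(cfg)
cmp
#> Sugarcane campaign: 4 fields, 512 biometric records, 40 destructive records

fits <- fit_growth_curves(cmp)
fits
#> Campaign growth-curve fits: general biomass (delta_y = 2.42 kg) + 4 field
#> re-fits; general density + 16 unit re-fits

tidy(fits$biomass_fields[["F1"]])
#> # A tibble: 3 × 5
#>   term    estimate std.error conf.low conf.high
#>   <chr>      <dbl>     <dbl>    <dbl>     <dbl>
#> 1 delta_y   2.29     0.0554    2.18      2.40
#> 2 k         0.0245   0.00194   0.0206    0.0284
#> 3 t0      151.       4.03    143.      159.

predict_tch(fits, t_grid = c(75, 225, 330)) |> head(3)
#> # A tibble: 3 × 6
#>   field_id unit_id     t  BM_C C_row   TCH
#>   <chr>    <chr>   <dbl> <dbl> <dbl> <dbl>
#> 1 F1       F1-ESU1    75 0.307 14.9   38.0
#> 2 F1       F1-ESU1   225 1.97  11.7  193.
#> 3 F1       F1-ESU1   330 2.26   8.95 169.
```

Field F1's re-fitted asymptote (2.29 kg, true value 2.2) sits inside the
widened pooled bounds; unit F1-ESU1 climbs from 38 t/ha at day 75 to about
170 t/ha at day 330 as biomass accumulates while cane density thins.
Uncertainty bands and precision tables follow from
`build_precision_table()`, `campaign_tch_uncertainty()` and
`propagate_tch()`; `autoplot()` methods draw the fits, bands and
variograms. The methods vignette
(`vignettes/sugarcane-biomass-uncertainty.Rmd`) documents the models,
the precision tiers and every pinned numerical choice.

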