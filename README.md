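# tidalissa

Integrated step-selection analysis (iSSA) for birds foraging in tidal
wetlands, where the usability of every site rises and falls with the
tide. The package was built for studies of wading-bird habitat selection
in estuaries containing a mix of natural wetlands (unvegetated flats,
eelgrass, tidal marsh) and shellfish aquaculture infrastructure, asking:
which wetland types does a bird select, and how does that selection
change with the water depth it would encounter there at that moment?

## What it does

**Covariate engine.** Overlays classed wetland vector layers (base
classes, eelgrass, shellfish gear) onto a 10 m raster with
shellfish > eelgrass > base precedence; merges a DEM with bathymetry at
the tide datum; interpolates hourly tide predictions with a
shape-preserving cubic; and computes time-specific water depth
`depth(x, y, t) = tide(t) − elevation(x, y)` (negative = above the
waterline).

**Tracks.** Reads Movebank-style GPS fixes; filters to accuracy < 10 m,
daylight (solar elevation ≥ 0°), and speed ≤ 5 m s⁻¹; regularises to
10-min steps; builds step lengths and signed turn angles.

**iSSA core.** Fits per-bird tentative movement kernels (gamma step
length, mean-zero von Mises turn angle), samples 10 available steps per
observed step, restricts end-of-step depths to [−0.5, 1] m, and
maximises the stratified conditional-logistic partial likelihood

```
ℓ(β) = Σ_s [ x_used'β − log Σ_j exp(x_j'β) ]
```

by Newton–Raphson with analytic derivatives. Seven candidate models
(wetland and linear/quadratic depth, up to the full
wetland × (depth + depth²) interaction) are ranked by AICc; the best
model yields log relative-selection-strength (log-RSS) curves versus the
unvegetated-flat reference with delta-method intervals, and a
step-length × wetland refit corrects the movement kernel for the
imprint of selection (`shape' = shape + β_ln(sl)`,
`1/scale' = 1/scale − β_sl`). Birds whose models separate (e.g. a bird
that almost never enters shellfish areas) are flagged non-converged and
excluded from pooled inference.

**ODBA.** Overall Dynamic Body Acceleration per 6 s, 10 Hz tri-axial
burst: the sum over axes of absolute deviations from each axis's burst
mean. A random-intercept mixed model (`odba ~ wetland + (1 | bird)`,
ML) with a likelihood-ratio test compares energy expenditure across
wetland types.

**Synthetic truth.** A generator builds tidal landscapes, mixed
semidiurnal tides, movers that choose steps by `exp(x'β)` against their
own kernel, and accelerometer bursts with calibrated ODBA — so the whole
pipeline is validated end to end against known parameters.

## Worked example

```r
library(tidalissa)
ls    <- make_landscape(seed = 1)            # 1.2 x 1.2 km synthetic estuary
tide  <- make_tide(duration_days = 45)
truth <- synthetic_truth()
fixes <- simulate_track(ls$habitat, ls$elevation, tide, truth,
                        n_steps = 1500, bird_id = "egret01", seed = 1)

cfg  <- run_config(seed = 1)
prep <- prepare_bird(fixes, ls$habitat, ls$elevation, tide, cfg)
prep$kernel
#> movement_kernel (tentative): gamma(shape = 1.221, scale = 50.35 m), vonMises(kappa = 0.3769)
#>   mean step length 61.5 m

cand <- fit_candidates(prep$strata, cfg)
cand$aicc[, c("model", "K", "AICc", "dAICc", "weight")]
#>                     model  K AICc  dAICc    weight
#> 1                    full 11 4421  0.000 9.792e-01
#> 2 wetland_depth_quadratic  5 4429  8.021 1.775e-02
#> 3         wetland_x_depth  7 4434 12.800 1.627e-03
#> 4                 wetland  3 4435 13.688 1.044e-03
#> 5           wetland_depth  4 4436 15.609 3.995e-04
#> 6         depth_quadratic  2 4480 59.594 1.122e-13
#> 7                   depth  1 4491 70.577 4.627e-16

log_rss(cand$fits$full, "shellfish", c(0, 0.3, 0.8))
#>     wetland depth log_rss    lwr  upr
#> 1 shellfish   0.0   0.675 -0.682 2.03
#> 2 shellfish   0.3   1.194  0.628 1.76
#> 3 shellfish   0.8  -0.815 -2.031 0.40
```

Reading the output: the tentative kernel says this bird's 10-min steps
average ~62 m with weak directional persistence. The AICc table puts
essentially all model weight on the full wetland × quadratic-depth
interaction — selection of wetland types genuinely depends on water
depth. The log-RSS rows compare shellfish areas against unvegetated
flats at the same depth: selection is strongest near 0.3 m of water
(log-RSS 1.19, CI excluding 0) and collapses by 0.8 m — the narrow-band
pattern the quadratic interaction encodes.

`run_all()` orchestrates the same steps for many birds plus the ODBA
mixed model, writing per-bird fit JSONs, AICc tables, RSS curves and a
run log; `inst/cli/tidal-issa.R` is a thin script wrapper
(`run --config run.yaml`, `simulate --out dir`).

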