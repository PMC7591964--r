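# afmwv

Work-of-indentation analysis for AFM force curves on soft and biological
samples.

## The problem

AFM nanoindentation estimates the local Young's modulus of a soft sample
(a cell, a gel, a tissue section) by pressing a sharp tip into it and
fitting the load–indentation curve with a contact-mechanics model. For a
conical tip on a linear elastic half-space the model is Sneddon's relation

    P = (2/π) · E tan(θ) / (1 − ν²) · h²

with load *P*, indentation depth *h*, Young's modulus *E*, Poisson's ratio
*ν* and cone half-angle *θ*. The fit is only meaningful when the sample
actually behaves as a linear elastic half-space over the probed depth —
which thin samples on stiff substrates, and heterogeneous samples such as
cells, often do not.

`afmwv` implements a validity test and an alternative modulus estimator
built on one physical quantity: the **work done by the indenter per unit
contact volume**,

    W/V,   W = ∫₀^hmax P dh,   V = (8 tan²θ / 3π²) · hmax³  (cone),

which has units of pressure (J/m³ = Pa). For a cone on an elastic
half-space the ratio is depth-independent,

    W/V = π E / (4 (1 − ν²) tan θ),

so plotting *W* against *h³* gives a straight line exactly when Hertzian
analysis applies. A linear graph validates the Sneddon fit and yields the
modulus directly from the slope-free ratio, E = 4 (1 − ν²) tanθ (W/V) / π;
a curved graph flags depth-dependent mechanics (substrate feel-through or
heterogeneity), which the package then characterises by a second-degree
polynomial in x = h³ and a depth-resolved W/V profile. Batch analysis over
force-volume grids produces modulus and W/V maps with summary statistics.

## Who it is for

Anyone processing AFM force-spectroscopy data on soft matter: raw
displacement–deflection records (z, d, spring constant k) or pre-converted
load–indentation curves, single curves or force-volume grids. A synthetic
curve generator with known ground truth supports validation end to end.

## Worked example

```r
library(afmwv)
cone <- indenter_cone(25)                     # 25-degree conical tip

# a synthetic fibroblast-like curve: E = 5.16 kPa, k = 0.01 N/m, 1% noise
fc    <- gen_hertzian_raw(E = 5160, noise = 0.01, seed = 7)
curve <- to_indentation(fc)                   # contact point + h = (z-z0)-(d-d0)

fit <- fit_sneddon(curve, cone, nu = 0.5)
fit
#> <Sneddon fit: E = 5.179 kPa, a = 2050 N/m^2, R^2 = 0.9984, n = 997>

wp <- work_numeric(curve)                     # cumulative trapezoid work
linearity_test(wp)
#> <W = f(h^3) linearity: R^2 = 1.00000 >= threshold 0.9990 -> linear (Hertzian)>

wvp <- wv_profile(wp, cone)                   # depth-resolved W/V
mean(wvp$wv) / 1e3
#> 11.51                                      # kJ/m^3
E_from_wv(mean(wvp$wv), cone) / 1e3
#> 5.13                                       # kPa, agrees with the Sneddon fit
```

The two estimates agree because the curve is Hertzian: the linearity test
passed, so both routes are valid and the W/V route needs no fitting at all.
For depth-dependent curves (`linearity_test()` fails) use
`fit_wv_polynomial()` + `wv_at_depth()` and `linear_range_detect()` to find
the depth range where Hertzian analysis still holds.

Grid workflows: `gen_grid()` → `analyze_grid()` → `summarize_map()` /
`autoplot()`; `write_map_tsv()` and `write_map_summary_json()` export
results. A thin command-line wrapper lives at `inst/cli/afmwv`
(`simulate`, `analyze`, `map` subcommands).

## Acceptance script

`scripts/acceptance.R` recomputes the package's reference quantities from
scratch — the Sneddon-fit modulus of the reference load–indentation
relation, the modulus recovered from a measured W/V ratio, and the
depth-dependent W/V values evaluated from the reference work polynomial —
and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
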