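---
title: "Work per unit contact volume: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Work per unit contact volume: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmwv)
```

## The model

For any axisymmetric indenter pressed into a linear elastic half-space the
load–indentation relation is a power law, $P = a h^m$, with $m = 2$ for a
cone and $m = 3/2$ for a sphere (parabolic approximation). Three closed-form
quantities follow: the work of indentation
$W = a\,h_{\max}^{m+1}/(m+1)$, the contact stiffness
$S = a m h_{\max}^{m-1}$, and — through the universal relation
$S/r_c = 2E/(1-\nu^2)$ — the contact radius $r_c = c\,h_c^{m-1}$ with
$c = a m (1-\nu^2) b^{m-1} / 2E$ and $b = h_{\max}/h_c$ the depth ratio
($\pi/2$ for a cone, $2$ for a sphere). Integrating $\pi r^2$ over the
contact depth gives the volume of the indenter part in contact, and hence
the ratio the package is named for:

$$\frac{W}{V} = \frac{a\,(2m-1)\,b^{2m-1}}{\pi c^2 (m+1)}\; h_{\max}^{2-m}.$$

At $m = 2$ the depth dependence vanishes: for a cone,

$$\frac{W}{V} = \frac{\pi E}{4 (1-\nu^2)\tan\theta},$$

a material constant with units of pressure. Two consequences drive the whole
package:

1. **Validity test.** $V \propto h^3$ for a cone, so $W/V$ constant is
   equivalent to $W = f(h^3)$ being a straight line. An ordinary
   least-squares $R^2$ on that graph classifies a curve as Hertzian or
   depth-dependent without committing to any particular contact model.
2. **Modulus estimator.** Inverting the constant gives
   $E = 4(1-\nu^2)\tan\theta\,(W/V)/\pi$ — a modulus from a single measured
   ratio, no curve fit, valid exactly when the test passes.

For a sphere $W/V \propto \sqrt{h_{\max}/R}$ even on a perfect half-space,
so the flat-ratio diagnostic is a strictly conical tool; the spherical form
is provided for completeness.

### Two derivation notes

* The conical constant is implemented with $\tan\theta$ in the
  *denominator*. A variant with $\tan\theta$ in the numerator circulates,
  but it is dimensionally consistent yet numerically inconsistent with the
  $m=2$ reduction of the general power-law form above, and it fails the
  package's own cross-checks (`wv_general()` vs `wv_conical_from_E()` agree
  to machine precision only with the denominator form; the acceptance tests
  pin the same choice against the reference worked values).
* The spherical form produced by the same reduction carries a $1/\pi$
  factor that some published variants omit. The derivation-consistent form
  is the default; `wv_spherical(..., printed_form = TRUE)` exposes the
  $\pi$-free variant for comparison with such sources. No worked example
  exists to arbitrate externally, so internal consistency decides the
  default.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `half_angle` | degrees at the boundary, radians inside | 25 | common effective half-angle of sharp pyramidal probes; pyramids are handled by the cone approximation with a user-supplied effective angle |
| `nu` | — | 0.5 | incompressible limit, the standard assumption for cells |
| `k` | N/m | 0.01 | a soft cantilever typical of live-cell work |
| `linearity_threshold` | — | 0.999 | separates clean Hertzian work curves ($R^2 \approx 0.9998$) from clearly depth-dependent ones ($R^2 \lesssim 0.997$) with margin on both sides; configurable |
| `floor_frac` | — | 0.05 | $V \to 0$ as $h^3$, so pointwise ratios below 5% of the maximum depth amplify noise and integration error without adding information |
| `depth_limit` | m | none | restrict analysis to a shallow range (e.g. 200 nm) when substrate effects are suspected |
| `thickness` | m | none | when supplied, indentation beyond 10% of it triggers a warning (the 5–10% rule of thumb); no correction is applied |

All computation is SI internally (m, N, Pa, J); nanometre/nanonewton columns
are converted at the I/O boundary by declared units, because silent unit
mixing is the dominant error mode in this domain.

## Numerical choices

**Work integration.** Cumulative composite trapezoid on the measured grid,
no resampling; non-uniform grids are handled natively, which avoids
interpolation bias on raw AFM data. The first sample is joined to the
origin with one trapezoid, consistent with $P(0)=0$. Convergence is second
order; at 1000 points the end-point work of a quadratic load is accurate to
$\sim 5\times10^{-7}$ relative.

**Contact-point detection.** The default method scans every candidate split
$z_0$, modelling a constant baseline before it and a Sneddon-type quadratic
after it, and keeps the split with the smallest total squared residual. Two
details are deliberate:

* The post-contact model is quadratic in the *candidate indentation*
  $h = (z - z_0) - (d - d_0)$, not in piezo travel $z - z_0$. With soft
  cantilevers the bending term $P/k$ is comparable to $h$, and a quadratic
  in $z$ alone biases the split towards the baseline.
* On strongly depth-dependent curves the quadratic under-fits the deep
  stiffening and drags the split late. The detector therefore refines
  itself on a shallow truncated sub-curve — where the quadratic is locally
  valid — but only when the post-contact residual exceeds the baseline
  noise level by a clear factor, so Hertzian curves are never touched. The
  first re-acceptance margin is strict (noise cannot trigger a spurious
  shift); once a real shift is confirmed the iteration converges with a
  tight margin.

A linear baseline tilt (photodiode artifact) is estimated on the
pre-contact segment, removed when statistically significant
(t-test, p < 0.01), and the contact point is relocated on the corrected
signal. A simple threshold method (first sample above baseline mean +
$n\sigma$, default $n=5$) is available as `method = "threshold"`.

**Monotone depth.** Deflection noise enters both channels ($P = k\,\delta$,
$h = \Delta z - \delta$), making the computed depth locally non-monotone.
The pairs are *reordered by depth* rather than dropping backward samples:
dropping selects against positive force noise and biases every downstream
estimate low by several percent at realistic noise, while reordering keeps
every raw value and no smoothing is introduced.

**W/V modulus route.** When a curve passes the linearity test, the reported
`E_wv_Pa` uses the endpoint ratio $W(h_{\max})/V(h_{\max})$: the full-depth
work integral averages force noise away, whereas the mean of the pointwise
profile weights its noise-amplified shallow part equally. The pointwise
profile is still reported (`wv_mean_Jm3`) as the depth-resolved descriptor.

**Linear-range detection.** Sub-profiles $[0, h]$ are scanned from 20% of
the depth range upward, one sample at a time, and the scan *stops at the
first failure* of the linearity threshold. The largest passing prefix is
not a safe answer: once the substrate bends the $W = f(h^3)$ graph, deeper
prefixes can look spuriously straight again because the stiff regime
dominates the regression.

**Polynomial degree.** The depth-dependent work summary is a fixed
second-degree polynomial in $x = h^3$; higher degrees add nothing
identifiable on single curves and are out of scope.

## The synthetic generator: what a green test establishes

`gen_hertzian_raw()` states a reference experiment — 25° cone, $k = 0.01$
N/m, $\nu = 0.5$, depths to 1000 nm, Gaussian force noise with SD equal to
1% of the maximum load — and builds the raw record through the standard
instrument identities $z = z_0 + h + P/k$, $d = P/k$, with a flat
pre-contact baseline. Depth dependence is emulated two ways:
a quartic stiffening term $P = a_1 h^2 + a_2 h^4$, and a soft-on-stiff
bilayer whose effective modulus follows a logistic transition at a stated
onset depth. The transition width defaults to 25 nm, a sharp interface on
the scale of the layer (~6% of the default 400 nm onset): a bilayer is
physically a step in material, and the logistic is numerical smoothing, not
a claim about interphase breadth. Pixel moduli in grids default to a
lognormal law (positive, right-skewed, as cell maps are), mean 7.4 kPa and
SD 2 kPa. All randomness flows from one seed.

What the generator does **not** emulate: viscoelastic creep and hysteresis,
adhesion, tip imperfection, drift across a map, and the heavy-tailed
instrument noise of real photodiodes. A green recovery test therefore
establishes correctness of the *analysis chain* under the stated noise
model — not fidelity to every failure mode of a real instrument.

One stated-world consequence worth knowing: with a soft cantilever, force
noise defined relative to the *maximum* load makes the shallow contact foot
of a strongly stiffening curve sub-noise. Contact-point recovery on noisy
bilayer curves is therefore intrinsically poor, and the bilayer
onset-localisation guarantee is stated noise-free.

## Known limitations

* Strictly conical (or effective-cone pyramidal) analysis for the flat-ratio
  test; blunted tips, hyperboloids and adhesive contact are out of scope.
* No bottom-effect correction: thin samples are flagged (thickness warning,
  linear-range detection), never corrected.
* A depth-dependent verdict cannot distinguish substrate feel-through from
  genuine heterogeneity; the package flags and quantifies, it does not
  attribute.
* The quartic detection example is deliberately strong: a quartic term
  contributing 20% of the maximum load perturbs the work curve too little
  to fail the 0.999 linearity threshold (its work exponent $x^{5/3}$ is
  close to linear in $x$); robust detection needs roughly a 50%
  contribution, and the tests assert exactly that.
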