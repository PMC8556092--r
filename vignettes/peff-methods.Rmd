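---
title: "Methods: effective point of measurement of a cylindrical chamber in carbon-ion beams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: effective point of measurement of a cylindrical chamber in carbon-ion beams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peffkit)
```

## Scope and model overview

A cylindrical ionization chamber aligned with its axis perpendicular to a
carbon-ion beam reads a chord-length- and fluence-weighted average of the
dose over its air cavity, not the dose at its geometric centre. This
vignette documents the models the package implements to locate the
effective point of measurement (P_eff), the conventions and tunable
parameters, the numerical choices, and what the synthetic-beam tests do
and do not demonstrate.

Four computational layers build on each other:

1. **WET accounting** (`chambers`, `curves`): every material slab between
   the nozzle and a chamber's point of measurement is converted to
   water-equivalent thickness so peak positions from different chambers
   live on a common water-depth axis.
2. **Cavity weighting** (`dutreix`): the classical constant-shift
   integral for forward-directed fluence.
3. **Scatter decomposition** (`barrier`): energy- and field-size-
   dependent splitting of the shift into vertical and horizontal
   components through a screened spreading-angle model.
4. **Shift extraction** (`curves`, `synthbeam`): peak-to-peak comparison
   of a plane-parallel reference curve and a cylindrical-chamber curve.

## Water-equivalent thickness rules

Per-material scaling constants convert physical thickness to WET: PMMA
multiplies by 1.16; graphite by its density times 1.16/1.19 (the PMMA
factor per unit density); lacquer and water count at face value. These
constants reproduce both published worked chamber-wall calculations
bit-exactly:

```{r}
chs <- builtin_chambers()
sapply(chs, chamber_wet)
```

Two conventions coexist in the source material for thin graphite coats:
the 34080 record folds its 0.02 mm coat into the PMMA electrode layer and
scales the combined 1.78 mm by 1.16 (giving 2.0648 mm), while the 34070
record scales graphite separately by density. Neither is declared
canonical, so the bundled records reproduce each published calculation as
printed, per chamber, and the factors are exposed through `wet_factors()`
for other protocols. The quoted 3% uncertainty on the PMMA factor
corresponds to roughly 0.1 mm of depth for these windows.

The published Farmer-chamber wall WET of "4.022 mm" is treated as a
transcription slip (it repeats the 34070 window value); the Farmer layer
list itself sums to 0.551 mm, which is what the bundled record yields.

## The cavity-weighting integral

For a parallel, uniform, forward-directed fluence Φ entering a cylinder
of radius r, a chord at polar angle θ (measured from the beam axis) sits
y = r cos θ above the centre, has length 2y, and receives Φ·cos θ·ds
particles with ds = r dθ. Weighting displacement by track length and
entry fluence,

$$\frac{y_{\rm eff}}{r}
  = \frac{\int_0^{\pi/2}\cos^3\theta\,d\theta}
         {\int_0^{\pi/2}\cos^2\theta\,d\theta}
  = \frac{2/3}{\pi/4} = \frac{8}{3\pi} \approx 0.8488 ,$$

the familiar 0.85 r upstream shift. Both the closed form
(`dutreix_ratio()`) and a Gauss–Legendre quadrature
(`dutreix_shift()`) are provided; the quadrature exists so a non-uniform
angular weight can be injected and because the same machinery evaluates
the scatter integrals below. Any constant fluence cancels exactly.

## Scatter decomposition and the barrier model

Carbon-ion transport in the cavity is not purely forward: the incident
beam spreads by an angle φ, and the effective point splits into a
vertical (forward-scatter) and a horizontal (side-scatter) part. With
sin φ = +√(1−cos²φ) and the angle conventions sin(90−θ−φ) = cos(θ+φ),
cos(90−θ−φ) = sin(θ+φ), the chord-weighted angular integrals reduce to
closed forms built from four moments (∫cos⁵ = 8/15, ∫cos⁴sin = 1/5,
∫sin²cos³ = ∫sin³cos² = 2/15):

$$\frac{y_{\rm eff,v}}{r} = \frac{4}{\pi}\left(\frac{8\cos^2\varphi}{15}
   - \frac{\cos\varphi\sin\varphi}{5}\right), \qquad
  \frac{y_{\rm eff,h}}{r}\Big|_{\rm integral} =
  \frac{4}{\pi}\left(\frac{2\cos^2\varphi}{15}
   + \frac{2\cos\varphi\sin\varphi}{15}\right).$$

`vertical_shift()` and `horizontal_shift_integral()` evaluate these both
by 128-node Gauss–Legendre quadrature of the printed integrands and in
closed form; the two routes agree to 1e-9.

### Dual-mode evaluation

The published chain from beam parameters to cos φ is

$$\cos\varphi = 1 - \frac{2\alpha R_L}{1+\alpha-R_L}, \qquad
  \alpha = \varepsilon\,e^{-1.1}Z^{-0.68}/E_c \;(\text{one reading}), \qquad
  \varepsilon = 1.6\,e^{\ln E_c\,\sqrt{FS}} \;(\text{one reading}),$$

with R_L = −0.6 and Z = 7.4. As typeset these formulas are ambiguous in
operator precedence, and no reading we tried reproduces the published
calibration grid — the literal cos φ exceeds 1 for every tabulated α
(e.g. α = 0.84, R_L = −0.6 gives 1.413). The package therefore evaluates
**two modes** and always labels which one produced a number:

* **literal** — the formulas exactly as typeset
  (`barrier_epsilon_literal()`, `barrier_alpha_literal()`,
  `cos_phi_literal()`), values flagged as not reproducing the
  calibration table. A magnitude-in-numerator variant of cos φ
  (1 − 2α|R_L|/(1+α−R_L)) is provided for inspection because it lands
  near the tabulated cells, but it does not reproduce all of them either.
* **calibrated** — anchored to the ten published grid cells. The
  screening factors follow an inverse-energy law α = C(FS)/E_c to within
  rounding; C is fitted by least squares per field size
  (C(3 cm) ≈ 100.9 MeV/u, C(10 cm) ≈ 23.0 MeV/u) and rounding the fit to
  two decimals reproduces all ten published α cells. cos φ and the
  horizontal-shift row are bilinear table interpolations, exact at the
  grid; log C is interpolated linearly in field size between 3 and
  10 cm. Requests outside 120–400 MeV/u or 3–10 cm are flagged
  (α law) or refused unless extrapolation is explicitly enabled
  (table rows).

The horizontal-shift **row** of the calibration grid cannot be derived
from the horizontal angular integral above (the published derivation
defers to an appendix that is not reproduced); `horizontal_shift_table()`
is therefore interpolation only, and the integral variant carries a flag
saying so. The vertical row, by contrast, *is* the vertical integral:
recomputing it from the tabulated cos φ matches nine of the ten cells
within 0.015 (the 400 MeV/u 3×3 cell, printed 0.34, deviates by ≈0.05
and is treated as a suspected misprint — documented, not asserted).
Recomputing the four trigonometric term rows from the *printed* (rounded)
cos φ values reproduces 37 of 40 cells after two-decimal rounding; the
three exceptions are consistent with the source table having been
computed from unrounded cos φ.

Totals are sums of the horizontal and vertical parts, stored as positive
magnitudes; the upstream direction is expressed as a leading minus sign
at serialization time only. Report columns round to two decimals
(round-half-to-even) and deviations to one decimal, matching the printed
precision of the reference material.

## Curve analysis

**Peak definition.** The Bragg peak is the vertex of a least-squares
parabola fitted over a ±2 mm window (configurable) around the maximum
sample, ties broken toward the smaller depth. This is exact for any
symmetric peak sampled symmetrically and is the whole peak model —
distal-80% or spline definitions are deliberately out of scope because
the reference workflow reports maximum-peak positions only. Degenerate
windows (flat or upward-curved fits) fall back to the sample maximum;
maxima at the scan boundary are refused with advice to extend the range.

**WET chains.** `corrected_peak_depth()` adds the summed WET of a
user-supplied item-by-item chain to the raw peak position. The bundled
`setup_330MeV_example.yaml` reproduces the published end results
(174.9 + 20.882 = 195.782 mm; 164.65 + 33.41 = 198.06 mm), but the
per-item values in it are illustrative: the source material prints only
the totals, so example chains are consistency checks, not reference
decompositions. Shift extraction is invariant under any common offset
added to both chains.

**Uncertainties.** `shift_ratio_table()` reports the mean ratio and the
sample standard deviation over replicate pairs per (energy, field size)
cell, with the uncertainty marked unavailable for single replicates. The
reference tables print "±" values without defining them; sample SD is
this package's choice.

## The synthetic beam generator

`beam_model()` is a phenomenological pristine-Bragg-curve model used to
make every curve operation testable without measurement data: a Gaussian
straggling peak of width σ (default 0.01·R) at range R = a·E^p, on a
gently rising pedestal (default 25% of peak) that continues through the
peak region to the hard cutoff at R + 5σ, emulating the entrance plateau
proximally and, crudely, the fragment pedestal distally. The exponent
defaults to p = 1.7 with a anchored so R(330 MeV/u) = 195.78 mm; both
are exposed. Noise is multiplicative Gaussian, seeded; identical seeds
give bit-identical curves.

The pedestal's symmetry about the peak is a deliberate design choice:
`apply_cavity()` volume-averages the curve with the chord-length kernel
w(u) = 2√(r²−u²) (normalized to unit mass; 64-node Gauss–Legendre over
the cavity diameter) before relabeling depths by the injected shift, and
a locally symmetric baseline keeps that averaging shift-free (residual
bias ≈ 0.002 mm at r = 3.05 mm). An asymmetric plateau-only shape
biases peak-to-peak recovery by ≈ 0.1 mm — real Bragg curves do carry
such asymmetry, which is one reason measured shift ratios carry
percent-level uncertainties while the synthetic recovery is tight.

What passing the synthetic tests shows: the extraction pipeline (parsing,
peak fitting, WET bookkeeping, ratio computation) recovers a known
injected displacement to ≤ 0.05 mm noise-free and ≤ 0.15 mm per curve
pair at 1% multiplicative noise, unbiased over seeds. What it does not
show: correctness of any transport physics — the generator has no
fragmentation spectrum, no energy-dependent straggling shape, no lateral
beam structure, and its cavity kernel is a pure chord-length weight with
no in-cavity spectrum change. Agreement of the barrier model with real
measurements is carried by the published calibration tables, not by the
generator.

Test and acceptance runs use 0.1 mm grids over ≈ 0–210 mm (a few
thousand samples per curve) and 20 noise seeds per condition; these sizes
make each end-to-end recovery a few milliseconds while leaving the
recovery tolerances comfortably resolvable.

## Dose conversion

The calibration relations are implemented with explicit unit bookkeeping:

* K(E) = D_meas·A/(S_Ex·MU), the only dimensionally consistent
  arrangement of the calibration quantities (dose × area per stopping
  power × monitor units), converted to particles/MU via
  1 MeV = 1.602176634e-13 J and 1 Gy·g = 1e-3 J.
* k_TP = (273.2+T)/(273.2+T₀)·(P₀/P), unity at the configurable
  reference conditions (20 °C, 1013.25 hPa). Whether the measured charge
  already includes this correction is protocol-dependent, so
  `absorbed_dose_peff()` exposes it as an explicit optional factor
  rather than hiding it.
* K_Q = [(w/e)_C12·s_w,air]/[(w/e)_Co60·(L/ρ)_w,air]. The stopping-power
  ratios and w values are cited to the literature without printed values
  in the source material, so all four are user-supplied inputs; the
  package bundles no physics constants presented as authoritative.

Recombination, polarity and humidity corrections are out of scope.

## Numerical choices

* Quadrature: Gauss–Legendre throughout (pracma nodes); 128 nodes
  default for the scatter integrals, 256 for the cavity integral, 64 for
  the chord kernel. All integrands are smooth on bounded intervals, so
  convergence is spectral; the closed-form/quadrature agreement at 1e-9
  is asserted in the test suite against an independent adaptive
  quadrature.
* Interpolation: bilinear for calibration-table lookups (exact at grid
  nodes); monotone piecewise-cubic (Fritsch–Carlson) only for overlay
  resampling, never for peak finding; linear interpolation of curve
  samples inside the cavity kernel.
* Curve serialization: 17-significant-digit text so write→read
  round-trips are bit-exact.
* Seeds: every stochastic operation takes an explicit integer seed and
  restores the caller's RNG state.

## Known limitations

* The literal barrier-model formulas cannot be made to reproduce the
  published calibration grid; the calibrated mode is anchored to that
  grid and is therefore only as good as the ten cells it interpolates.
  R_L is only ever described as a Gaussian-distribution parameter; its
  admissible range is unknown.
* The horizontal-shift row has no reproducible derivation; outside the
  tabulated grid the package refuses (or flags) rather than guesses.
* Measured shift ratios for conditions other than the tabulated grid
  (5×5, 8×8 cm² field sizes) are bundled as data but have no model
  counterpart at those field sizes beyond the α interpolation.
* SOBP composition, rectangular fields, film dosimetry and Monte-Carlo
  transport are out of scope.
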