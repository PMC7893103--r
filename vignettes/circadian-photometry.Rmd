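---
title: "Circadian light and circadian stimulus: model, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian light and circadian stimulus: model, assumptions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cslight)
```

`cslight` models the retinal circuit that converts light into a signal for
the suprachiasmatic nucleus, using nocturnal melatonin suppression as the
behavioral anchor. This vignette is the package's own account of the model
it implements, the constructions it had to choose where the underlying
tabulations are not published, and the numerical decisions that make the
results reproducible.

## The phototransduction model

The model has two stages.

**Spectral stage (circadian light, CL_A).** Every SPD is reduced to a
single scalar by spectrally weighted integrals over 380–780 nm. The circuit
is two-state: a blue-versus-yellow opponent signal
`b−y = ∫Sc·E dλ − k·∫Vc·E dλ` selects between a "cool" branch (b−y > 0), in
which the S-ON bipolar pathway adds to the melanopsin (ipRGC) response, and
a "warm" branch (b−y ≤ 0) driven by melanopsin alone. This makes the model
*subadditive*: adding long-wavelength light to a cool source can push b−y
negative and remove the opponent contribution entirely. The boundary
b−y = 0 belongs to the warm branch, and the model is knowingly
discontinuous there — the two branches represent different circuit states,
and no smoothing is applied.

In the original (2005) formulation the cool branch is

```
CL_A = 1548 [ ∫Mc E dλ + 0.7 (b−y) − 3.3 (1 − e^(−∫V′E dλ / 6.5)) ]
```

with `b−y` computed from macular-weighted but un-renormalized S and V
curves, and the warm branch is `1548 ∫Mc E dλ`. The constant 1548
calibrates the scale so that CIE Illuminant A at 1000 photopic lx gives
CL_A = 1000.

The revised formulation (CL_A 2.0) replaces the fixed rod threshold with
rod–cone interaction terms of the form

```
rod(a, g) = a · [∫V′E dλ / (∫Vc E dλ + g ∫Sc E dλ)] · (1 − e^(−∫V′E dλ / 6.5))
```

a scale-invariant rod-to-cone drive ratio times a saturating function of
the scotopic-weighted irradiance; `rod(2.30, 1.00)` modulates the
melanopsin pathway and `rod(1.60, 0.16)` the opponent pathway, and the
opponent weight drops from 0.7 to 0.21.

**Response stage (circadian stimulus, CS).** CS maps CL_A through a fixed
logistic, `CS = 0.7·[1 − 1/(1 + (CL_A/355.7)^1.1026)]`: the asymptote
(0.7), exponent, and half-saturation constant (355.7 for a 1-h exposure)
are treated as properties of the circuit and are never re-fitted per
dataset; only the half-saturation constant may move, and only through the
duration law `half_sat(t) = 355.7·t^−1` (t in hours, supported for 0.5–3 h
of continuous exposure) and the discrete spatial distribution factor
f ∈ {2.0, 1.0, 0.5} (full, central, superior visual field). Both reduce to
multiplication inside the logistic, so `CS_t,f` depends on the product
`t·f·CL_A` only.

### Where the display equation is ambiguous: per-pathway thresholds

The printed revised-model equation can be parsed two ways: subtract both
rod terms from the combined cool-branch signal, or subtract each rod term
from its own pathway. The package implements the per-pathway reading with
each pathway floored at zero:

```
CL_A 2.0 = 1548 [ max(∫Mc E − rod(2.30, 1.00), 0) + max(0.21(b−y) − rod(1.60, 0.16), 0) ]
```

(the second term only when b−y > 0). The reasons are physiological and
behavioral. Physiologically, the rod–cone interaction is described as
*elevating the threshold* of a pathway; a threshold can silence a pathway,
not drive it below zero. Behaviorally, the combined reading makes the
model's small-signal response *negative* for narrowband stimuli near
470–490 nm — the opponent-pathway rod term's ratio is large there (V′ is
near its peak while Vc and g₂·Sc are small) — which collapses the derived
spectral sensitivity exactly where the circuit is known to be most
sensitive. Under the per-pathway reading the constant-criterion derivation
(below) peaks at 460 nm; under the combined reading it cannot peak above
~440 nm. Negative totals are floored at zero in both model generations:
circadian light is a stimulus magnitude.

The 1548 calibration constant is carried unchanged into the revised model,
as printed. The package does not silently recalibrate: `run_calibrate()`
evaluates Illuminant A at 1000 photopic lx under both models and reports
each value and its deviation from 1000. Under the revised model the warm
branch retains its rod term, so some deviation from 1000 is structural and
is reported rather than absorbed.

```{r calibrate}
run_calibrate()
```

## Spectral weighting functions

Seven curves enter the model; all are kept on one shared wavelength grid
(default 380–780 nm at 1 nm).

- **V and V′** are the standard photopic (1924) and scotopic (1951)
  luminous efficiency tabulations, bundled as two-column text at 5-nm
  resolution (the abridged tabulation, with the 507-nm scotopic peak as an
  extra knot) and interpolated linearly onto the session grid. The
  grid-refinement invariant in the test suite bounds the interpolation
  error of any weighted integral at well under 1%.
- **Mc, the in-vivo melanopsin template**, is constructed, not tabulated: a
  vitamin-A1 photopigment nomogram (Govardovskii-type α and β bands)
  multiplied by a crystalline-lens transmittance model, with two free
  knobs — the nomogram λmax and a lens-density scale — solved at run time
  (Nelder–Mead on a smooth peak/FWHM objective, cached per variant) so the
  corneal curve meets the published constraints: peak 485 nm / FWHM 89 nm
  for the default `rea` variant, peak 490 nm / FWHM 84 nm for the
  alternate `cie` variant. The template is specified in the literature
  only by these two scalars, so construction-plus-tuning reproduces
  everything that is actually pinned down.
- **S (S-cone fundamental) and mp (macular pigment)** have no resolvable
  source tabulation, so the package ships documented analytic stand-ins:
  the same A1 nomogram × lens model with λmax tuned so the corneal S-cone
  peak lands at 441 nm, and an asymmetric-Gaussian macular optical density
  peaking at 0.35 (2° viewing) at 460 nm with a broader short-wave than
  long-wave flank, transmittance `10^(−OD)`. Only the *shapes* matter for
  the renormalized Vc and Sc; `build_weighting_function(..., file =)`
  accepts replacement two-column tabulations for users who prefer specific
  published tables.

The lens model is a single exponential in wavelength
(`density = scale · 2 · exp(−(λ − 380)/60)`), a smooth approximation to
young-adult small-pupil lens density; its absolute level is absorbed by the
template tuning. No age dependence, field-size dependence, or 10°
fundamentals are modeled.

## SPDs and photometry

SPDs are corneal spectral irradiance in W·m⁻²·nm⁻¹ on the session grid,
assuming a cosine-corrected detector; pupil size is not modeled. Integrals
use the rectangle rule (`Σ value·Δλ`), matching the tabulation resolution.
Illuminance uses 683 lm/W (photopic) and 1700 lm/W (scotopic maximum).
Monochromatic photon-rate/irradiance conversion uses `hc = 1.98645e−25 J·m`
and the 10⁴ cm²/m² area factor. Generators cover the stimuli the model is
usually probed with: a Planckian radiator at 2856 K normalized to 100 at
560 nm (Illuminant A), general blackbodies, Gaussian narrowband lines
(default FWHM 10 nm — nominal single wavelengths need finite width on a
sampled grid), multi-Gaussian LED composites with an optional spectral
notch (for "warm LED with a 480-nm gap" comparisons), and equal-energy
spectra. Out-of-grid wavelengths in an input file contribute nothing: the
weighting functions are zero outside their domain.

## Analysis procedures

**Constant-criterion sensitivity.** For each narrowband wavelength the
package solves (by monotone root-finding in log level) for the total
irradiance at which the model chain `cla_2020 → cs_tf` reaches a criterion
response, 0.35 by default — half the 0.7 asymptote. Relative sensitivity is
the smallest criterion irradiance over all wavelengths divided by the
criterion irradiance at each wavelength. The search is anchored at a
reference overall level of 300 scotopic lx; because sensitivity is a ratio
of criterion irradiances, the derived curve is invariant to uniform
rescaling of all stimuli, and the anchor only has to put the root bracket
in range.

```{r sens, eval = FALSE}
sens <- derive_relative_sensitivity(seq(400, 650, 5))
sens$wavelengths[which.max(sens$relative_sensitivity)]  # 460
```

**Fixed-shape logistic fitting.** `fit_half_saturation()` estimates the
half-saturation constant alone (asymptote and exponent pinned) by least
squares: a coarse grid over log-spaced candidates followed by
golden-section refinement of the bracketing interval. Fitting and alignment
are done in log-level coordinates throughout. `align_log_shift()` finds the
log₁₀ translation of one dose-response curve that minimizes squared
response differences against another over their overlapping range — a
least-squares stand-in for alignment "to a mid-point", whose exact
objective is not specified in the source material.
`fit_duration_exponent()` fits `half_sat = C·t^b` in log-log space, with
`C` pinned to 355.7 when `fix_coefficient = TRUE`.

**Attainable precision of the half-saturation fit.** With n single
observations of fractional suppression at noise σ, the logistic's
information about the half-saturation constant is bounded:
`dCS/d ln(half_sat) = 0.7·p·u/(1+u)² ≤ 0.193` (u the logistic argument,
maximized at the half-saturation point), so `SE(ln K) ≥ σ/(0.193·√n)` for
*any* dose placement. At n = 8, σ = 0.03 that is ≈ 5.5% relative — a
single 8-point dataset cannot localize the half-saturation constant much
better than ±5% at one standard error, and the test suite asserts recovery
at the precision this bound supports (within 15% in ≥90% of seeded
replicates) rather than pretending to more.

## Synthetic suppression data

`generate_synthetic_dataset()` emulates the *structure* of a study-level
suppression table: stimulus spec, level, duration, distribution factor,
observed suppression. True responses come from the model itself
(`cs_tf(cla_2020(...))`); observation noise is additive Gaussian on
fractional suppression (σ = 0.03 by default, the simplest model consistent
with assay scatter), clipped to [−0.2, 1] since measured suppression can go
slightly negative. Generation is seeded and restores the RNG state.

What passing tests on these data do and do not show: they demonstrate that
the fitting procedures recover known generating parameters under the
declared noise model, and that the model pipeline is self-consistent. They
do not validate the model against human melatonin data — real suppression
datasets have between-subject variability, non-Gaussian and
level-dependent noise, and prior-light-history effects that the generator
deliberately omits. The published fit qualities to the original study
datasets cannot be recomputed here because those datasets are not bundled.

## Configuration, sizes, and determinism

Run configuration is YAML (`model`, `cs`, `exposure`, `grid`, `seed`
sections; unknown keys are rejected; command-line flags override the
file). The default grid is 380–780 nm at 1 nm (401 samples); template
tuning runs once per session per variant on an internal 360–830 nm
reference grid so tuned constants do not depend on the session grid. The
test suite uses 10³ random levels/triples for the CS invariants, 10²
random polychromatic SPDs for branch checks, and 100 seeded replicates for
recovery tests; the sensitivity derivation covers 400–650 nm in 5-nm steps.
All randomized tests fix seeds. Bit-exact invariance of `CS_t,f` under
permutation of (t, f, CL_A) is guaranteed by multiplying the three factors
in sorted order.

Degenerate inputs have defined conventions: an all-zero SPD gives zero for
every quantity (the rod ratio's 0/0 is defined as 0 — no rod signal, no
threshold elevation); ties in `peak_wavelength()` break toward the shorter
wavelength; `fwhm()` reports which side of the curve failed to cross
half-maximum when the support is truncated.

## Limitations

The model is silent on intermittent or flickering light and hysteresis,
habituation beyond 3 h of continuous exposure, pupil-size adaptation,
prior light history, and phase-shift or sleep outcomes; f takes only three
discrete levels, an acknowledged first approximation to retinal
anisotropy. CS predicts melatonin suppression during the early biological
night, not every circadian endpoint. Whether stimuli should be treated as
corneal or retinal irradiance is not fully settled; the package uniformly
treats input as corneal irradiance with a cosine detector.
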