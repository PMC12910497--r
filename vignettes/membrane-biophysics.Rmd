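---
title: "Models and methods: DIB permeametry, tensiometry, DSC and Raman band ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: DIB permeametry, tensiometry, DSC and Raman band ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memphys)
```

memphys implements the four measurement chains used to quantify how a small
amphipathic guest molecule (serotonin is the motivating case) nonspecifically
remodels model lipid membranes, together with the factorial statistics that
tie them together. This vignette is the package's account of the underlying
models, the tunable parameters, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## Osmotic water permeability from droplet interface bilayers

Two lipid-monolayer-coated aqueous droplets in oil adhere over a contact
patch where a bilayer (a DIB) forms. If one droplet carries an impermeant
solute, water flows across the bilayer toward it. With solute content
$n_i$ (osmoles) fixed and osmolarity $c_i = n_i / V_i$, the volume flux is

$$\frac{dV_1}{dt} = P_f\, V_w\, A\,(c_1 - c_2), \qquad
  \frac{dV_2}{dt} = -\frac{dV_1}{dt},$$

where $P_f$ (µm/s) is the osmotic water permeability, $V_w$ the molar
volume of water (18.05 cm³/mol near 30 °C) and $A$ the bilayer area.
This is the standard osmotic-permeability definition; units are arranged so
$P_f$ emerges in µm/s from diameters in µm, areas in µm² and
osmolarities derived from mOsm/kg. Assumptions worth stating:

* solutes are impermeant (ion permeation is ~8 orders of magnitude slower
  than water permeation), so $n_i$ is constant;
* droplets stay spherical; the spherical-cap volume correction for the
  small contact patch is ignored (it is below the noise floor for the
  contact angles involved);
* the bilayer area is constant over the short observation window by
  default; `dynamic_area = TRUE` recomputes it at constant contact angle;
* osmolality (mOsm/kg) converts to osmolarity assuming solution density
  1.0 kg/L. The default 186 mOsm/kg corresponds to nominally 0.1 M NaCl
  (van 't Hoff factor 2 with osmotic coefficient 0.93); whenever a
  measured osmolality exists it should be passed explicitly.

`simulate_osmosis()` integrates this with an adaptive solver (deSolve
lsodar, rtol 1e-8) and stops at droplet depletion via a root function.

`estimate_pf()` offers two estimators. `initial_rate` fits a line to the
droplet volumes over the opening window (the larger of 10 frames and 10% of
the series) and divides the slope by $V_w A \Delta c_0$; it is simple but
noise-hungry, since the opening window contains little signal.
`ode_fit` (the default) minimises the summed squared diameter residuals of
the forward model over $P_f \in (0, 10^4]$ µm/s by bounded 1-D
optimisation. Two numerical choices matter at realistic frame noise:

* the fit starts from a whole-trace slope estimate rather than the opening
  window (the short-window slope can even be negative at 0.5% radius
  noise);
* the simulated trajectory starts from quadratic-trend intercepts of the
  observed volumes, not the raw first frame — a 0.5% error in the first
  frame alone is comparable to the entire osmotic diameter change over a
  60 s window and would otherwise bias the fit badly.

With 0.5% multiplicative radius noise per frame, single-run estimates
scatter with ~12% SD; this is why the assay pools tens of runs per
condition. At 0.1% frame noise the estimator contributes ~2.4% spread.

## Droplet-pair geometry and image segmentation

For adherent spheres of radii $R_1, R_2$ at centre distance $D$, the
contact patch is the common chord disk: the chord half-length is
$r_c = \sqrt{R_1^2 - a^2}$ with $a = (D^2 + R_1^2 - R_2^2)/2D$, the bilayer
area $A_b = \pi r_c^2$, and the contact angle is taken per droplet as
$\theta_i = \arcsin(r_c / R_i)$ and averaged. This convention makes
$\theta \to 0$ at tangency, so the tension balance below returns
$\gamma_b = 2\gamma_m$ for a non-adherent pair; it is the standard DIB
geometry. Where a primary measurement protocol is not available, this
convention is a documented assumption of the package.

`detect_droplet_pair()` segments micrographs (origin top-left, x rightward,
y downward, pixel units; a µm/px scale is applied downstream): Gaussian
smoothing, Otsu threshold, connected components (EBImage), then an
algebraic Kåsa circle fit refined by Gauss-Newton passes on each component
boundary. Adherent pairs merge into one peanut-shaped blob; its boundary is
split along the principal axis and boundary pixels are iteratively
reassigned to the nearer fitted circle, which recovers both arcs. Fitted
radii carry a half-pixel correction because boundary pixel centres sit
inside the true edge. Clean synthetic frames are recovered to about half a
pixel, frames with 5% additive noise to about two pixels.

## Bilayer tensiometry

At the three-phase contact line the bilayer tension balances the two
monolayer tensions pulling at angle $\theta$:

$$\gamma_b = 2\,\gamma_m \cos\theta .$$

Degrees are the external unit everywhere (matching tensiometer output);
conversion to radians is internal. `tension_table()` fills in $\gamma_b$
for a record table, rounds to 2 decimals by default (the reporting
precision of the instrument tables), and then normalises to each membrane's
zero-concentration control — rounding first means the relative column
matches what a reader recomputes from a published table. First-order error
propagation
$\sigma_{\gamma_b}^2 = (2\cos\theta\,\sigma_{\gamma_m})^2 +
(2\gamma_m\sin\theta\,\sigma_\theta)^2$ is available but optional, since
repeated-measurement SDs are usually reported instead.

## DSC thermogram reduction

A thermogram is `(T_C, cp_kcal_mol_C)` on a strictly increasing (not
necessarily uniform) grid; all integrals are trapezoidal. Heating scans are
analysed as endotherms; cooling scans are sign-flipped on read.

`baseline_correct()` fits straight lines under the pre- and
post-transition flanks and interpolates between them, by default
sigmoidally with the cumulative peak area as the interpolation weight (so
the baseline step sits where the transition occurs); a plain linear
interpolation is available via `method = "linear"`. Because the algorithm
behind the original instrument software is unspecified, this construction
is the package's own, and two refinements proved necessary:

* flanks widen adaptively from the outer 15% of the window to everything
  beyond three rough peak widths from the apex — the extra lever arm keeps
  the interpolated baseline stable under noise;
* both flank lines are fitted jointly with a shared $c/(T - T_m)^2$ term
  ($c \ge 0$) standing in for a heavy (Lorentzian-like) peak tail. Without
  it, the tail leaking into the flanks tilts the lines and biases the
  enthalpy low by ~2% for a pseudo-Voigt peak with 20% Lorentz character;
  keeping the term whenever its fitted amplitude is positive leaves the
  baseline unbiased, while a negative amplitude (unphysical) degenerates
  to plain lines, so clean Gaussian-tailed scans are unaffected.

`analyze_transition()` reports $T_m$ as the apex of a quadratic fit over
the contiguous top 25% of the peak (exact for symmetric peaks, robust to
point noise), the enthalpy as the trapezoidal integral over the peak
support — the region above 1% of peak height, extended outward to the zero
crossings of a lightly smoothed copy of the trace, so point-level noise
does not truncate the tails early — and the fwhm by linear interpolation of
the raw half-height crossings (the slope there is steep, so noise jitter is
small). A peak lower than 5 flank SDs is reported as "no transition";
a peak inside a flank is an unsuitable window.

Choices a user may care about: enthalpy is normalised per mole of total
lipid (not per mole of the majority lipid) in mixtures; the finite scan
window truncates heavy tails, which costs ~0.6% of the area of a
20%-Lorentz pseudo-Voigt of width 1.5 °C and grows with width — wide
transitions near the window edge are fundamentally harder, and the
analyzer refuses apexes inside the flank regions rather than guessing.

## Raman C–H band ratios

Acyl-chain order is read from the C–H stretching region: methylene
symmetric (~2850 cm⁻¹), methylene antisymmetric (~2890 cm⁻¹) and terminal
methyl (~2930 cm⁻¹) bands. The key order parameter is
$I_{2930}/I_{2890}$; it rises as gauche content rises and packing loosens.
`preprocess_spectrum()` removes a cubic polynomial baseline fitted outside
the band windows (windows padded by 50 cm⁻¹ so band tails do not pull the
polynomial) and rescales so the 2850 band maximum is 1. Band intensities
are windowed maxima over ±10 cm⁻¹ of the nominal centres — band positions
are only approximate in this kind of data, and maxima on normalised
spectra are robust; the window half-width is the package's choice.

A guest molecule with an indole ring contributes its own intensity; its
contribution is removed by `subtract_reference()`: the pure-guest spectrum
is scaled by the ratio of sample to reference intensity of the 1540 cm⁻¹
indole band (windowed maximum over 1520–1560 cm⁻¹), subtracted, clipped at
zero (the clipped negative mass is kept as a QC metric), and the result is
re-normalised to the 2850 band. The re-normalisation makes subtraction
exact — under the module's unit-2850 convention — whenever the sample is a
nonnegative linear combination of a lipid-only spectrum and the reference;
the property suite verifies this over random mixing weights. The
1540-anchor scaling rule is the package's documented assumption.

## Statistics

The study design is a 3-membrane × 6-concentration fixed-effects factorial.
`normalize_to_control()` divides by the control mean per membrane; the
control's error bar is the relative SD of the raw control replicates.
`two_way_anova()` is the standard balanced decomposition (`stats::aov`)
with interaction; unbalanced tables fall back to Type-II sums of squares
with a warning. `tukey_hsd()` performs studentized-range comparisons with
the residual mean square of the full two-way fit, in the two families the
figures of such studies annotate: concentrations within a membrane, or
membranes at a concentration; p values come from `stats::ptukey` and the
test suite cross-checks them against an independent numerical integration
of the studentized range distribution. Stars map to
0.05/0.01/0.001/0.0001.

## The synthetic-data generators

`default_effect_model()` encodes, per membrane and observable, a control
level and a saturating dose response
$\mathrm{value}(c) = \mathrm{control} + \mathrm{amp}\,c/(c + c_{50})$ with
$c_{50} = 10$ mM — the concentration regime where effects become prominent
— and amp set so the 40 mM (4:1 molar ratio) condition matches the
end-point values of the motivating study. Control permeabilities are
73/62/67 µm/s for DOPC, DOPC/DOPS (10:1) and DOPC/SM/Chol (1:1:0.2);
control transitions are (−16.68 °C, 8.34 kcal/mol, 1.5 °C),
(−15.88, 9.10, 0.95) and (−18.67, 2.67, 2.73). Raman control ratios
(0.85/0.80/0.75) and their relative amplitudes (0.12/0.28/0.28), and the
DOPC/DOPS tensiometry column, are illustrative — such controls are not
tabulated — and are flagged as such rather than estimated. Replicate noise
defaults: 3% CV on permeability runs, 0.1 °C SD on $T_m$, 5% CV on
enthalpy and width, 3% on ratios, 2% on monolayer tension, 0.3° on contact
angles; frame-level radius noise is 0.1% for study emulation (so the
per-run permeability spread matches the reported replicate SDs) and 0.5%
where the estimator is deliberately stress-tested.

Generators are pure functions of their parameters and seed (the global RNG
stream is left untouched), and every object carries its ground truth in
attributes, making round-trip recovery the universal test pattern. The DSC
generator uses a pseudo-Voigt peak with Lorentz fraction 0.2 (MLV
endotherms are near-Gaussian; heavier tails would push area outside the
finite scan window) on a gentle linear baseline. The Raman generator uses
Gaussian bands plus a guest reference with the 1540 cm⁻¹ band and a small
2930 cm⁻¹ contribution.

What the generators do **not** emulate: instrument artifacts (CCD spikes,
DSC hysteresis), multi-component or asymmetric transitions, domain (lo/ld)
structure — the band-ratio read-out is a bulk measurement by design — and
droplet deformation beyond spheres. Passing tests therefore demonstrate
correctness of the analysis chains under the stated statistical structure,
not robustness to every artifact of real instruments.

## Problem sizes and determinism

The test-suite simulations are sized to be decisive yet quick: 60 s
droplet traces at 1 Hz; 200 randomized thermograms (Gaussian peaks, noise
up to 2% of height, apex kept clear of the baseline flanks) for the
recovery property; 10,000 null factorial tables (n = 2 per cell) for the
type-I error of the ANOVA layer; 100 random droplet-pair images for the
detection property; and a full pipeline run with 50 permeability runs and
3 spectroscopy/calorimetry replicates per cell — the replication structure
of the emulated study — for the membrane-ordering check. All stochastic
tests fix their seeds.

## A worked run

```{r pipeline, eval = FALSE}
res <- run_full_pipeline(
  n_replicates = c(pf = 50, tm = 3, dh = 3, fwhm = 3, ratio = 3,
                   gamma_m = 3, theta = 3),
  seed = 1
)
membrane_sensitivity(res$normalized)
plot_dose_response(dplyr::filter(res$normalized, observable == "pf"))
```

With the default effect model this recovers the ordering of membrane
responsiveness DOPC/DOPS ≈ DOPC/SM/Chol > DOPC across permeability,
thermotropic and chain-order observables, with bilayer tension dropping
most where permeability rises most.

## Known limitations

* The contact-angle convention ($\arcsin(r_c/R)$, averaged over the two
  droplets) and the 1540-anchor subtraction rule are assumptions standing
  in for unavailable primary protocols; both are isolated behind single
  functions and easy to swap.
* `ode_fit` treats the bilayer area as constant during fitting; traces
  with large fractional volume changes should use `dynamic_area`
  simulation and short fitting windows.
* Enthalpy recovery degrades for transitions wider than ~1/6 of the scan
  window, and the heavy-tail area lost beyond the window is not
  extrapolated.
* Tukey comparisons assume homoscedastic cells (pooled residual mean
  square), as the classical procedure does.
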