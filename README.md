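# memphys

Analysis chains for quantifying how small amphipathic molecules
(serotonin being the motivating case) nonspecifically remodel model lipid
membranes. The package is aimed at membrane-biophysics labs running four
complementary assays on the same 3-membrane × 6-concentration factorial
design — DOPC, DOPC/DOPS (10:1) and DOPC/SM/Chol (1:1:0.2) bilayers over a
guest-molecule dose series — and wanting one tested, scriptable pipeline
from raw instrument records to annotated statistics:

* **DIB permeametry** — the osmotic water permeability coefficient
  *P*<sub>f</sub> from droplet-interface-bilayer shrink/swell traces.
  Forward model `dV₁/dt = P_f·V_w·A·(c₁ − c₂)` with impermeant solutes
  (`c_i = n_i/V_i`); estimation by initial-rate or bounded ODE least
  squares.
* **Droplet-pair geometry** — spherical-cap contact geometry
  (`r_c`, `θ = arcsin(r_c/R)`, `A_b = π r_c²`) and segmentation of droplet
  pairs from grayscale micrographs (threshold → components → Kåsa circle
  fit with Gauss-Newton refinement; touching pairs are split along the
  blob's principal axis).
* **Bilayer tensiometry** — `γ_b = 2 γ_m cos θ` with control
  normalisation and optional first-order error propagation.
* **DSC reduction** — sigmoidal (cumulative-area-weighted) baseline
  subtraction with tail-aware flank fits, then *T*<sub>m</sub> (apex),
  ΔH (trapezoidal integral over the peak support) and fwhm.
* **Raman C–H band ratios** — polynomial baseline removal, unit-2850
  normalisation, subtraction of the guest's own spectrum anchored on its
  1540 cm⁻¹ indole band, and the order ratio *I*₂₉₃₀/*I*₂₈₉₀.
* **Statistics** — control normalisation, two-way fixed-effects ANOVA
  with interaction, Tukey HSD in the families such studies annotate, and
  star thresholds 0.05/0.01/0.001/0.0001.

Seeded generators (`gen_droplet_timeseries()`, `gen_thermogram()`,
`gen_raman_spectrum()`, `gen_droplet_image()`, `gen_study_dataset()`)
emulate every raw input with known ground truth, so the whole pipeline is
testable end to end without instrument data.

All user-facing functions take a data frame first and return tibbles, so
chains compose with the pipe; fitted objects have `tidy()`/`glance()`
methods and results have `plot_*()`/`autoplot()` helpers.

## Worked example

Simulate a control DIB experiment (100 µm droplets, 186 mOsm/kg gradient,
θ = 31.2°) and recover the permeability:

```r
library(memphys)

ts <- simulate_osmosis(pf = 73, times = 0:60, theta_deg = 31.2)
estimate_pf(ts)
#> <pf_fit> Pf = 72.99 um/s (ode_fit, 61 frames, RMS diameter residual 7.25e-05 um)
```

The estimator recovers the generative 73 µm/s to 0.01%; on real traces the
residual line is the first quality check (here it is integrator-level
noise only).

Bilayer tension from tensiometry records (the package ships a reference
table of monolayer tensions and contact angles for DOPC and DOPC/SM/Chol
across the dose series):

```r
recs <- read_tension_records(system.file("extdata",
        "tensiometry_reference.csv", package = "memphys"))
tension_table(recs)[c(1, 6, 7, 12), c("membrane", "serotonin_mM",
                                      "gamma_b_mN_m", "rel_gamma_b")]
#>   membrane     serotonin_mM gamma_b_mN_m rel_gamma_b
#> 1 DOPC                    0         1.92       1
#> 2 DOPC                   40         0.88       0.458
#> 3 DOPC/SM/Chol            0         2.17       1
#> 4 DOPC/SM/Chol           40         0.69       0.318
```

Bilayer tension roughly halves for DOPC and drops to a third for the
raft-like ternary mixture at the top dose — the same composition
dependence the permeability and calorimetry chains report.

Reduce a synthetic control endotherm:

```r
tg <- gen_thermogram(tm = -16.68, dh = 8.34, fwhm = 1.5, noise_sd = 0)
analyze_transition(baseline_correct(tg))
#>    Tm_C dH_kcal_mol fwhm_C peak_height
#> 1 -16.7        8.28   1.50        4.88
```

`Tm` is exact, `ΔH` is 0.7% low (the heavy-tail area beyond the finite
scan window), `fwhm` exact.

The whole factorial study, from synthetic raw records to ANOVA/Tukey
tables:

```r
res <- run_full_pipeline(n_replicates = c(pf = 50, tm = 3, dh = 3,
                                          fwhm = 3, ratio = 3,
                                          gamma_m = 3, theta = 3), seed = 1)
membrane_sensitivity(res$normalized)   # relative change at the top dose
```

which recovers the ordering of membrane responsiveness
DOPC/DOPS ≈ DOPC/SM/Chol > DOPC across observables.

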